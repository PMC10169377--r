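# MultiColony: an ordered collection of colonies (apiary, region, age group).
#
# A slot holds a Colony, an *empty* Colony (no members), or NULL (a
# placeholder). Vectorized operations apply colony-by-colony in order, so a
# vectorized call is exactly equivalent to mapping the scalar operation.

#' Create a MultiColony
#'
#' Builds a collection of colonies from a virgin-queen population (one
#' colony per queen), from a list of colonies, or as `n` NULL placeholder
#' slots.
#'
#' @param x a `BeePop` of virgin queens, a list of `Colony` objects, or
#'   `NULL`.
#' @param n number of NULL placeholder slots when `x` is `NULL`.
#' @param simParamBee simulation parameters (default: global).
#' @return A `MultiColony` object.
#' @export
createMultiColony <- function(x = NULL, n = NULL, simParamBee = NULL) {
  if (is.null(x)) {
    colonies <- vector("list", if (is.null(n)) 0L else resolveN(n, "n"))
  } else if (inherits(x, "BeePop")) {
    colonies <- lapply(seq_len(nInd(x)), function(i) {
      createColony(x[i], simParamBee = simParamBee)
    })
  } else if (is.list(x)) {
    stopifnot(all(vapply(x, function(cl) is.null(cl) || inherits(cl, "Colony"), TRUE)))
    colonies <- x
  } else stopf("'x' must be a BeePop, a list of colonies, or NULL")
  mc <- structure(list(colonies = colonies), class = "MultiColony")
  assertUniqueColonyIds(mc)
  mc
}

#' @noRd
assertUniqueColonyIds <- function(mc) {
  ids <- colonyIds(mc)
  if (anyDuplicated(ids[!is.na(ids)])) stopf("duplicated colony ids in MultiColony")
  invisible(mc)
}

#' Number of colonies in a MultiColony
#'
#' `nColonies()` counts all slots, `nNullColonies()` the NULL placeholders,
#' and `nEmptyColonies()` the colonies without any individuals.
#'
#' @param mc a `MultiColony`.
#' @return Integer count.
#' @export
nColonies <- function(mc) {
  stopifnot(inherits(mc, "MultiColony"))
  length(mc$colonies)
}

#' @rdname nColonies
#' @export
nNullColonies <- function(mc) sum(vapply(mc$colonies, is.null, TRUE))

#' @rdname nColonies
#' @export
nEmptyColonies <- function(mc) {
  sum(vapply(mc$colonies, function(cl) {
    !is.null(cl) && nQueens(cl) + nWorkers(cl) + nDrones(cl) +
      nVirginQueens(cl) == 0L
  }, TRUE))
}

#' @noRd
colonyIds <- function(mc) {
  vapply(mc$colonies, function(cl) if (is.null(cl)) NA_character_ else cl$id, "")
}

#' @exportS3Method base::print
print.MultiColony <- function(x, ...) {
  cat("MultiColony\n")
  cat(sprintf("  colonies: %d (empty: %d, NULL: %d)\n", nColonies(x),
              nEmptyColonies(x), nNullColonies(x)))
  real <- Filter(Negate(is.null), x$colonies)
  if (length(real)) {
    cat(sprintf("  queenright: %d | swarmed: %d | split: %d | superseded: %d | collapsed: %d | productive: %d\n",
                sum(vapply(real, isQueenPresent, TRUE)),
                sum(vapply(real, hasSwarmed, TRUE)),
                sum(vapply(real, hasSplit, TRUE)),
                sum(vapply(real, hasSuperseded, TRUE)),
                sum(vapply(real, hasCollapsed, TRUE)),
                sum(vapply(real, isProductive, TRUE))))
  }
  invisible(x)
}

#' @export
`[.MultiColony` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, colonyIds(x))
    if (anyNA(i)) stopf("unknown colony id")
  }
  structure(list(colonies = x$colonies[i]), class = "MultiColony")
}

#' @export
c.MultiColony <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "MultiColony")))
  mc <- structure(list(colonies = do.call(c, lapply(parts, `[[`, "colonies"))),
                  class = "MultiColony")
  assertUniqueColonyIds(mc)
  mc
}

#' Pull colonies out of a MultiColony
#'
#' Partitions the collection into `pulled` and `remnant` parts, preserving
#' relative order within each. Selection is by uniform sampling of `n`
#' colonies, by colony `ids`, or by a predicate function over colonies.
#'
#' @param mc a `MultiColony`.
#' @param n number of colonies to sample uniformly.
#' @param ids colony ids to pull.
#' @param predicate function `Colony -> logical`.
#' @return A list with `pulled` and `remnant` `MultiColony` objects.
#' @export
pullColonies <- function(mc, n = NULL, ids = NULL, predicate = NULL) {
  stopifnot(inherits(mc, "MultiColony"))
  allIds <- colonyIds(mc)
  if (!is.null(ids)) {
    take <- match(as.character(ids), allIds)
    if (anyNA(take)) stopf("unknown colony id(s): %s",
                           paste(ids[is.na(take)], collapse = ", "))
  } else if (!is.null(predicate)) {
    take <- which(vapply(mc$colonies, function(cl) !is.null(cl) && isTRUE(predicate(cl)), TRUE))
  } else {
    n <- resolveN(if (is.null(n)) 1L else n, "n")
    if (n > nColonies(mc)) stopf("cannot pull %d of %d colonies", n, nColonies(mc))
    take <- sort(sample.int(nColonies(mc), n))
  }
  keep <- setdiff(seq_len(nColonies(mc)), take)
  list(pulled = mc[take], remnant = mc[keep])
}

#' Select the best colonies
#'
#' Keeps the `n` colonies with the highest values of `use` (e.g. colony
#' genetic or phenotypic values from [calcColonyValue()]). Ties are broken
#' deterministically by smaller colony id.
#'
#' @param mc a `MultiColony` without NULL slots.
#' @param n number of colonies to keep.
#' @param use numeric vector, one value per colony.
#' @return A `MultiColony` of the selected colonies, best first.
#' @export
selectColonies <- function(mc, n, use) {
  stopifnot(inherits(mc, "MultiColony"))
  if (length(use) != nColonies(mc)) {
    stopf("'use' must supply one value per colony (%d needed, %d given)",
          nColonies(mc), length(use))
  }
  n <- resolveN(n, "n")
  if (n > nColonies(mc)) stopf("cannot select %d of %d colonies", n, nColonies(mc))
  ord <- order(-use, as.numeric(colonyIds(mc)))
  mc[ord[seq_len(n)]]
}

# --- vectorized colony operations -----------------------------------------

# Apply a scalar colony function over the slots, recycling per-colony
# arguments; errors are rethrown naming the colony.
#' @noRd
mapColonies <- function(mc, fun, ..., perColony = list()) {
  nc <- nColonies(mc)
  perColony <- lapply(perColony, function(a) {
    if (is.null(a) || is.function(a) || length(a) == 1L) rep(list(a), nc)
    else if (length(a) == nc) as.list(a)
    else stopf("per-colony argument of length %d does not match %d colonies",
               length(a), nc)
  })
  lapply(seq_len(nc), function(i) {
    cl <- mc$colonies[[i]]
    if (is.null(cl)) stopf("NULL colony slot %d", i)
    args <- c(list(cl), lapply(perColony, `[[`, i), list(...))
    tryCatch(do.call(fun, args),
             error = function(e) stopf("colony '%s': %s", cl$id, conditionMessage(e)))
  })
}

#' @rdname buildUp
#' @export
buildUp.MultiColony <- function(x, nWorkers = NULL, nDrones = NULL,
                                simParamBee = NULL, ...) {
  res <- mapColonies(x, buildUp.Colony, simParamBee = simParamBee,
                     perColony = list(nWorkers = nWorkers, nDrones = nDrones))
  createMultiColony(res)
}

#' @rdname swarm
#' @export
swarm.MultiColony <- function(x, p = NULL, nVirginQueens = NULL,
                              simParamBee = NULL, ...) {
  res <- mapColonies(x, swarm.Colony, nVirginQueens = nVirginQueens,
                     simParamBee = simParamBee, perColony = list(p = p))
  list(swarm = createMultiColony(lapply(res, `[[`, "swarm")),
       remnant = createMultiColony(lapply(res, `[[`, "remnant")))
}

#' @rdname split.Colony
#' @export
split.MultiColony <- function(x, p = NULL, nVirginQueens = NULL,
                              simParamBee = NULL, ...) {
  res <- mapColonies(x, split.Colony, nVirginQueens = nVirginQueens,
                     simParamBee = simParamBee, perColony = list(p = p))
  list(split = createMultiColony(lapply(res, `[[`, "split")),
       remnant = createMultiColony(lapply(res, `[[`, "remnant")))
}

#' @rdname supersede
#' @export
supersede.MultiColony <- function(x, nVirginQueens = NULL, simParamBee = NULL, ...) {
  createMultiColony(mapColonies(x, supersede.Colony,
                                nVirginQueens = nVirginQueens,
                                simParamBee = simParamBee))
}

#' @rdname collapse
#' @export
collapse.MultiColony <- function(x, ...) {
  createMultiColony(mapColonies(x, collapse.Colony))
}

#' @rdname downsize
#' @export
downsize.MultiColony <- function(x, p = NULL, simParamBee = NULL, ...) {
  createMultiColony(mapColonies(x, downsize.Colony, simParamBee = simParamBee,
                                perColony = list(p = p)))
}
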