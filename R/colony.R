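# Colony: the operational unit of the simulation.
#
# A colony holds at most one queen (with her stored fathers), plus worker,
# drone, and virgin-queen populations, a location, and event flags. All
# colony operations are functional: they return a modified copy. A collapsed
# colony is frozen — only read access is allowed afterwards.

#' @noRd
newColonyId <- function(sp) {
  sp$lastColonyId <- sp$lastColonyId + 1L
  as.character(sp$lastColonyId)
}

#' @noRd
assertMutable <- function(colony) {
  if (inherits(colony, "Colony") && isTRUE(colony$collapsed)) {
    stopf("colony '%s' has collapsed; further simulation with it is not allowed",
          colony$id)
  }
  invisible(colony)
}

#' Create a colony
#'
#' Starts a colony from a single female: a virgin queen (to be mated later
#' with [cross()]) or an already mated queen (then `fathers` must carry her
#' spermatheca). The new colony has a fresh id, an unset location, all event
#' flags off, and is not productive.
#'
#' @param x a `BeePop` holding exactly one virgin queen or queen.
#' @param fathers father `BeePop` when `x` is a mated queen.
#' @param simParamBee simulation parameters (default: global).
#' @return A `Colony` object.
#' @export
createColony <- function(x = NULL, fathers = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  queen <- newBeePop(); virginQueens <- newBeePop()
  if (!is.null(x)) {
    stopifnot(inherits(x, "BeePop"))
    if (nInd(x) != 1L) stopf("provide exactly one female to head the colony")
    caste <- getCaste(x, sp)
    if (caste == "virginQueen") {
      virginQueens <- x
    } else if (caste == "queen") {
      if (is.null(fathers) || nInd(fathers) == 0L) {
        stopf("a mated queen must come with her stored fathers")
      }
      queen <- x
    } else stopf("a colony must be headed by a virgin queen or a queen, not a %s", caste)
  }
  structure(
    list(id = newColonyId(sp), location = c(NA_real_, NA_real_),
         queen = queen,
         fathers = if (nInd(queen)) fathers else newBeePop(),
         workers = newBeePop(), drones = newBeePop(),
         virginQueens = virginQueens,
         swarmed = FALSE, split = FALSE, superseded = FALSE,
         collapsed = FALSE, productive = FALSE),
    class = "Colony"
  )
}

#' @exportS3Method base::print
print.Colony <- function(x, ...) {
  cat("Colony\n")
  cat("  id:", x$id, "\n")
  cat("  location:", if (all(is.na(x$location))) "NA" else
    paste(x$location, collapse = ", "), "\n")
  cat("  queen:", if (nInd(x$queen)) x$queen$id else "NA", "\n")
  cat(sprintf("  fathers: %d | workers: %d | drones: %d | virgin queens: %d\n",
              nFathers(x), nWorkers(x), nDrones(x), nVirginQueens(x)))
  cat(sprintf("  swarmed: %s | split: %s | superseded: %s | collapsed: %s | productive: %s\n",
              x$swarmed, x$split, x$superseded, x$collapsed, x$productive))
  invisible(x)
}

# --- counting and access ---------------------------------------------------

#' @noRd
casteSlot <- function(caste) {
  switch(match.arg(caste, c("queen", "fathers", "workers", "drones", "virginQueens")),
         queen = "queen", fathers = "fathers", workers = "workers",
         drones = "drones", virginQueens = "virginQueens")
}

#' Count caste members of a colony
#'
#' `countCaste()` counts individuals of one caste; `nQueens()`,
#' `nFathers()`, `nWorkers()`, `nDrones()` and `nVirginQueens()` are
#' shorthands. Collapsed colonies remain countable (reading is allowed).
#'
#' @param colony a `Colony`.
#' @param caste one of `"queen"`, `"fathers"`, `"workers"`, `"drones"`,
#'   `"virginQueens"`.
#' @return Integer count.
#' @export
countCaste <- function(colony, caste) {
  stopifnot(inherits(colony, "Colony"))
  nInd(colony[[casteSlot(caste)]])
}

#' @rdname countCaste
#' @export
nQueens <- function(colony) countCaste(colony, "queen")

#' @rdname countCaste
#' @export
nFathers <- function(colony) countCaste(colony, "fathers")

#' @rdname countCaste
#' @export
nWorkers <- function(colony) countCaste(colony, "workers")

#' @rdname countCaste
#' @export
nDrones <- function(colony) countCaste(colony, "drones")

#' @rdname countCaste
#' @export
nVirginQueens <- function(colony) countCaste(colony, "virginQueens")

#' Copy or pull caste members from a colony
#'
#' `getCastePop()` copies individuals (the colony is left unchanged);
#' `pullCastePop()` removes `n` uniformly sampled individuals and returns
#' both the pulled population and the modified colony.
#'
#' @param colony a `Colony`.
#' @param caste caste slot name, as in [countCaste()].
#' @param n for pulling: how many to remove (default: all).
#' @return `getCastePop()`: a `BeePop`. `pullCastePop()`: a list with
#'   `pulled` and `colony`.
#' @export
getCastePop <- function(colony, caste) {
  stopifnot(inherits(colony, "Colony"))
  colony[[casteSlot(caste)]]
}

#' @rdname getCastePop
#' @export
pullCastePop <- function(colony, caste, n = NULL) {
  stopifnot(inherits(colony, "Colony"))
  assertMutable(colony)
  slot <- casteSlot(caste)
  pop <- colony[[slot]]
  if (is.null(n)) n <- nInd(pop)
  n <- resolveN(n, "n")
  if (n > nInd(pop)) {
    stopf("cannot pull %d individuals from %d %s", n, nInd(pop), caste)
  }
  take <- sample.int(nInd(pop), n)
  pulled <- pop[take]
  colony[[slot]] <- pop[setdiff(seq_len(nInd(pop)), take)]
  list(pulled = pulled, colony = colony)
}

#' Add, remove, or replace caste members
#'
#' `addCastePop()` inserts individuals (or creates `n` new brood members of
#' that caste from the colony queen); `removeCastePop()` drops all (or `n`
#' sampled) members; `replaceCastePop()` removes current members and creates
#' fresh replacements from the queen.
#'
#' @param colony a `Colony`.
#' @param caste caste slot, one of `"workers"`, `"drones"`,
#'   `"virginQueens"` (the queen is managed by [cross()] / [reQueen()]).
#' @param x a `BeePop` to add, or a count/sampler of new brood to create.
#' @param n how many to remove (default: all).
#' @param simParamBee simulation parameters (default: global).
#' @return The modified `Colony`.
#' @export
addCastePop <- function(colony, caste, x, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  stopifnot(inherits(colony, "Colony"))
  assertMutable(colony)
  slot <- casteSlot(caste)
  if (slot == "queen") stopf("cannot add a queen; use cross() or reQueen()")
  if (!inherits(x, "BeePop")) {
    x <- switch(slot,
      workers = createWorkers(colony, x, sp)$workers,
      drones = createDrones(colony, x, sp),
      virginQueens = createVirginQueens(colony, x, sp),
      stopf("cannot create members for slot '%s'", slot))
  } else {
    want <- c(workers = "worker", drones = "drone",
              virginQueens = "virginQueen", fathers = "father")[[slot]]
    if (!all(getCaste(x, sp) == want)) {
      stopf("individuals added to '%s' must have caste '%s'", slot, want)
    }
  }
  colony[[slot]] <- c(colony[[slot]], x)
  colony
}

#' @rdname addCastePop
#' @export
removeCastePop <- function(colony, caste, n = NULL) {
  stopifnot(inherits(colony, "Colony"))
  assertMutable(colony)
  slot <- casteSlot(caste)
  if (is.null(n)) {
    colony[[slot]] <- newBeePop()
    return(colony)
  }
  pullCastePop(colony, caste, n)$colony
}

#' @rdname addCastePop
#' @export
replaceCastePop <- function(colony, caste, n, simParamBee = NULL) {
  colony <- removeCastePop(colony, caste)
  addCastePop(colony, caste, n, simParamBee)
}

# --- status ---------------------------------------------------------------

#' Colony status flags and caste presence
#'
#' Production is on only after a build-up and is turned off when a colony
#' swarms, collapses, is downsized, or is split off from another colony.
#'
#' @param colony a `Colony`.
#' @param caste caste slot name for `isCastePresent()`.
#' @return A logical scalar.
#' @export
isProductive <- function(colony) isTRUE(colony$productive)

#' @rdname isProductive
#' @export
hasSwarmed <- function(colony) isTRUE(colony$swarmed)

#' @rdname isProductive
#' @export
hasSplit <- function(colony) isTRUE(colony$split)

#' @rdname isProductive
#' @export
hasSuperseded <- function(colony) isTRUE(colony$superseded)

#' @rdname isProductive
#' @export
hasCollapsed <- function(colony) isTRUE(colony$collapsed)

#' @rdname isProductive
#' @export
isCastePresent <- function(colony, caste) countCaste(colony, caste) > 0L

#' @rdname isProductive
#' @export
isQueenPresent <- function(colony) isCastePresent(colony, "queen")

#' @rdname isProductive
#' @export
isVirginQueensPresent <- function(colony) isCastePresent(colony, "virginQueens")

#' @rdname isProductive
#' @export
isFathersPresent <- function(colony) isCastePresent(colony, "fathers")
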