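# Mating: drone congregation areas, mating stations, cross plans, cross().
#
# A virgin queen mates once, with several drones (polyandry; typically 6-24
# in nature), and stores their sperm for life. Mated drones die: they become
# "fathers", live on only inside the queen's spermatheca, and can never
# mate again.

#' Create a drone congregation area (DCA)
#'
#' Pools drones from one or more sources into a single population, as at a
#' natural congregation area where drones of many colonies gather. Sources
#' that are colonies contribute their current drones (copied out); drone
#' populations are pooled as-is. Each drone retains its pedigree.
#'
#' @param x a `BeePop` of drones, a `Colony`, a `MultiColony`, or a list of
#'   such sources.
#' @param simParamBee simulation parameters (default: global).
#' @return A `BeePop` of drones.
#' @export
createDCA <- function(x, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  sources <- if (inherits(x, "MultiColony")) x$colonies
             else if (inherits(x, c("BeePop", "Colony"))) list(x)
             else if (is.list(x)) x
             else stopf("unsupported DCA source")
  pops <- lapply(sources, function(s) {
    if (inherits(s, "Colony")) getCastePop(s, "drones")
    else if (inherits(s, "BeePop")) s
    else stopf("unsupported DCA source")
  })
  dca <- do.call(c, c(pops, list(newBeePop())))
  if (nInd(dca) == 0L) stopf("no drones found in the DCA sources")
  if (!all(isDrone(dca, sp))) stopf("DCA sources must contain drones only")
  dca
}

#' Create a mating station DCA
#'
#' Emulates a mating station: `nDPQs` daughter virgin queens (drone-producing
#' queens, DPQs) are reared from the sire colony, and each contributes
#' `nDronesPerDPQ` drones. All drones at the station are therefore grandsons
#' of the sire colony's queen.
#'
#' @param sireColony a `Colony` with a mated queen.
#' @param nDPQs number of drone-producing queens (> 0).
#' @param nDronesPerDPQ drones per DPQ (count or sampler).
#' @param simParamBee simulation parameters (default: global).
#' @return A `BeePop` of drones.
#' @export
createMatingStationDCA <- function(sireColony, nDPQs = 10, nDronesPerDPQ = 100,
                                   simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  stopifnot(inherits(sireColony, "Colony"))
  if (nInd(sireColony$queen) == 0L) stopf("the sire colony must have a mated queen")
  nDPQs <- resolveN(nDPQs, "nDPQs")
  if (nDPQs < 1L) stopf("'nDPQs' must be at least 1")
  dpqs <- createVirginQueens(sireColony, nDPQs, sp)
  if (nInd(dpqs) == 0L) stopf("no viable drone-producing queens could be reared")
  createDrones(dpqs, nDronesPerDPQ, sp)
}

#' Pull groups of drones from a DCA
#'
#' Samples `n` disjoint drone groups (one per virgin queen to be mated)
#' uniformly without replacement; sampled drones are removed from the DCA.
#'
#' @param dca a `BeePop` of drones.
#' @param n number of groups.
#' @param nFathers group size (count or sampler, drawn per group); default
#'   `nFathers` from the simulation parameters.
#' @param simParamBee simulation parameters (default: global).
#' @return A list with `groups` (list of `BeePop`s) and the depleted `dca`.
#' @export
pullDroneGroupsFromDCA <- function(dca, n, nFathers = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  stopifnot(inherits(dca, "BeePop"))
  n <- resolveN(n, "n")
  groups <- vector("list", n)
  for (g in seq_len(n)) {
    k <- resolveN(if (is.null(nFathers)) sp$nFathers else nFathers, "nFathers")
    if (k < 1L) stopf("each drone group needs at least one drone")
    if (k > nInd(dca)) {
      stopf("DCA exhausted: %d drones requested but only %d left", k, nInd(dca))
    }
    take <- sample.int(nInd(dca), k)
    groups[[g]] <- dca[take]
    dca <- dca[setdiff(seq_len(nInd(dca)), take)]
  }
  list(groups = groups, dca = dca)
}

#' Create a random cross plan
#'
#' Assigns to every virgin queen a disjoint, uniformly sampled set of
#' `nDrones` drone ids from the DCA.
#'
#' @param virginQueenIds character vector of virgin-queen ids.
#' @param dca a `BeePop` of drones.
#' @param nDrones drones per queen.
#' @param simParamBee simulation parameters (default: global).
#' @return A named list (`CrossPlan`): queen id -> drone ids.
#' @export
createRandomCrossPlan <- function(virginQueenIds, dca, nDrones = NULL,
                                  simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  stopifnot(inherits(dca, "BeePop"))
  nDrones <- resolveN(if (is.null(nDrones)) sp$nFathers else nDrones, "nDrones")
  need <- length(virginQueenIds) * nDrones
  if (need > nInd(dca)) {
    stopf("cross plan needs %d drones but the DCA holds %d", need, nInd(dca))
  }
  picked <- sample(dca$id, need)
  plan <- base::split(picked, rep(seq_along(virginQueenIds), each = nDrones))
  names(plan) <- as.character(virginQueenIds)
  structure(plan, class = "CrossPlan")
}

#' Mate virgin queens
#'
#' Mates each target virgin queen to a group of drones. The virgin queen is
#' promoted to a queen (caste transition) and can lay eggs; the mated drones
#' become fathers, die, and are stored in her spermatheca. A colony's
#' virgin-queen slot is emptied by a successful cross; a queen can never be
#' crossed again, and a drone can never mate twice.
#'
#' @param x a `Colony` (one of its virgin queens is mated; any others are
#'   removed), a `BeePop` of virgin queens, or a `MultiColony`.
#' @param drones a `BeePop` of drones (single target), or a list of drone
#'   groups (one per target).
#' @param crossPlan a `CrossPlan` mapping virgin-queen ids to drone ids; the
#'   drones are then taken from `dca`.
#' @param dca drone `BeePop` backing `crossPlan`.
#' @param simParamBee simulation parameters (default: global).
#' @return The mated object: `Colony`, list of queen/fathers pairs, or
#'   `MultiColony`.
#' @export
cross <- function(x, ...) UseMethod("cross")

# Mate one virgin queen to one drone group; registry transitions included.
#' @noRd
mateOne <- function(vq, drones, sp) {
  if (nInd(drones) == 0L) stopf("cannot mate a virgin queen to an empty drone group")
  if (!all(isVirginQueen(vq, sp))) stopf("only an unmated virgin queen can be crossed")
  casteD <- getCaste(drones, sp)
  if (any(casteD != "drone")) {
    stopf("drone group contains already mated (father) or non-drone individuals")
  }
  transitionCaste(sp, vq$id, "queen")
  transitionCaste(sp, drones$id, "father")
  list(queen = vq, fathers = drones)
}

#' @rdname cross
#' @export
cross.BeePop <- function(x, drones = NULL, crossPlan = NULL, dca = NULL,
                         simParamBee = NULL, ...) {
  sp <- getSimParamBee(simParamBee)
  if (!is.null(crossPlan)) {
    stopifnot(inherits(dca, "BeePop"))
    drones <- lapply(x$id, function(id) {
      ids <- crossPlan[[id]]
      if (is.null(ids)) stopf("cross plan has no entry for virgin queen '%s'", id)
      dca[ids]
    })
  }
  if (inherits(drones, "BeePop")) drones <- list(drones)
  if (length(drones) != nInd(x)) {
    stopf("%d drone groups for %d virgin queens", length(drones), nInd(x))
  }
  lapply(seq_len(nInd(x)), function(i) mateOne(x[i], drones[[i]], sp))
}

#' @rdname cross
#' @export
cross.Colony <- function(x, drones = NULL, crossPlan = NULL, dca = NULL,
                         simParamBee = NULL, ...) {
  sp <- getSimParamBee(simParamBee)
  assertMutable(x)
  if (nInd(x$queen) > 0L) stopf("colony '%s' already has a mated queen", x$id)
  if (nInd(x$virginQueens) == 0L) stopf("colony '%s' has no virgin queen to mate", x$id)
  vq <- x$virginQueens[1L]
  if (!is.null(crossPlan)) {
    stopifnot(inherits(dca, "BeePop"))
    ids <- crossPlan[[vq$id]]
    if (is.null(ids)) stopf("cross plan has no entry for virgin queen '%s'", vq$id)
    drones <- dca[ids]
  }
  mated <- mateOne(vq, drones, sp)
  x$queen <- mated$queen
  x$fathers <- mated$fathers
  x$virginQueens <- newBeePop()
  x
}

#' @rdname cross
#' @export
cross.MultiColony <- function(x, drones = NULL, crossPlan = NULL, dca = NULL,
                              simParamBee = NULL, ...) {
  nc <- nColonies(x)
  if (is.null(crossPlan)) {
    if (!is.list(drones) || length(drones) != nc) {
      stopf("provide a list of %d drone groups (one per colony)", nc)
    }
  }
  res <- lapply(seq_len(nc), function(i) {
    cl <- x$colonies[[i]]
    if (is.null(cl)) stopf("NULL colony slot %d", i)
    cross.Colony(cl, drones = if (is.null(crossPlan)) drones[[i]],
                 crossPlan = crossPlan, dca = dca, simParamBee = simParamBee)
  })
  createMultiColony(res)
}
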