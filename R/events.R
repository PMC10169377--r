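# Colony events: build-up, swarming, splitting, supersedure, collapse,
# downsizing, combining, requeening.
#
# Worker shares are rounded with round(), i.e. round-half-to-even, which is
# deterministic and unbiased. Where an event creates virgin queens they are
# daughters of the (departing or removed) queen, csd-filtered like any brood.

#' Build up a colony
#'
#' Creates brood to bring the worker and drone populations up to the target
#' counts (top-up semantics: nothing is removed, and a second call with the
#' same targets adds nothing). Building up always switches the colony to
#' productive.
#'
#' @param x a `Colony` (or `MultiColony`) with a mated queen, not collapsed.
#' @param nWorkers,nDrones target counts (or samplers); defaults from the
#'   simulation parameters.
#' @param simParamBee simulation parameters (default: global).
#' @param ... passed to methods.
#' @return The built-up object.
#' @export
buildUp <- function(x, ...) UseMethod("buildUp")

#' @rdname buildUp
#' @export
buildUp.Colony <- function(x, nWorkers = NULL, nDrones = NULL,
                           simParamBee = NULL, ...) {
  sp <- getSimParamBee(simParamBee)
  assertMutable(x)
  if (nInd(x$queen) == 0L) stopf("cannot build up a colony without a mated queen")
  targetW <- resolveN(if (is.null(nWorkers)) sp$nWorkers else nWorkers, "nWorkers")
  targetD <- resolveN(if (is.null(nDrones)) sp$nDrones else nDrones, "nDrones")
  needW <- max(0L, targetW - nWorkers(x))
  needD <- max(0L, targetD - nDrones(x))
  if (needW > 0L) x$workers <- c(x$workers, createWorkers(x, needW, sp)$workers)
  if (needD > 0L) x$drones <- c(x$drones, createDrones(x, needD, sp))
  x$productive <- TRUE
  x
}

#' Swarm a colony
#'
#' The old queen leaves with a proportion `p` of the workers (the swarm);
#' the remnant keeps the remaining workers, all drones, and freshly reared
#' virgin queens that are daughters of the departed queen. Both resulting
#' colonies are non-productive and flagged as swarmed. The swarm keeps the
#' original colony id (identity follows the queen); the remnant gets a
#' fresh id.
#'
#' @param x a `Colony` (or `MultiColony`) with a queen, not collapsed.
#' @param p proportion of workers leaving (number or proportion sampler);
#'   default `swarmP` from the simulation parameters.
#' @param nVirginQueens number of virgin queens reared in the remnant;
#'   default from the simulation parameters.
#' @param simParamBee simulation parameters (default: global).
#' @param ... passed to methods.
#' @return A list with `swarm` and `remnant`.
#' @export
swarm <- function(x, ...) UseMethod("swarm")

#' @rdname swarm
#' @export
swarm.Colony <- function(x, p = NULL, nVirginQueens = NULL,
                         simParamBee = NULL, ...) {
  sp <- getSimParamBee(simParamBee)
  assertMutable(x)
  if (nInd(x$queen) == 0L) stopf("cannot swarm a queenless colony")
  p <- resolveP(if (is.null(p)) sp$swarmP else p, strength = nWorkers(x))
  nLeave <- as.integer(round(p * nWorkers(x)))
  # virgin queens are daughters of the queen that swarms
  vq <- createVirginQueens(x, nVirginQueens, sp)
  moved <- pullCastePop(x, "workers", nLeave)
  swarmCol <- x
  swarmCol$workers <- moved$pulled
  swarmCol$drones <- newBeePop()
  swarmCol$virginQueens <- newBeePop()
  remnant <- moved$colony
  remnant$id <- newColonyId(sp)
  remnant$queen <- newBeePop(); remnant$fathers <- newBeePop()
  remnant$virginQueens <- vq
  swarmCol$swarmed <- remnant$swarmed <- TRUE
  swarmCol$productive <- remnant$productive <- FALSE
  list(swarm = swarmCol, remnant = remnant)
}

#' Split a colony
#'
#' A beekeeper removes a proportion `p` of the workers to start a new hive
#' (the split), which also receives freshly reared virgin queens (daughters
#' of the queen); the remnant keeps the queen, the remaining workers, and
#' all drones. The split is non-productive; the remnant's production status
#' is unchanged. The remnant keeps the colony id (the queen's side).
#'
#' @param x a `Colony` (or `MultiColony`) with a queen, not collapsed.
#' @param p proportion of workers removed; default `splitP`.
#' @inheritParams swarm
#' @return A list with `split` and `remnant`.
#' @export
split.Colony <- function(x, p = NULL, nVirginQueens = NULL,
                         simParamBee = NULL, ...) {
  sp <- getSimParamBee(simParamBee)
  assertMutable(x)
  if (nInd(x$queen) == 0L) stopf("cannot split a queenless colony")
  p <- resolveP(if (is.null(p)) sp$splitP else p, strength = nWorkers(x))
  nTake <- as.integer(round(p * nWorkers(x)))
  vq <- createVirginQueens(x, nVirginQueens, sp)
  moved <- pullCastePop(x, "workers", nTake)
  remnant <- moved$colony
  splitCol <- createColony(simParamBee = sp)
  splitCol$workers <- moved$pulled
  splitCol$virginQueens <- vq
  splitCol$split <- remnant$split <- TRUE
  splitCol$productive <- FALSE
  list(split = splitCol, remnant = remnant)
}

#' Supersede a colony's queen
#'
#' The queen dies (is removed) and the colony rears new virgin queens from
#' her brood. The colony remains productive — the workers are still present
#' and working.
#'
#' @param x a `Colony` (or `MultiColony`) with a queen, not collapsed.
#' @inheritParams swarm
#' @return The modified object.
#' @export
supersede <- function(x, ...) UseMethod("supersede")

#' @rdname supersede
#' @export
supersede.Colony <- function(x, nVirginQueens = NULL, simParamBee = NULL, ...) {
  sp <- getSimParamBee(simParamBee)
  assertMutable(x)
  if (nInd(x$queen) == 0L) stopf("cannot supersede a queenless colony")
  vq <- createVirginQueens(x, nVirginQueens, sp)
  x$queen <- newBeePop(); x$fathers <- newBeePop()
  x$virginQueens <- c(x$virginQueens, vq)
  x$superseded <- TRUE
  x
}

#' Collapse a colony
#'
#' Marks the colony as collapsed and non-productive. All individuals are
#' kept (so the genetic make-up of failed colonies can be studied), but any
#' further mutating operation on the colony is an error.
#'
#' @param x a `Colony` (or `MultiColony`), not already collapsed.
#' @param ... passed to methods.
#' @return The collapsed object.
#' @export
collapse <- function(x, ...) UseMethod("collapse")

#' @rdname collapse
#' @export
collapse.Colony <- function(x, ...) {
  if (isTRUE(x$collapsed)) stopf("colony '%s' has already collapsed", x$id)
  x$collapsed <- TRUE
  x$productive <- FALSE
  x
}

#' Downsize a colony
#'
#' Removes a proportion `p` of the workers and all drones and virgin queens
#' (wintering preparation). The queen is retained; the colony becomes
#' non-productive.
#'
#' @param x a `Colony` (or `MultiColony`), not collapsed.
#' @param p proportion of workers removed; default `downsizeP`.
#' @inheritParams swarm
#' @return The downsized object.
#' @export
downsize <- function(x, ...) UseMethod("downsize")

#' @rdname downsize
#' @export
downsize.Colony <- function(x, p = NULL, simParamBee = NULL, ...) {
  sp <- getSimParamBee(simParamBee)
  assertMutable(x)
  p <- resolveP(if (is.null(p)) sp$downsizeP else p, strength = nWorkers(x))
  nDrop <- as.integer(round(p * nWorkers(x)))
  x <- pullCastePop(x, "workers", nDrop)$colony
  x$drones <- newBeePop()
  x$virginQueens <- newBeePop()
  x$productive <- FALSE
  x
}

#' Combine two colonies
#'
#' A beekeeping intervention that merges a weak colony into a strong one:
#' the strong colony gains the weak colony's workers and drones and keeps
#' its own queen, id, and flags. The weak colony's queen is discarded.
#'
#' @param strong,weak `Colony` objects; neither may be collapsed.
#' @return The combined `Colony`.
#' @export
combine <- function(strong, weak) {
  stopifnot(inherits(strong, "Colony"), inherits(weak, "Colony"))
  assertMutable(strong); assertMutable(weak)
  strong$workers <- c(strong$workers, weak$workers)
  strong$drones <- c(strong$drones, weak$drones)
  strong
}

#' Requeen a colony
#'
#' Installs a new head female, removing the existing queen (if any). With a
#' mated queen (plus her `fathers`) the colony's virgin queens are also
#' cleared — the new queen would kill them; with a virgin queen the colony
#' becomes queenless with that single virgin queen awaiting [cross()].
#'
#' @param x a `Colony` (or `MultiColony`), not collapsed.
#' @param queen a `BeePop` of one: a queen or a virgin queen.
#' @param fathers the mated queen's stored fathers.
#' @inheritParams swarm
#' @return The requeened object.
#' @export
reQueen <- function(x, ...) UseMethod("reQueen")

#' @rdname reQueen
#' @export
reQueen.Colony <- function(x, queen, fathers = NULL, simParamBee = NULL, ...) {
  sp <- getSimParamBee(simParamBee)
  assertMutable(x)
  stopifnot(inherits(queen, "BeePop"))
  if (nInd(queen) != 1L) stopf("provide exactly one new queen")
  caste <- getCaste(queen, sp)
  if (caste == "queen") {
    if (is.null(fathers) || nInd(fathers) == 0L) {
      stopf("a mated queen must come with her stored fathers")
    }
    x$queen <- queen; x$fathers <- fathers
    x$virginQueens <- newBeePop()
  } else if (caste == "virginQueen") {
    x$queen <- newBeePop(); x$fathers <- newBeePop()
    x$virginQueens <- queen
  } else stopf("cannot requeen with a %s", caste)
  x
}
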