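# Creating caste individuals: virgin queens, workers, drones.

# Build a BeePop from survivor eggs, registering ids, caste, and pedigree.
#' @noRd
broodToPop <- function(survivors, caste, motherId, sp) {
  n <- length(survivors$genomes)
  ids <- registerInd(sp, n, caste, mother = motherId, father = survivors$fatherId)
  newBeePop(ids, rep(motherId, n), survivors$fatherId, rep(2L, n),
            lapply(survivors$genomes, `[[`, "haplo"),
            lapply(survivors$genomes, `[[`, "ibd"))
}

#' Create virgin queens
#'
#' From founder genomes, creates the base population of virgin queens: one
#' per founder, each carrying two meiotic gametes of that founder's diploid
#' genome (the second redrawn so the two csd words differ — base virgin
#' queens are viable females by construction). Founder csd alleles are
#' edited first (see [editCsdAlleles()]) if that has not been done yet.
#'
#' From a colony, creates daughter virgin queens of the colony queen and her
#' stored fathers; csd-homozygous brood is removed, so fewer than `nInd`
#' individuals may be returned.
#'
#' @param x a `FounderGenomes` object or a `Colony` with a mated queen.
#' @param nInd number of virgin queens (or a count sampler). From founders
#'   the maximum is the number of founder individuals; from a colony this is
#'   the number of fertilised eggs before csd filtering. Default: the
#'   founder count, or `nVirginQueens` from the simulation parameters.
#' @param simParamBee simulation parameters (default: global).
#' @return A `BeePop` of virgin queens.
#' @examples
#' founders <- simulateFounderGenomes(nCar = 6, nChr = 1, nSegSites = 30)
#' SP <- newSimParamBee(founders, nCsdAlleles = 8, seed = 1)
#' vq <- createVirginQueens(founders)
#' isVirginQueen(vq)
#' @export
createVirginQueens <- function(x, nInd = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  if (inherits(x, "FounderGenomes")) {
    n <- resolveN(if (is.null(nInd)) x$nInd else nInd, "nInd")
    if (n > x$nInd) {
      stopf("cannot create %d base virgin queens from %d founders", n, x$nInd)
    }
    if (!x$csdEdited) {
      x <- editCsdAlleles(x, simParamBee = sp)
      sp$founders <- x
    }
    csd <- sp$genome$csd
    ids <- registerInd(sp, n, "virginQueen")
    haplo <- vector("list", n); ibd <- vector("list", n)
    for (i in seq_len(n)) {
      g <- founderGenome(x, i)
      g1 <- gameteFrom(g$haplo, g$ibd, sp$genome)
      for (try in 1:100) {
        g2 <- gameteFrom(g$haplo, g$ibd, sp$genome)
        if (csdWordsOf(g1$haplo, csd) != csdWordsOf(g2$haplo, csd)) break
      }
      z <- zygote(g1, g2)
      haplo[[i]] <- z$haplo; ibd[[i]] <- z$ibd
    }
    return(newBeePop(ids, ploidy = rep(2L, n), haplo = haplo, ibd = ibd))
  }
  if (inherits(x, "Colony")) {
    assertMutable(x)
    if (nInd(x$queen) == 0L) stopf("colony has no mated queen")
    n <- resolveN(if (is.null(nInd)) sp$nVirginQueens else nInd, "nInd")
    eggs <- makeEggs(x$queen, x$fathers, n, sp)
    kept <- filterCsdViable(eggs, x$queen, sp)
    return(broodToPop(kept$survivors, "virginQueen", x$queen$id[1L], sp))
  }
  stopf("'x' must be FounderGenomes or a Colony")
}

#' Create drones
#'
#' Drones develop from unfertilised eggs: each drone genome is a single
#' meiotic gamete of its mother, so drones are haploid, have no father, and
#' are not csd-filtered (haploids cannot be csd-homozygous). The mother can
#' be a virgin queen (to kick-start a simulation before any queen exists) or
#' the mated queen of a colony.
#'
#' @param x a `BeePop` of one or more virgin queens / queens, or a `Colony`
#'   with a queen.
#' @param nInd drones per mother (count or sampler); default `nDrones` from
#'   the simulation parameters.
#' @param simParamBee simulation parameters (default: global).
#' @return A `BeePop` of haploid drones (pooled across mothers).
#' @export
createDrones <- function(x, nInd = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  if (inherits(x, "Colony")) {
    assertMutable(x)
    if (nInd(x$queen) == 0L) stopf("colony has no mated queen")
    mothers <- x$queen
  } else if (inherits(x, "BeePop")) {
    mothers <- x
    caste <- getCaste(mothers, sp)
    if (!all(caste %in% c("virginQueen", "queen"))) {
      stopf("drones can only be created from virgin queens or queens")
    }
  } else stopf("'x' must be a BeePop or a Colony")
  if (nInd(mothers) == 0L) stopf("no mother provided")
  pops <- lapply(seq_len(nInd(mothers)), function(i) {
    n <- resolveN(if (is.null(nInd)) sp$nDrones else nInd, "nInd")
    ids <- registerInd(sp, n, "drone", mother = mothers$id[i])
    gam <- lapply(seq_len(n), function(e) {
      gameteFrom(mothers$haplo[[i]], mothers$ibd[[i]], sp$genome)
    })
    newBeePop(ids, mother = rep(mothers$id[i], n), ploidy = rep(1L, n),
              haplo = lapply(gam, `[[`, "haplo"),
              ibd = lapply(gam, `[[`, "ibd"))
  })
  do.call(c, c(pops, list(newBeePop())))
}

#' Create workers
#'
#' Forms `nInd` fertilised eggs from the colony queen and her stored fathers
#' (the father of each egg sampled uniformly from the spermatheca), removes
#' csd-homozygous zygotes, and returns the surviving diploid workers. The
#' queen's cumulative homozygous-brood count is updated (see [nHomBrood()]);
#' the brood is not topped up, so fewer than `nInd` workers may come back.
#'
#' @param x a `Colony` with a mated queen.
#' @param nInd number of eggs (count or sampler); default `nWorkers` from
#'   the simulation parameters.
#' @param simParamBee simulation parameters (default: global).
#' @return A list with `workers` (a `BeePop`) and `nRemoved`.
#' @export
createWorkers <- function(x, nInd = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  stopifnot(inherits(x, "Colony"))
  assertMutable(x)
  if (nInd(x$queen) == 0L) stopf("colony has no mated queen")
  n <- resolveN(if (is.null(nInd)) sp$nWorkers else nInd, "nInd")
  eggs <- makeEggs(x$queen, x$fathers, n, sp)
  kept <- filterCsdViable(eggs, x$queen, sp)
  list(workers = broodToPop(kept$survivors, "worker", x$queen$id[1L], sp),
       nRemoved = kept$nRemoved)
}

# --- caste predicates ------------------------------------------------------

#' Check caste membership
#'
#' `checkCaste()` returns, for each individual, whether it currently belongs
#' to the given caste; `isQueen()`, `isVirginQueen()`, `isWorker()`,
#' `isDrone()` and `isFather()` are shorthands.
#'
#' @param x a `BeePop` or character vector of ids.
#' @param caste one of `"queen"`, `"father"`, `"worker"`, `"drone"`,
#'   `"virginQueen"`.
#' @param simParamBee simulation parameters (default: global).
#' @return Logical vector in input order.
#' @export
checkCaste <- function(x, caste, simParamBee = NULL) {
  caste <- match.arg(caste, c("queen", "father", "worker", "drone", "virginQueen"))
  getCaste(x, simParamBee) == caste
}

#' @rdname checkCaste
#' @export
isQueen <- function(x, simParamBee = NULL) checkCaste(x, "queen", simParamBee)

#' @rdname checkCaste
#' @export
isVirginQueen <- function(x, simParamBee = NULL) checkCaste(x, "virginQueen", simParamBee)

#' @rdname checkCaste
#' @export
isWorker <- function(x, simParamBee = NULL) checkCaste(x, "worker", simParamBee)

#' @rdname checkCaste
#' @export
isDrone <- function(x, simParamBee = NULL) checkCaste(x, "drone", simParamBee)

#' @rdname checkCaste
#' @export
isFather <- function(x, simParamBee = NULL) checkCaste(x, "father", simParamBee)
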