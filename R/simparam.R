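# SimParamBee: global simulation parameters and registries.
#
# A single mutable object (an environment) holds everything shared across a
# simulation: the genome specification with the csd window, caste-size and
# event-proportion defaults, the trait architecture, the global caste
# registry and pedigree, and the id counter. One SimParamBee is registered as
# the active global context so functions can omit the argument, mirroring
# common usage; explicit passing is always possible.

#' Create global simulation parameters
#'
#' Sets up a `SimParamBee` object from simulated or imported founder genomes
#' and registers it as the active global context. The csd locus is placed as
#' a window of `log2(nCsdAlleles)` consecutive tracked sites on `csdChr`; the
#' window receives zero internal genetic width so that its sites are always
#' co-inherited and an individual's csd allele is the 0/1 word read along the
#' window.
#'
#' Default caste sizes describe a deliberately small demonstration colony
#' (100 workers, 10 drones); real colonies are orders of magnitude larger and
#' all defaults are configurable, including by samplers from
#' [makeCountSampler()] / [makeProportionSampler()].
#'
#' @param founders a `FounderGenomes` object.
#' @param nWorkers default full-size colony worker count.
#' @param nDrones default colony drone count.
#' @param nVirginQueens default number of virgin queens reared after
#'   swarming, splitting, or supersedure.
#' @param nFathers default number of drones a queen mates with.
#' @param swarmP default proportion of workers leaving with a swarm.
#' @param splitP default proportion of workers removed in a split.
#' @param downsizeP default proportion of workers removed at downsizing.
#' @param csdChr chromosome carrying the csd locus (default chromosome 3,
#'   its position in the real genome, or chromosome 1 for smaller genomes).
#' @param csdPos relative position of the csd window along the chromosome's
#'   tracked sites, in `[0, 1]`.
#' @param nCsdAlleles number of possible csd alleles; must be a power of two
#'   `>= 2` (the window has `log2(nCsdAlleles)` biallelic sites).
#' @param seed optional integer seed; if given, R's RNG is seeded so the
#'   whole simulation trace is reproducible.
#' @return A `SimParamBee` object (also registered globally).
#' @examples
#' founders <- simulateFounderGenomes(nCar = 4, nChr = 1, nSegSites = 30)
#' SP <- newSimParamBee(founders, nCsdAlleles = 8, seed = 42)
#' SP
#' @export
newSimParamBee <- function(founders,
                           nWorkers = 100, nDrones = 10, nVirginQueens = 10,
                           nFathers = 15,
                           swarmP = 0.5, splitP = 0.3, downsizeP = 0.85,
                           csdChr = NULL, csdPos = 0.5, nCsdAlleles = 128,
                           seed = NULL) {
  stopifnot(inherits(founders, "FounderGenomes"))
  if (!isPowerOfTwo(nCsdAlleles) || nCsdAlleles < 2) {
    stopf("'nCsdAlleles' must be a power of two >= 2, got %s", format(nCsdAlleles))
  }
  for (p in c(swarmP = swarmP, splitP = splitP, downsizeP = downsizeP)) {
    if (p <= 0 || p >= 1) stopf("event proportions must lie strictly within (0, 1)")
  }
  spec <- founders$genome
  if (is.null(csdChr)) csdChr <- if (spec$nChr >= 3L) 3L else 1L
  if (csdChr < 1L || csdChr > spec$nChr) {
    stopf("'csdChr' (%d) outside the genome (%d chromosomes)", csdChr, spec$nChr)
  }
  len <- as.integer(log2(nCsdAlleles))
  nSites <- nLoci(spec, csdChr)
  if (nSites < len) {
    stopf("chromosome %d has %d sites; csd window needs %d", csdChr, nSites, len)
  }
  if (csdPos < 0 || csdPos > 1) stopf("'csdPos' must lie within [0, 1]")
  start <- 1L + as.integer(round(csdPos * (nSites - len)))
  spec$csd <- list(chr = as.integer(csdChr), start = start, len = len,
                   nAlleles = as.integer(nCsdAlleles))
  # zero internal genetic width: the window is inherited as one block
  win <- start:(start + len - 1L)
  spec$mapPos[[csdChr]][win] <- spec$mapPos[[csdChr]][win[1L]]

  if (!is.null(seed)) set.seed(as.integer(seed))
  sp <- new.env(parent = emptyenv())
  sp$genome <- spec
  sp$founders <- founders
  sp$nWorkers <- nWorkers; sp$nDrones <- nDrones
  sp$nVirginQueens <- nVirginQueens; sp$nFathers <- nFathers
  sp$swarmP <- swarmP; sp$splitP <- splitP; sp$downsizeP <- downsizeP
  sp$seed <- seed
  sp$lastId <- 0L
  sp$lastColonyId <- 0L
  sp$caste <- new.env(parent = emptyenv())     # id -> caste label
  sp$ped <- new.env(parent = emptyenv())       # id -> c(mother, father)
  sp$homBrood <- new.env(parent = emptyenv())  # queen id -> cumulative count
  sp$traits <- NULL
  sp$snpChip <- NULL
  class(sp) <- "SimParamBee"
  .pkg$SP <- sp
  sp
}

#' Resolve the active simulation parameters
#'
#' Returns the explicitly supplied `SimParamBee`, or the globally registered
#' one created by the last [newSimParamBee()] call.
#'
#' @param simParamBee a `SimParamBee` or `NULL` (use the global one).
#' @return A `SimParamBee` object.
#' @export
getSimParamBee <- function(simParamBee = NULL) {
  sp <- if (is.null(simParamBee)) .pkg$SP else simParamBee
  if (is.null(sp)) stopf("no SimParamBee found; create one with newSimParamBee()")
  stopifnot(inherits(sp, "SimParamBee"))
  sp
}

#' @exportS3Method base::print
print.SimParamBee <- function(x, ...) {
  cat("SimParamBee\n")
  fmt <- function(v) if (is.function(v)) "<sampler>" else format(v)
  cat(sprintf("  defaults: nWorkers=%s nDrones=%s nVirginQueens=%s nFathers=%s\n",
              fmt(x$nWorkers), fmt(x$nDrones),
              fmt(x$nVirginQueens), fmt(x$nFathers)))
  cat(sprintf("  proportions: swarmP=%.2f splitP=%.2f downsizeP=%.2f\n",
              x$swarmP, x$splitP, x$downsizeP))
  csd <- x$genome$csd
  cat(sprintf("  csd: chr %d, %d sites (%d alleles)\n", csd$chr, csd$len,
              csd$nAlleles))
  cat("  individuals registered:", x$lastId, "\n")
  cat("  traits:", if (is.null(x$traits)) "none" else x$traits$nTraits, "\n")
  invisible(x)
}

# --- id, caste registry and pedigree -------------------------------------

# Allocate n fresh individual ids and register caste + parents.
#' @noRd
registerInd <- function(sp, n, caste, mother = NA_character_,
                        father = NA_character_) {
  ids <- as.character(sp$lastId + seq_len(n))
  sp$lastId <- sp$lastId + as.integer(n)
  mother <- rep_len(mother, n); father <- rep_len(father, n)
  for (i in seq_len(n)) {
    assign(ids[i], caste, envir = sp$caste)
    assign(ids[i], c(mother[i], father[i]), envir = sp$ped)
  }
  ids
}

# Caste transitions are restricted: a virgin queen may become a queen and a
# drone may become a father; nothing else ever changes caste.
#' @noRd
transitionCaste <- function(sp, ids, to) {
  allowed <- c(queen = "virginQueen", father = "drone")
  for (id in ids) {
    cur <- get0(id, envir = sp$caste, inherits = FALSE)
    if (is.null(cur)) stopf("unknown individual id '%s'", id)
    if (!identical(cur, unname(allowed[to]))) {
      stopf("caste transition %s -> %s not allowed for individual '%s'", cur, to, id)
    }
    assign(id, to, envir = sp$caste)
  }
  invisible(ids)
}

#' Get the caste of individuals
#'
#' Looks up the current caste label (`queen`, `father`, `worker`, `drone`, or
#' `virginQueen`) of each individual in the global registry. Castes change
#' only at mating: a virgin queen becomes a queen and mated drones become
#' fathers.
#'
#' @param x a `BeePop` or a character vector of individual ids.
#' @param simParamBee simulation parameters (default: global).
#' @return Character vector of caste labels, in input order.
#' @export
getCaste <- function(x, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  ids <- if (inherits(x, "BeePop")) x$id else as.character(x)
  vapply(ids, function(id) {
    v <- get0(id, envir = sp$caste, inherits = FALSE)
    if (is.null(v)) stopf("unknown individual id '%s'", id)
    v
  }, "", USE.NAMES = FALSE)
}

#' Export the global pedigree
#'
#' @param simParamBee simulation parameters (default: global).
#' @return A data.frame with columns `id`, `mother`, `father`, ordered by id.
#' @export
getPedigree <- function(simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  ids <- ls(sp$ped)
  ids <- ids[order(as.numeric(ids))]
  ped <- t(vapply(ids, function(id) get(id, envir = sp$ped), character(2)))
  data.frame(id = ids, mother = unname(ped[, 1]), father = unname(ped[, 2]),
             caste = getCaste(ids, sp), row.names = NULL)
}
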