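# Meiosis and gamete formation under the haplodiploid system.
#
# Queens and workers are proper diploids; drones are haploid and their sperm
# is clonal (one meiosis-free genome copy). Crossovers follow the Haldane
# model: per chromosome a Poisson number of crossovers with mean equal to the
# chromosome's genetic length in Morgans, positions uniform on the genetic
# map, no interference and no obligate chiasma. Because the csd window has
# zero genetic width, its sites always travel together.

# One gamete (alleles + ibd labels per chromosome) from a diploid genome
# given as lists of 2 x nSites matrices.
#' @noRd
gameteFrom <- function(haplo, ibd, spec) {
  nChr <- spec$nChr
  al <- vector("list", nChr)
  lab <- vector("list", nChr)
  for (c in seq_len(nChr)) {
    map <- spec$mapPos[[c]]
    glen <- spec$genLength[c]
    start <- sample.int(2L, 1L)
    ncx <- stats::rpois(1L, lambda = glen)
    if (ncx == 0L) {
      rows <- rep(start, length(map))
    } else {
      cx <- sort(stats::runif(ncx, 0, glen))
      seg <- findInterval(map, cx)
      rows <- (start + seg - 1L) %% 2L + 1L
    }
    idx <- cbind(rows, seq_along(map))
    al[[c]] <- matrix(haplo[[c]][idx], nrow = 1L)
    lab[[c]] <- matrix(ibd[[c]][idx], nrow = 1L)
  }
  list(haplo = al, ibd = lab)
}

#' Sample a meiotic gamete from a diploid individual
#'
#' Recombines and segregates one individual's two genomes into a single
#' gamete, tracking founder-haplotype origin (identity by descent) through
#' crossovers. Haploid drones are rejected; their clonal sperm is produced by
#' [droneGamete()].
#'
#' @param pop a `BeePop`.
#' @param i index or id of the (diploid) parent within `pop`.
#' @param simParamBee simulation parameters (default: global).
#' @return A list with `haplo` and `ibd`: per chromosome a `1 x nSites`
#'   matrix of alleles / founder labels.
#' @export
meiosis <- function(pop, i = 1L, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  stopifnot(inherits(pop, "BeePop"))
  if (is.character(i)) i <- match(i, pop$id)
  if (pop$ploidy[i] != 2L) stopf("meiosis requires a diploid parent; use droneGamete() for drones")
  gameteFrom(pop$haplo[[i]], pop$ibd[[i]], sp$genome)
}

#' Clonal gamete of a haploid drone
#'
#' Drone sperm carries an exact copy of the drone's single genome (drones
#' arise from unfertilised eggs and produce genetically identical sperm), so
#' the gamete is the drone genome itself, ibd labels included.
#'
#' @inheritParams meiosis
#' @return A gamete as in [meiosis()].
#' @export
droneGamete <- function(pop, i = 1L, simParamBee = NULL) {
  stopifnot(inherits(pop, "BeePop"))
  if (is.character(i)) i <- match(i, pop$id)
  if (pop$ploidy[i] != 1L) stopf("droneGamete() requires a haploid drone")
  list(haplo = pop$haplo[[i]], ibd = pop$ibd[[i]])
}

# Diploid genome from two gametes.
#' @noRd
zygote <- function(motherGamete, fatherGamete) {
  list(haplo = Map(rbind, motherGamete$haplo, fatherGamete$haplo),
       ibd = Map(rbind, motherGamete$ibd, fatherGamete$ibd))
}

# Founder individual i as a diploid genome (haplotype rows 2i-1, 2i), with
# ibd labels equal to the founder haplotype numbers.
#' @noRd
founderGenome <- function(founders, i) {
  rows <- c(2L * i - 1L, 2L * i)
  list(
    haplo = lapply(founders$haplo, function(h) h[rows, , drop = FALSE]),
    ibd = lapply(founders$haplo, function(h) {
      matrix(rep(rows, ncol(h)), nrow = 2L)
    })
  )
}

# ---------------------------------------------------------------------------
# csd founder editing

#' Edit founder csd alleles
#'
#' Overwrites the csd-window haplotypes of the founders so that the
#' population carries the desired number of csd alleles at (as far as integer
#' counts allow) uniform frequencies — emulating the allelic richness that
#' balancing selection maintains at the real locus. Allele words are assigned
#' round-robin across haplotypes from a complement-closed set of distinct 0/1
#' words, so that every founder is csd-heterozygous and every window site
#' stays segregating.
#'
#' @param founders a `FounderGenomes` object.
#' @param nCsdAlleles number of distinct alleles to install; defaults to the
#'   `nCsdAlleles` of the simulation parameters. Must be at least 2 and at
#'   most `2^windowLength`. If it exceeds the number of founder haplotypes a
#'   warning is issued (not all alleles can be represented).
#' @param simParamBee simulation parameters (default: global).
#' @return The edited `FounderGenomes`.
#' @export
editCsdAlleles <- function(founders, nCsdAlleles = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  stopifnot(inherits(founders, "FounderGenomes"))
  csd <- sp$genome$csd
  if (is.null(csd)) stopf("no csd window defined in the simulation parameters")
  if (is.null(nCsdAlleles)) nCsdAlleles <- csd$nAlleles
  L <- csd$len
  if (nCsdAlleles < 2) stopf("'nCsdAlleles' must be at least 2")
  if (nCsdAlleles > 2^L) {
    stopf("'nCsdAlleles' (%d) exceeds the %d words a %d-site window can encode",
          nCsdAlleles, 2^L, L)
  }
  nHap <- 2L * founders$nInd
  if (nCsdAlleles > nHap) {
    warnf("%d csd alleles requested but only %d founder haplotypes exist; not all alleles will be represented",
          nCsdAlleles, nHap)
  }
  words <- csdWordSet(nCsdAlleles, L)
  win <- csd$start:(csd$start + L - 1L)
  h <- founders$haplo[[csd$chr]]
  idx <- (seq_len(nHap) - 1L) %% nCsdAlleles + 1L
  h[, win] <- words[idx, , drop = FALSE]
  founders$haplo[[csd$chr]] <- h
  founders$csdEdited <- TRUE
  founders
}

# A set of n distinct L-bit words in which every bit position segregates.
# For the full space, all words; otherwise a complement-closed random set
# (each word paired with its bitwise complement), which guarantees both
# alleles at every window site. Consecutive words in the returned order are
# always distinct, so round-robin assignment keeps founders heterozygous.
#' @noRd
csdWordSet <- function(n, L) {
  toBits <- function(v) {
    matrix(vapply(v, function(x) as.integer(intToBits(x)[seq_len(L)]),
                  integer(L)),
           ncol = L, byrow = TRUE)
  }
  if (n == 2^L) return(toBits(0:(2^L - 1L)))
  full <- 2L^L
  half <- sample.int(full / 2L, ceiling(n / 2)) - 1L  # words with top bit 0
  comp <- (full - 1L) - half                          # bitwise complements
  words <- as.integer(rbind(half, comp))[seq_len(n)]
  toBits(words)
}

# csd word (as a collapsed 0/1 string) for each haplotype row of a genome.
#' @noRd
csdWordsOf <- function(haplo, csd) {
  win <- csd$start:(csd$start + csd$len - 1L)
  apply(haplo[[csd$chr]][, win, drop = FALSE], 1L, paste, collapse = "")
}
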