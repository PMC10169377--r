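# Genomic data extraction and relationship matrices.
#
# Haplotype matrices have one row per haplotype (drones contribute a single
# row); genotype matrices are allele-dosage matrices with drones scored 0/2
# under the doubled-haploid convention, so they stay ploidy-uniform.
# Column labels follow chromosome_locus; haplotype rows individual_haplotype.

# Resolve the target to a BeePop (possibly across a MultiColony).
#' @noRd
targetPop <- function(x, caste, sp) {
  if (inherits(x, "MultiColony")) {
    pops <- lapply(x$colonies, function(cl) {
      if (is.null(cl)) newBeePop() else targetPop(cl, caste, sp)
    })
    return(do.call(c, c(pops, list(newBeePop()))))
  }
  if (inherits(x, "Colony")) {
    if (is.null(caste)) stopf("specify the 'caste' to extract from a colony")
    return(getCastePop(x, caste))
  }
  stopifnot(inherits(x, "BeePop"))
  x
}

# Site index list (per chromosome) for a given view of the genome.
#' @noRd
whichSites <- function(which, sp) {
  spec <- sp$genome
  switch(which,
    segSites = lapply(seq_len(spec$nChr), function(c) seq_len(nLoci(spec, c))),
    qtl = {
      if (is.null(sp$traits)) stopf("no traits defined; QTL are not available")
      sp$traits$qtl
    },
    snp = {
      if (is.null(sp$snpChip)) stopf("no SNP chip defined; call addSnpChip() first")
      sp$snpChip
    },
    stopf("unknown site set '%s'", which)
  )
}

#' @noRd
extractHaplo <- function(pop, sites, sp) {
  if (nInd(pop) == 0L) stopf("no individuals to extract from")
  rows <- lapply(seq_len(nInd(pop)), function(i) {
    do.call(cbind, lapply(seq_along(sites), function(c) {
      pop$haplo[[i]][[c]][, sites[[c]], drop = FALSE]
    }))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- unlist(lapply(seq_len(nInd(pop)), function(i) {
    paste(pop$id[i], seq_len(pop$ploidy[i]), sep = "_")
  }))
  colnames(m) <- unlist(lapply(seq_along(sites), function(c) {
    paste(c, sites[[c]], sep = "_")
  }))
  m
}

#' @noRd
extractGeno <- function(pop, sites, sp) {
  h <- extractHaplo(pop, sites, sp)
  starts <- c(0L, cumsum(pop$ploidy))
  g <- t(vapply(seq_len(nInd(pop)), function(i) {
    rows <- (starts[i] + 1L):starts[i + 1L]
    d <- colSums(h[rows, , drop = FALSE])
    if (pop$ploidy[i] == 1L) d <- 2L * d
    d
  }, numeric(ncol(h))))
  rownames(g) <- pop$id
  colnames(g) <- colnames(h)
  g
}

#' Extract haplotypes and genotypes
#'
#' `getSegSiteHaplo()`/`getSegSiteGeno()` work on all tracked segregating
#' sites, `getQtlHaplo()`/`getQtlGeno()` on the trait QTL, and
#' `getSnpHaplo()`/`getSnpGeno()` on the SNP chip loci (see
#' [addSnpChip()]). All accept a `BeePop`, a `Colony` (with `caste`), or a
#' `MultiColony`.
#'
#' @param x a `BeePop`, `Colony`, or `MultiColony`.
#' @param caste caste slot when `x` is a colony or collection.
#' @param simParamBee simulation parameters (default: global).
#' @return A haplotype (0/1) or genotype dosage (0/1/2; drones 0/2) matrix.
#' @export
getSegSiteHaplo <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  extractHaplo(targetPop(x, caste, sp), whichSites("segSites", sp), sp)
}

#' @rdname getSegSiteHaplo
#' @export
getSegSiteGeno <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  extractGeno(targetPop(x, caste, sp), whichSites("segSites", sp), sp)
}

#' @rdname getSegSiteHaplo
#' @export
getQtlHaplo <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  extractHaplo(targetPop(x, caste, sp), whichSites("qtl", sp), sp)
}

#' @rdname getSegSiteHaplo
#' @export
getQtlGeno <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  extractGeno(targetPop(x, caste, sp), whichSites("qtl", sp), sp)
}

#' @rdname getSegSiteHaplo
#' @export
getSnpHaplo <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  extractHaplo(targetPop(x, caste, sp), whichSites("snp", sp), sp)
}

#' @rdname getSegSiteHaplo
#' @export
getSnpGeno <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  extractGeno(targetPop(x, caste, sp), whichSites("snp", sp), sp)
}

#' Define a SNP chip
#'
#' Samples `nSnpPerChr` marker loci per chromosome uniformly among tracked
#' sites, excluding trait QTL and the csd window, and stores them in the
#' simulation parameters for [getSnpHaplo()]/[getSnpGeno()].
#'
#' @param nSnpPerChr markers per chromosome.
#' @param simParamBee simulation parameters (default: global).
#' @return The modified `SimParamBee`, invisibly.
#' @export
addSnpChip <- function(nSnpPerChr, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  spec <- sp$genome
  chip <- vector("list", spec$nChr)
  for (c in seq_len(spec$nChr)) {
    avail <- seq_len(nLoci(spec, c))
    if (!is.null(sp$traits)) avail <- setdiff(avail, sp$traits$qtl[[c]])
    if (!is.null(spec$csd) && spec$csd$chr == c) {
      avail <- setdiff(avail, spec$csd$start:(spec$csd$start + spec$csd$len - 1L))
    }
    if (nSnpPerChr > length(avail)) {
      stopf("chromosome %d has only %d sites free for %d markers", c,
            length(avail), nSnpPerChr)
    }
    chip[[c]] <- sort(sample(avail, nSnpPerChr))
  }
  sp$snpChip <- chip
  invisible(sp)
}

#' Extract identity-by-descent haplotypes
#'
#' Returns, for every haplotype and tracked site, the founder-haplotype
#' label it descends from (labels `1..2*nFounders`, assigned at founder
#' creation). Breakpoints between labels coincide with crossovers.
#'
#' @inheritParams getSegSiteHaplo
#' @return An integer matrix, rows as in [getSegSiteHaplo()].
#' @export
getIbdHaplo <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  pop <- targetPop(x, caste, sp)
  if (nInd(pop) == 0L) stopf("no individuals to extract from")
  sites <- whichSites("segSites", sp)
  rows <- lapply(seq_len(nInd(pop)), function(i) {
    do.call(cbind, lapply(seq_along(sites), function(c) {
      pop$ibd[[i]][[c]][, sites[[c]], drop = FALSE]
    }))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- unlist(lapply(seq_len(nInd(pop)), function(i) {
    paste(pop$id[i], seq_len(pop$ploidy[i]), sep = "_")
  }))
  colnames(m) <- unlist(lapply(seq_along(sites), function(c) {
    paste(c, sites[[c]], sep = "_")
  }))
  m
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Computes `G = Z Z' / (2 * sum(p * (1 - p)))` where `Z` is the dosage
#' matrix column-centred at twice the allele frequencies `p`. Frequencies
#' are computed from the supplied matrix unless `p` is given (e.g. base
#' population frequencies).
#'
#' @param geno a dosage matrix (individuals x loci, values 0/1/2), e.g. from
#'   [getSegSiteGeno()].
#' @param p optional allele frequencies per locus.
#' @return A symmetric positive semi-definite matrix with individual ids as
#'   dimnames.
#' @export
calcGRM <- function(geno, p = NULL) {
  if (!is.matrix(geno) || nrow(geno) < 2L) {
    stopf("'geno' must be a dosage matrix with at least 2 individuals")
  }
  if (is.null(p)) p <- colMeans(geno) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stopf("all loci are monomorphic; the relationship matrix is undefined")
  Z <- sweep(geno, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  G
}
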