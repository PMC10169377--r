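# Founder genomes: genetic map, structured-coalescent simulation, import.
#
# The honeybee genome is physically small (~250 Mbp over 16 chromosomes) but
# genetically long because of an extreme recombination rate (2.3e-7 per bp
# per meiosis). Tracked loci are abstract biallelic segregating sites; 0 is
# the ancestral and 1 the derived allele.

HONEYBEE_RECOMB_RATE <- 2.3e-7
HONEYBEE_GENOME_BP <- 250e6
HONEYBEE_N_CHR <- 16L

#' Genome specification
#'
#' Builds the genetic map shared by all individuals of a simulation: physical
#' chromosome lengths, tracked site positions, and map positions in Morgans
#' (`bp * recombRate`). The csd window (set later by [newSimParamBee()]) is
#' given zero internal genetic width so its sites never recombine apart.
#'
#' @param nChr number of chromosomes.
#' @param bpLength physical length per chromosome in bp (recycled).
#' @param recombRate expected crossovers per bp per meiosis.
#' @param lociPos list (per chromosome) of strictly increasing bp positions.
#' @return An object of class `GenomeSpec`.
#' @export
newGenomeSpec <- function(nChr, bpLength = HONEYBEE_GENOME_BP / HONEYBEE_N_CHR,
                          recombRate = HONEYBEE_RECOMB_RATE, lociPos) {
  nChr <- as.integer(nChr)
  bpLength <- rep_len(as.numeric(bpLength), nChr)
  if (length(lociPos) != nChr) stopf("'lociPos' must have one element per chromosome")
  for (c in seq_len(nChr)) {
    pos <- lociPos[[c]]
    if (any(diff(pos) <= 0)) stopf("site positions must be strictly increasing (chromosome %d)", c)
    if (any(pos < 0 | pos > bpLength[c])) stopf("site positions outside chromosome %d", c)
  }
  mapPos <- lapply(seq_len(nChr), function(c) lociPos[[c]] * recombRate)
  structure(
    list(nChr = nChr, bpLength = bpLength, recombRate = recombRate,
         lociPos = lociPos, mapPos = mapPos,
         genLength = bpLength * recombRate, csd = NULL),
    class = "GenomeSpec"
  )
}

#' @exportS3Method base::print
print.GenomeSpec <- function(x, ...) {
  cat("Genome specification\n")
  cat("  chromosomes:", x$nChr, "\n")
  cat("  sites/chr:  ", paste(vapply(x$lociPos, length, 1L), collapse = ", "), "\n")
  cat("  genetic length (M):", paste(signif(x$genLength, 3), collapse = ", "), "\n")
  if (!is.null(x$csd)) {
    cat(sprintf("  csd window: chr %d, sites %d..%d\n", x$csd$chr, x$csd$start,
                x$csd$start + x$csd$len - 1L))
  }
  invisible(x)
}

#' @noRd
nLoci <- function(spec, chr) length(spec$lociPos[[chr]])

# ---------------------------------------------------------------------------
# Structured coalescent sampler
#
# Genealogies for blocks of tracked sites are drawn from a three-population
# divergence model: an ancestral population splits into mellifera and the
# ancestor of (ligustica, carnica), which then split. Within a block sites
# are completely linked; between blocks they are independent, which
# approximates the very long genetic map. Exactly the requested number of
# segregating sites is produced by placing that many mutations on the
# genealogy proportionally to branch length (every branch subtends a proper
# non-empty leaf subset, so every site is segregating by construction).

# Simulate one coalescent tree and return, for `nSites` mutations, the 0/1
# carrier matrix (rows = haplotypes in input order).
#' @noRd
coalescentBlock <- function(popOf, nSites, splitTimes) {
  nHap <- length(popOf)
  if (nHap == 1L) stopf("coalescent needs at least 2 haplotypes")
  # one node per lineage; a node's branch runs from its birth to the
  # coalescence that removes it, so each branch is recorded exactly once
  leafSet <- vector("list", 2L * nHap - 1L)
  leafSet[seq_len(nHap)] <- as.list(seq_len(nHap))
  nextNode <- nHap
  act <- seq_len(nHap)            # node id per active lineage
  birth <- numeric(nHap)          # birth time per active lineage
  pop <- popOf                    # population label per active lineage
  t <- 0
  branchNode <- integer(2L * nHap - 2L)
  branchLen <- numeric(2L * nHap - 2L)
  nBranch <- 0L
  # events: at tSplit1 lig+car -> anc2; at tSplit2 anc2+mel -> anc
  events <- list(
    list(time = splitTimes[1], from = c("ligustica", "carnica"), to = "anc2"),
    list(time = splitTimes[2], from = c("anc2", "mellifera"), to = "anc")
  )
  while (length(act) > 1L) {
    ks <- table(pop)
    rates <- ks * (ks - 1) / 2
    total <- sum(rates)
    nextEv <- if (length(events)) events[[1]]$time else Inf
    wait <- if (total > 0) stats::rexp(1L, rate = total) else Inf
    if (t + wait >= nextEv) {
      pop[pop %in% events[[1]]$from] <- events[[1]]$to
      t <- nextEv
      events <- events[-1]
    } else {
      t <- t + wait
      p <- sample(names(rates), 1L, prob = as.numeric(rates) / total)
      pair <- sample(which(pop == p), 2L)
      # both coalescing lineages close their branches
      for (q in pair) {
        nBranch <- nBranch + 1L
        branchNode[nBranch] <- act[q]
        branchLen[nBranch] <- t - birth[q]
      }
      nextNode <- nextNode + 1L
      leafSet[[nextNode]] <- c(leafSet[[act[pair[1]]]], leafSet[[act[pair[2]]]])
      act[pair[1]] <- nextNode
      birth[pair[1]] <- t
      act <- act[-pair[2]]
      birth <- birth[-pair[2]]
      pop <- pop[-pair[2]]
    }
  }
  # place mutations proportionally to branch length; the root lineage's
  # open branch is never recorded, so every site is segregating
  idx <- seq_len(nBranch)
  hit <- sample(idx, nSites, replace = TRUE, prob = branchLen[idx])
  m <- matrix(0L, nrow = nHap, ncol = nSites)
  for (j in seq_len(nSites)) m[leafSet[[branchNode[hit[j]]]], j] <- 1L
  m
}

#' Simulate founder honeybee genomes
#'
#' Draws phased founder haplotypes from a structured coalescent under a
#' three-subspecies divergence model (*A. m. mellifera* splitting first from
#' the ancestor of *A. m. ligustica* and *A. m. carnica*). Exactly
#' `nSegSites` segregating sites are produced per chromosome. Genetic map
#' positions are assigned as bp x `recombRate`.
#'
#' The published demographic model behind the real species is not fully
#' parameterised here; split times (in coalescent units) are configurable
#' stand-ins chosen so that between-subspecies divergence exceeds
#' within-subspecies diversity.
#'
#' @param nCar,nLig,nMel founder counts per subspecies (diploid individuals).
#' @param nChr number of chromosomes.
#' @param nSegSites segregating sites retained per chromosome.
#' @param bpLength physical chromosome length(s) in bp.
#' @param recombRate recombination rate per bp.
#' @param splitTimes two increasing coalescent-unit times: (ligustica-carnica
#'   split, mellifera split).
#' @param sitesPerBlock tracked sites sharing one genealogy (complete linkage
#'   within a block, independence between blocks).
#' @return A `FounderGenomes` object: per chromosome a `2*nInd x nSegSites`
#'   0/1 haplotype matrix, plus the genome specification and a subspecies
#'   label per founder.
#' @examples
#' founders <- simulateFounderGenomes(nCar = 10, nChr = 3, nSegSites = 100)
#' founders
#' @export
simulateFounderGenomes <- function(nCar = 0, nLig = 0, nMel = 0,
                                   nChr = 3, nSegSites = 100,
                                   bpLength = HONEYBEE_GENOME_BP / HONEYBEE_N_CHR,
                                   recombRate = HONEYBEE_RECOMB_RATE,
                                   splitTimes = c(0.3, 0.6),
                                   sitesPerBlock = 10) {
  nCar <- resolveN(nCar, "nCar"); nLig <- resolveN(nLig, "nLig")
  nMel <- resolveN(nMel, "nMel")
  nInd <- nCar + nLig + nMel
  if (nInd < 1L) stopf("at least one founder individual is required")
  nChr <- resolveN(nChr, "nChr")
  nSegSites <- resolveN(nSegSites, "nSegSites")
  if (nSegSites < 1L) stopf("'nSegSites' must be at least 1")
  if (length(splitTimes) != 2L || any(diff(splitTimes) <= 0) || any(splitTimes <= 0)) {
    stopf("'splitTimes' must be two increasing positive times")
  }
  subspecies <- rep(c("carnica", "ligustica", "mellifera"), times = c(nCar, nLig, nMel))
  popOf <- rep(subspecies, each = 2L)
  bpLength <- rep_len(bpLength, nChr)
  haplo <- vector("list", nChr)
  lociPos <- vector("list", nChr)
  for (c in seq_len(nChr)) {
    blocks <- list()
    made <- 0L
    while (made < nSegSites) {
      take <- min(sitesPerBlock, nSegSites - made)
      blocks[[length(blocks) + 1L]] <- coalescentBlock(popOf, take, splitTimes)
      made <- made + take
    }
    h <- do.call(cbind, blocks)
    # random site order decouples block structure from map position order
    h <- h[, sample.int(ncol(h)), drop = FALSE]
    pos <- sort(sample.int(bpLength[c] - 1L, nSegSites))
    haplo[[c]] <- h
    lociPos[[c]] <- as.numeric(pos)
  }
  spec <- newGenomeSpec(nChr, bpLength, recombRate, lociPos)
  structure(
    list(nInd = nInd, haplo = haplo, subspecies = subspecies,
         genome = spec, csdEdited = FALSE),
    class = "FounderGenomes"
  )
}

#' @exportS3Method base::print
print.FounderGenomes <- function(x, ...) {
  cat("Founder genomes\n")
  cat("  individuals:", x$nInd,
      sprintf("(%s)", paste(names(table(x$subspecies)), table(x$subspecies),
                            sep = ":", collapse = ", ")), "\n")
  cat("  chromosomes:", x$genome$nChr, "| sites/chr:",
      paste(vapply(x$haplo, ncol, 1L), collapse = ", "), "\n")
  cat("  csd alleles edited:", x$csdEdited, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Haplotype import / export

#' Import founder haplotypes
#'
#' Builds a `FounderGenomes` object from user-supplied phased haplotypes —
#' either a phased VCF file or a plain 0/1 matrix (rows = haplotypes,
#' columns = sites) with a site map. Non-segregating sites are dropped with a
#' message. Haplotypes are paired in order into diploid founders; with
#' `haploid = TRUE` (e.g. drone-derived haplotypes) each haplotype is
#' duplicated into a fully homozygous founder.
#'
#' @param source path to a phased VCF, or a 0/1 matrix.
#' @param chr,pos for matrix input: chromosome index and bp position per
#'   column (ignored for VCF input, which carries its own coordinates).
#' @param haploid logical; treat each row as a haploid (drone) genome.
#' @param bpLength,recombRate genome map parameters, as in
#'   [simulateFounderGenomes()].
#' @return A `FounderGenomes` object.
#' @export
importHaplotypes <- function(source, chr = NULL, pos = NULL, haploid = FALSE,
                             bpLength = NULL, recombRate = HONEYBEE_RECOMB_RATE) {
  if (is.character(source) && length(source) == 1L) {
    v <- vcfR::read.vcfR(source, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (any(grepl("/", gt, fixed = TRUE))) stopf("VCF genotypes must be phased ('|')")
    pl <- lengths(strsplit(gt, "|", fixed = TRUE))
    if (length(unique(pl)) != 1L) stopf("mixed-ploidy VCF genotypes are not supported")
    ploidy <- unique(pl)
    nSamp <- ncol(gt)
    hap <- matrix(0L, nrow = nSamp * ploidy, ncol = nrow(gt))
    k <- 0L
    for (s in seq_len(nSamp)) {
      ps <- strsplit(gt[, s], "|", fixed = TRUE)
      for (h in seq_len(ploidy)) {
        k <- k + 1L
        hap[k, ] <- as.integer(vapply(ps, `[[`, "", h))
      }
    }
    chr <- match(v@fix[, "CHROM"], unique(v@fix[, "CHROM"]))
    pos <- as.numeric(v@fix[, "POS"])
    source <- hap
    if (ploidy == 1L) haploid <- TRUE
  }
  if (!is.matrix(source)) stopf("'source' must be a VCF path or a 0/1 matrix")
  if (!all(source %in% c(0L, 1L))) stopf("haplotype matrix must be 0/1")
  if (is.null(chr) || is.null(pos) || length(chr) != ncol(source) ||
      length(pos) != ncol(source)) {
    stopf("'chr' and 'pos' must give one entry per site")
  }
  if (haploid) {
    source <- source[rep(seq_len(nrow(source)), each = 2L), , drop = FALSE]
  } else if (nrow(source) %% 2L != 0L) {
    stopf("diploid import needs an even number of haplotypes (or haploid = TRUE)")
  }
  # drop non-segregating sites
  seg <- colMeans(source) > 0 & colMeans(source) < 1
  if (any(!seg)) {
    message(sum(!seg), " non-segregating site(s) dropped on import")
    source <- source[, seg, drop = FALSE]
    chr <- chr[seg]; pos <- pos[seg]
  }
  if (ncol(source) == 0L) stopf("no segregating sites left after filtering")
  nChr <- max(chr)
  ord <- order(chr, pos)
  source <- source[, ord, drop = FALSE]; chr <- chr[ord]; pos <- pos[ord]
  haplo <- lapply(seq_len(nChr), function(c) source[, chr == c, drop = FALSE])
  lociPos <- lapply(seq_len(nChr), function(c) pos[chr == c])
  if (is.null(bpLength)) bpLength <- vapply(lociPos, function(p) max(p) + 1, 1)
  spec <- newGenomeSpec(nChr, bpLength, recombRate, lociPos)
  structure(
    list(nInd = nrow(source) / 2L, haplo = haplo,
         subspecies = rep("imported", nrow(source) / 2L),
         genome = spec, csdEdited = FALSE),
    class = "FounderGenomes"
  )
}

#' Write phased haplotypes to a VCF file
#'
#' Emits a minimal phased VCF (GT field only) for founder genomes or a
#' population. Haploid drones are written with a single allele per genotype.
#'
#' @param x a `FounderGenomes` or [BeePop] object.
#' @param file output path.
#' @param simParamBee simulation parameters (needed for populations).
#' @return `file`, invisibly.
#' @export
writePhasedVcf <- function(x, file, simParamBee = NULL) {
  if (inherits(x, "FounderGenomes")) {
    spec <- x$genome
    ids <- paste0("founder", seq_len(x$nInd))
    hapOf <- function(c) x$haplo[[c]]
    ploidy <- rep(2L, x$nInd)
  } else if (inherits(x, "BeePop")) {
    sp <- getSimParamBee(simParamBee)
    spec <- sp$genome
    ids <- x$id
    ploidy <- x$ploidy
    hapOf <- function(c) do.call(rbind, lapply(x$haplo, `[[`, c))
  } else stopf("'x' must be FounderGenomes or a BeePop")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=apisim",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  for (c in seq_len(spec$nChr)) {
    h <- hapOf(c)
    pos <- spec$lociPos[[c]]
    rowStart <- c(0L, cumsum(ploidy))
    for (j in seq_along(pos)) {
      gts <- vapply(seq_along(ids), function(i) {
        rows <- (rowStart[i] + 1L):rowStart[i + 1L]
        paste(h[rows, j], collapse = "|")
      }, "")
      writeLines(paste(c(as.character(c), format(pos[j], scientific = FALSE),
                         sprintf("chr%d_site%d", c, j), "A", "T", ".", "PASS",
                         ".", "GT", gts), collapse = "\t"), con)
    }
  }
  invisible(file)
}
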