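# Complementary sex determination (csd).
#
# Fertilised (diploid) eggs heterozygous at the csd locus develop into
# females; csd homozygotes develop into diploid drones that workers kill, so
# they are removed from the brood and never enter the simulation. An allele
# is the 0/1 word read along the non-recombining csd window.

#' Retrieve csd alleles
#'
#' Reports the csd allele(s) of each individual: two non-recombining window
#' haplotypes for diploids, one for haploid drones, as strings of 0s and 1s
#' (ancestral / derived alleles along the window).
#'
#' @param x a `BeePop`, or a `FounderGenomes` object.
#' @param collapse if `TRUE` (default) return a named character vector of
#'   words (names follow the `individual_haplotype` convention); if `FALSE`
#'   return the 0/1 matrix with `chromosome_locus` column labels.
#' @param simParamBee simulation parameters (default: global).
#' @return Words or a 0/1 matrix, one row per haplotype.
#' @export
getCsdAlleles <- function(x, collapse = TRUE, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  csd <- sp$genome$csd
  win <- csd$start:(csd$start + csd$len - 1L)
  if (inherits(x, "FounderGenomes")) {
    m <- x$haplo[[csd$chr]][, win, drop = FALSE]
    rn <- paste(rep(seq_len(x$nInd), each = 2L), rep(1:2, x$nInd), sep = "_")
  } else if (inherits(x, "BeePop")) {
    rows <- lapply(seq_len(nInd(x)), function(i) {
      x$haplo[[i]][[csd$chr]][, win, drop = FALSE]
    })
    m <- do.call(rbind, rows)
    rn <- unlist(lapply(seq_len(nInd(x)), function(i) {
      paste(x$id[i], seq_len(x$ploidy[i]), sep = "_")
    }))
  } else stopf("'x' must be a BeePop or FounderGenomes")
  rownames(m) <- rn
  colnames(m) <- paste(csd$chr, win, sep = "_")
  if (collapse) {
    stats::setNames(apply(m, 1L, paste, collapse = ""), rn)
  } else m
}

#' Test csd heterozygosity
#'
#' `TRUE` for a diploid individual whose two csd window words differ. All
#' living diploid individuals in a simulation are csd-heterozygous, because
#' homozygous brood is removed at creation.
#'
#' @param x a `BeePop` of diploid individuals.
#' @param simParamBee simulation parameters (default: global).
#' @return Logical vector, one entry per individual.
#' @export
isCsdHeterozygous <- function(x, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  stopifnot(inherits(x, "BeePop"))
  if (any(x$ploidy != 2L)) stopf("csd heterozygosity is defined for diploids only")
  csd <- sp$genome$csd
  vapply(seq_len(nInd(x)), function(i) {
    w <- csdWordsOf(x$haplo[[i]], csd)
    w[1L] != w[2L]
  }, TRUE)
}

#' Theoretical brood homozygosity of a mated queen
#'
#' With queen csd words `{a1, a2}` and stored father words `f_1..f_k` (each
#' father equally likely to sire an egg), the probability that a fertilised
#' egg is csd-homozygous is `(1/(2k)) * sum_j([f_j == a1] + [f_j == a2])`:
#' the egg carries one maternal word with probability 1/2 each, and is
#' homozygous when the (clonal) paternal word matches it. The value is
#' bounded by 1/2.
#'
#' @param x a `Colony` with a mated queen, or a queen `BeePop` of one
#'   (then `fathers` must be supplied).
#' @param fathers father `BeePop` (when `x` is a queen population).
#' @param simParamBee simulation parameters (default: global).
#' @return Probability in `[0, 1/2]`.
#' @export
pHomBrood <- function(x, fathers = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  qf <- queenAndFathers(x, fathers)
  csd <- sp$genome$csd
  a <- csdWordsOf(qf$queen$haplo[[1L]], csd)
  f <- vapply(seq_len(nInd(qf$fathers)), function(j) {
    csdWordsOf(qf$fathers$haplo[[j]], csd)
  }, "")
  # (1/(2k)) * sum_j([f_j == a1] + [f_j == a2]); c() below has 2k entries
  mean(c(f == a[1L], f == a[2L]))
}

#' Realized number of homozygous brood of a queen
#'
#' Cumulative count of csd-homozygous (removed) offspring since the queen
#' mated, updated every time brood is created from her.
#'
#' @inheritParams pHomBrood
#' @return Non-negative integer count.
#' @export
nHomBrood <- function(x, fathers = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  qf <- queenAndFathers(x, fathers)
  v <- get0(qf$queen$id[1L], envir = sp$homBrood, inherits = FALSE)
  if (is.null(v)) 0L else v
}

# Resolve (queen, fathers) from a Colony or explicit pair; a virgin queen
# (no stored fathers) is an error.
#' @noRd
queenAndFathers <- function(x, fathers = NULL) {
  if (inherits(x, "Colony")) {
    if (nInd(x$queen) == 0L) stopf("colony has no mated queen")
    queen <- x$queen; fathers <- x$fathers
  } else if (inherits(x, "BeePop")) {
    if (nInd(x) != 1L) stopf("'x' must contain exactly one queen")
    queen <- x
  } else stopf("'x' must be a Colony or a queen BeePop")
  if (is.null(fathers) || nInd(fathers) == 0L) {
    stopf("queen has no stored fathers (virgin queen?)")
  }
  list(queen = queen, fathers = fathers)
}

# --- candidate brood -------------------------------------------------------

# Form nInd fertilised eggs from queen x stored fathers: the father of each
# egg is sampled uniformly from the spermatheca, the maternal gamete is
# meiotic, the paternal gamete clonal.
#' @noRd
makeEggs <- function(queen, fathers, nInd, sp) {
  fatherIdx <- if (nInd > 0L) sample.int(nInd(fathers), nInd, replace = TRUE) else integer(0)
  genomes <- lapply(seq_len(nInd), function(e) {
    zygote(gameteFrom(queen$haplo[[1L]], queen$ibd[[1L]], sp$genome),
           droneGamete(fathers, fatherIdx[e]))
  })
  list(genomes = genomes, fatherId = fathers$id[fatherIdx])
}

#' Remove csd-homozygous zygotes from candidate brood
#'
#' Keeps only csd-heterozygous zygotes (the females); homozygotes are
#' discarded — they would develop into diploid drones that workers kill —
#' and the queen's cumulative homozygous-brood counter (see [nHomBrood()])
#' is incremented. The requested brood size is never topped up after
#' removal.
#'
#' @param candidates candidate brood from the internal egg generator (a list
#'   with `genomes` and `fatherId`), as produced inside [createWorkers()]
#'   and [createVirginQueens()].
#' @param queen the mated queen (`BeePop` of one) the brood came from.
#' @param simParamBee simulation parameters (default: global).
#' @return A list with `survivors` (filtered candidates) and `nRemoved`.
#' @export
filterCsdViable <- function(candidates, queen, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  csd <- sp$genome$csd
  ok <- vapply(candidates$genomes, function(g) {
    w <- csdWordsOf(g$haplo, csd)
    w[1L] != w[2L]
  }, TRUE)
  nRemoved <- sum(!ok)
  qid <- queen$id[1L]
  prev <- get0(qid, envir = sp$homBrood, inherits = FALSE)
  assign(qid, (if (is.null(prev)) 0L else prev) + nRemoved, envir = sp$homBrood)
  list(
    survivors = list(genomes = candidates$genomes[ok],
                     fatherId = candidates$fatherId[ok]),
    nRemoved = nRemoved
  )
}
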