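# Quantitative genetics: additive trait architecture, genetic and phenotypic
# values, and colony-level value mapping.
#
# Traits are purely additive: gv = intercept + sum over QTL of effect x
# allele dosage. Haploid drones are scored as doubled haploids (dosage 0/2),
# keeping them on the diploid scale. Honeybee colony phenotypes typically
# combine a queen effect (egg laying, pheromones) and a worker effect (the
# actual work), often negatively correlated; the default colony value is
# queen effect of the queen + the sum of the workers' worker effects.

#' Add correlated additive traits
#'
#' Defines the trait architecture in the simulation parameters: `nQtlPerChr`
#' QTL per chromosome sampled uniformly among tracked sites (excluding the
#' csd window), with per-QTL effect vectors drawn from a multivariate normal
#' with correlation matrix `corA`. Effects are centred and scaled so that
#' the *base virgin-queen population* (virgin queens carrying two meiotic
#' gametes of one founder each) has mean `mean` and additive variance `var`
#' per trait; the calibration sample is simulated internally from the
#' founders.
#'
#' @param nQtlPerChr QTL per chromosome.
#' @param mean,var target mean and genetic variance per trait.
#' @param corA genetic correlation matrix (symmetric PSD, unit diagonal).
#' @param varE environmental variance per trait (used by [setPheno()]).
#' @param corE environmental correlation matrix.
#' @param simParamBee simulation parameters (default: global).
#' @return The modified `SimParamBee`, invisibly.
#' @examples
#' founders <- simulateFounderGenomes(nCar = 8, nChr = 1, nSegSites = 40)
#' SP <- newSimParamBee(founders, nCsdAlleles = 4, seed = 3)
#' addTraitA(nQtlPerChr = 10, mean = c(10, 0), var = c(1, 1),
#'           corA = matrix(c(1, -0.5, -0.5, 1), 2), varE = c(1, 2))
#' @export
addTraitA <- function(nQtlPerChr, mean = 0, var = 1, corA = NULL,
                      varE = NULL, corE = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  nTraits <- length(mean)
  if (length(var) != nTraits) stopf("'mean' and 'var' lengths differ")
  if (is.null(corA)) corA <- diag(nTraits)
  if (is.null(corE)) corE <- diag(nTraits)
  if (is.null(varE)) varE <- rep(0, nTraits)
  checkCorMat(corA, nTraits, "corA")
  checkCorMat(corE, nTraits, "corE")
  spec <- sp$genome
  qtl <- vector("list", spec$nChr)
  for (c in seq_len(spec$nChr)) {
    avail <- seq_len(nLoci(spec, c))
    if (!is.null(spec$csd) && spec$csd$chr == c) {
      avail <- setdiff(avail, spec$csd$start:(spec$csd$start + spec$csd$len - 1L))
    }
    if (nQtlPerChr > length(avail)) {
      stopf("chromosome %d has only %d usable sites for %d QTL", c,
            length(avail), nQtlPerChr)
    }
    qtl[[c]] <- sort(sample(avail, nQtlPerChr))
  }
  nQtl <- nQtlPerChr * spec$nChr
  effects <- MASS::mvrnorm(nQtl, mu = rep(0, nTraits), Sigma = corA)
  effects <- matrix(effects, nrow = nQtl)

  # calibration: raw genetic values in a simulated base virgin-queen sample
  founders <- sp$founders
  reps <- max(1L, ceiling(400 / founders$nInd))
  raw <- matrix(0, nrow = reps * founders$nInd, ncol = nTraits)
  k <- 0L
  for (r in seq_len(reps)) {
    for (i in seq_len(founders$nInd)) {
      g <- founderGenome(founders, i)
      g1 <- gameteFrom(g$haplo, g$ibd, spec)
      g2 <- gameteFrom(g$haplo, g$ibd, spec)
      dose <- qtlDosageFromHaplo(Map(rbind, g1$haplo, g2$haplo), qtl)
      k <- k + 1L
      raw[k, ] <- dose %*% effects
    }
  }
  sds <- apply(raw, 2L, stats::sd)
  if (any(sds == 0)) stopf("degenerate trait calibration (no genetic variance); use more QTL or founders")
  scale <- sqrt(var) / sds
  effects <- sweep(effects, 2L, scale, `*`)
  intercept <- mean - colMeans(raw) * scale

  sp$traits <- list(nTraits = nTraits, qtl = qtl, effects = effects,
                    intercept = intercept, mean = mean, var = var,
                    corA = corA, varE = varE, corE = corE)
  invisible(sp)
}

#' @noRd
checkCorMat <- function(m, n, what) {
  if (!is.matrix(m) || any(dim(m) != n) || !isSymmetric(unname(m)) ||
      any(abs(diag(m) - 1) > 1e-8)) {
    stopf("'%s' must be a symmetric %dx%d correlation matrix", what, n)
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stopf("'%s' is not positive semi-definite", what)
  }
}

# QTL allele dosage from a haplotype list (rows = haplotypes per chr);
# haploids are doubled.
#' @noRd
qtlDosageFromHaplo <- function(haplo, qtl) {
  unlist(lapply(seq_along(qtl), function(c) {
    h <- haplo[[c]][, qtl[[c]], drop = FALSE]
    d <- colSums(h)
    if (nrow(haplo[[c]]) == 1L) d <- 2 * d
    d
  }))
}

#' @noRd
popQtlDosage <- function(pop, traits) {
  t(vapply(seq_len(nInd(pop)), function(i) {
    qtlDosageFromHaplo(pop$haplo[[i]], traits$qtl)
  }, numeric(sum(lengths(traits$qtl)))))
}

#' Genetic values
#'
#' Computes per-trait additive genetic values (`intercept + sum of QTL
#' effect x dosage`, drones on the doubled-haploid scale). For colonies, the
#' `caste` argument selects whose values are returned; for a `MultiColony`
#' one block per colony is returned.
#'
#' @param x a `BeePop`, `Colony`, or `MultiColony`.
#' @param caste caste slot (colony input), e.g. `"queen"`, `"workers"`.
#' @param simParamBee simulation parameters (default: global).
#' @return A numeric matrix (individuals x traits), or a named list of such
#'   matrices for a `MultiColony`.
#' @export
getGv <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  traits <- sp$traits
  if (is.null(traits)) stopf("no traits defined; call addTraitA() first")
  if (inherits(x, "MultiColony")) {
    res <- lapply(x$colonies, getGv, caste = caste, simParamBee = sp)
    names(res) <- colonyIds(x)
    return(res)
  }
  if (inherits(x, "Colony")) {
    if (is.null(caste)) stopf("specify the 'caste' to extract from a colony")
    x <- getCastePop(x, caste)
  }
  stopifnot(inherits(x, "BeePop"))
  if (nInd(x) == 0L) {
    warnf("no individuals in the requested caste")
    return(matrix(numeric(0), ncol = traits$nTraits))
  }
  g <- popQtlDosage(x, traits) %*% traits$effects
  g <- sweep(g, 2L, traits$intercept, `+`)
  rownames(g) <- x$id
  colnames(g) <- paste0("trait", seq_len(traits$nTraits))
  g
}

#' Draw phenotypes
#'
#' Sets phenotypes as `pheno = gv + e`, with environmental deviations drawn
#' per individual from a multivariate normal with variances `varE` and
#' correlations `corE` from the trait architecture. Each call redraws the
#' deviations. For colonies, all member populations get phenotypes.
#'
#' @param x a `BeePop`, `Colony`, or `MultiColony`.
#' @param simParamBee simulation parameters (default: global).
#' @return `x` with phenotypes stored (retrieve with [getPheno()]).
#' @export
setPheno <- function(x, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  traits <- sp$traits
  if (is.null(traits)) stopf("no traits defined; call addTraitA() first")
  if (inherits(x, "MultiColony")) {
    return(createMultiColony(lapply(x$colonies, setPheno, simParamBee = sp)))
  }
  if (inherits(x, "Colony")) {
    for (slot in c("queen", "fathers", "workers", "drones", "virginQueens")) {
      if (nInd(x[[slot]]) > 0L) x[[slot]] <- setPheno(x[[slot]], sp)
    }
    return(x)
  }
  stopifnot(inherits(x, "BeePop"))
  g <- getGv(x, simParamBee = sp)
  sdE <- sqrt(traits$varE)
  SigmaE <- diag(sdE, traits$nTraits) %*% traits$corE %*% diag(sdE, traits$nTraits)
  e <- MASS::mvrnorm(nInd(x), mu = rep(0, traits$nTraits), Sigma = SigmaE)
  x$pheno <- g + matrix(e, nrow = nInd(x))
  x
}

#' Stored phenotypes
#'
#' Retrieves phenotypes previously drawn with [setPheno()].
#'
#' @inheritParams getGv
#' @return As [getGv()].
#' @export
getPheno <- function(x, caste = NULL, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  if (inherits(x, "MultiColony")) {
    res <- lapply(x$colonies, getPheno, caste = caste, simParamBee = sp)
    names(res) <- colonyIds(x)
    return(res)
  }
  if (inherits(x, "Colony")) {
    if (is.null(caste)) stopf("specify the 'caste' to extract from a colony")
    x <- getCastePop(x, caste)
  }
  stopifnot(inherits(x, "BeePop"))
  if (nInd(x) == 0L) {
    warnf("no individuals in the requested caste")
    return(matrix(numeric(0), ncol = if (is.null(sp$traits)) 0L else sp$traits$nTraits))
  }
  if (is.null(x$pheno)) stopf("no phenotypes stored; call setPheno() first")
  p <- x$pheno
  rownames(p) <- x$id
  p
}

#' Colony-level values
#'
#' Maps individual values to a colony value. The default mapping is the
#' additive model used for traits like honey yield: the queen's
#' queen-effect value plus the sum of the workers' worker-effect values.
#' `FUN` replaces the default and receives the queen value matrix, the
#' worker value matrix, and the colony.
#'
#' @param x a `Colony` or `MultiColony`.
#' @param use `"gv"` (genetic) or `"pheno"` (phenotypic) values.
#' @param queenTrait,workersTrait trait indices of the queen and worker
#'   effect (defaults 1 and 2; with a single trait use 1 and 1).
#' @param combineWorkers `"sum"` (default additive model) or `"mean"`.
#' @param FUN optional `function(queenValues, workerValues, colony)`.
#' @param simParamBee simulation parameters (default: global).
#' @return A numeric value per colony (named vector for `MultiColony`).
#' @export
calcColonyValue <- function(x, use = c("gv", "pheno"), queenTrait = 1L,
                            workersTrait = 2L, combineWorkers = c("sum", "mean"),
                            FUN = NULL, simParamBee = NULL) {
  use <- match.arg(use)
  combineWorkers <- match.arg(combineWorkers)
  sp <- getSimParamBee(simParamBee)
  if (inherits(x, "MultiColony")) {
    v <- vapply(x$colonies, function(cl) {
      calcColonyValue(cl, use = use, queenTrait = queenTrait,
                      workersTrait = workersTrait,
                      combineWorkers = combineWorkers, FUN = FUN,
                      simParamBee = sp)
    }, numeric(1))
    names(v) <- colonyIds(x)
    return(v)
  }
  stopifnot(inherits(x, "Colony"))
  if (nInd(x$queen) == 0L) stopf("colony value needs a queen (colony '%s' is queenless)", x$id)
  extract <- if (use == "gv") getGv else getPheno
  qv <- extract(x, caste = "queen", simParamBee = sp)
  wv <- if (nWorkers(x) > 0L) extract(x, caste = "workers", simParamBee = sp)
        else matrix(numeric(0), ncol = ncol(qv))
  if (!is.null(FUN)) return(FUN(qv, wv, x))
  if (max(queenTrait, workersTrait) > ncol(qv)) {
    stopf("trait index out of range (only %d trait(s) defined)", ncol(qv))
  }
  wsum <- if (nrow(wv)) {
    if (combineWorkers == "sum") sum(wv[, workersTrait]) else mean(wv[, workersTrait])
  } else 0
  unname(qv[1L, queenTrait] + wsum)
}

#' @rdname calcColonyValue
#' @export
calcColonyGv <- function(x, ...) calcColonyValue(x, use = "gv", ...)

#' @rdname calcColonyValue
#' @export
calcColonyPheno <- function(x, ...) calcColonyValue(x, use = "pheno", ...)
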