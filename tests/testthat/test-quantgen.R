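# Trait architecture, genetic and phenotypic values, colony values.

test_that("trait scaling recovers target variances and correlation", {
  set.seed(90)
  nRep <- 20
  vars <- matrix(0, nRep, 2); cors <- numeric(nRep)
  for (r in seq_len(nRep)) {
    founders <- simulateFounderGenomes(nCar = 100, nChr = 2, nSegSites = 50)
    sp <- newSimParamBee(founders, nCsdAlleles = 8, seed = 900 + r)
    addTraitA(nQtlPerChr = 15, mean = c(10, 0), var = c(1, 1),
              corA = matrix(c(1, -0.5, -0.5, 1), 2), simParamBee = sp)
    base <- createVirginQueens(sp$founders, simParamBee = sp)
    g <- getGv(base, simParamBee = sp)
    vars[r, ] <- apply(g, 2, var)
    cors[r] <- cor(g[, 1], g[, 2])
    if (r == 1) {
      expect_lt(abs(mean(g[, 1]) - 10), 0.5)
      expect_lt(abs(mean(g[, 2]) - 0), 0.5)
    }
  }
  expect_lt(abs(mean(vars[, 1]) - 1), 0.1)
  expect_lt(abs(mean(vars[, 2]) - 1), 0.1)
  expect_lt(abs(mean(cors) - (-0.5)), 0.15)
})

test_that("uncorrelated traits come out uncorrelated", {
  set.seed(91)
  cors <- vapply(1:5, function(r) {
    # independent site genealogies keep the effective number of loci high
    founders <- simulateFounderGenomes(nCar = 100, nChr = 2, nSegSites = 50,
                                       sitesPerBlock = 1)
    sp <- newSimParamBee(founders, nCsdAlleles = 8, seed = 910 + r)
    addTraitA(nQtlPerChr = 15, mean = c(0, 0), var = c(1, 1), simParamBee = sp)
    base <- createVirginQueens(sp$founders, simParamBee = sp)
    g <- getGv(base, simParamBee = sp)
    cor(g[, 1], g[, 2])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.2) # identity corA, sampling noise only
})

test_that("addTraitA validates its inputs", {
  sim <- newTestSim(seed = 92)
  badCor <- matrix(c(1, 2, 2, 1), 2)
  expect_error(addTraitA(5, mean = c(0, 0), var = c(1, 1), corA = badCor,
                         simParamBee = sim$sp), "positive semi-definite")
  expect_error(addTraitA(500, mean = 0, var = 1, simParamBee = sim$sp),
               "usable sites")
  expect_error(getGv(baseVirginQueens(sim, 1), simParamBee = sim$sp),
               "no traits defined")
})

test_that("gv equals a brute-force dot product over QTL dosages", {
  sim <- newTestSim(seed = 93)
  sp <- sim$sp
  addTraitA(nQtlPerChr = 6, mean = c(5, -2), var = c(2, 1),
            corA = matrix(c(1, 0.3, 0.3, 1), 2), simParamBee = sp)
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 10, nDrones = 4)
  traits <- sp$traits

  for (pop in list(getCastePop(colony, "workers"), getCastePop(colony, "drones"),
                   colony$queen)) {
    g <- getGv(pop, simParamBee = sp)
    for (i in seq_len(nInd(pop))) {
      # independent oracle: rebuild the dosage from raw haplotype matrices
      dose <- unlist(lapply(seq_along(traits$qtl), function(c) {
        h <- pop$haplo[[i]][[c]][, traits$qtl[[c]], drop = FALSE]
        d <- colSums(h)
        if (pop$ploidy[i] == 1) d <- 2 * d
        d
      }))
      expect_equal(unname(g[i, ]),
                   unname(as.numeric(dose %*% traits$effects + traits$intercept)),
                   tolerance = 1e-12)
    }
  }
})

test_that("drone gv equals the doubled-haploid diploid equivalent", {
  sim <- newTestSim(seed = 94)
  sp <- sim$sp
  addTraitA(nQtlPerChr = 6, mean = 0, var = 1, simParamBee = sp)
  vq <- baseVirginQueens(sim, 1)
  drones <- createDrones(vq, nInd = 5, simParamBee = sp)
  g <- getGv(drones, simParamBee = sp)
  traits <- sp$traits
  for (i in 1:5) {
    doubled <- unlist(lapply(seq_along(traits$qtl), function(c) {
      2 * drones$haplo[[i]][[c]][1, traits$qtl[[c]]]
    }))
    expect_equal(unname(g[i, 1]),
                 unname(as.numeric(doubled %*% traits$effects + traits$intercept)))
  }
})

test_that("phenotypes are gv plus the configured environmental noise", {
  sim <- newTestSim(nFounders = 8, seed = 95)
  sp <- sim$sp
  addTraitA(nQtlPerChr = 6, mean = c(0, 0), var = c(1, 1),
            varE = c(0, 0), simParamBee = sp)
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 15, nDrones = 2)
  colony <- setPheno(colony, simParamBee = sp)
  # varE = 0: phenotype equals genetic value exactly
  expect_equal(getPheno(colony, "workers", simParamBee = sp),
               getGv(colony, "workers", simParamBee = sp))

  # redefine noise and check its realized variance and correlation
  addTraitA(nQtlPerChr = 6, mean = c(0, 0), var = c(1, 1),
            varE = c(1, 4), corE = matrix(c(1, -0.4, -0.4, 1), 2),
            simParamBee = sp)
  set.seed(96)
  workers <- createWorkers(colony, 500, sp)$workers
  resid <- NULL
  for (k in 1:20) { # 10^4 deviates in total
    wp <- setPheno(workers, simParamBee = sp)
    resid <- rbind(resid, wp$pheno - getGv(workers, simParamBee = sp))
  }
  expect_lt(abs(var(resid[, 1]) - 1) / 1, 0.05)
  expect_lt(abs(var(resid[, 2]) - 4) / 4, 0.05)
  expect_lt(abs(cor(resid[, 1], resid[, 2]) - (-0.4)), 0.05)
})

test_that("caste value extraction respects colony structure", {
  sim <- newTestSim(seed = 97)
  sp <- sim$sp
  addTraitA(nQtlPerChr = 5, mean = c(0, 0), var = c(1, 1), varE = c(1, 1),
            simParamBee = sp)
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 8, nDrones = 3)
  expect_equal(nrow(getGv(colony, "queen", simParamBee = sp)), 1)
  expect_equal(nrow(getGv(colony, "fathers", simParamBee = sp)), nFathers(colony))
  expect_warning(g <- getGv(colony, "virginQueens", simParamBee = sp),
                 "no individuals")
  expect_equal(nrow(g), 0)

  apiary <- createMultiColony(baseVirginQueens(sim, 3), simParamBee = sp)
  # one block per colony on a MultiColony
  gl <- suppressWarnings(getGv(apiary, "virginQueens", simParamBee = sp))
  expect_length(gl, 3)
})

test_that("default colony value is queen effect plus summed worker effects", {
  sim <- newTestSim(seed = 98)
  sp <- sim$sp
  addTraitA(nQtlPerChr = 5, mean = c(1, 0.1), var = c(1, 1), varE = c(1, 1),
            simParamBee = sp)
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 6, nDrones = 2)
  qv <- getGv(colony, "queen", simParamBee = sp)
  wv <- getGv(colony, "workers", simParamBee = sp)
  expect_equal(calcColonyValue(colony, "gv", simParamBee = sp),
               qv[1, 1] + sum(wv[, 2]))
  # additivity under worker-set union / invariance to ordering
  expect_equal(calcColonyGv(colony, simParamBee = sp),
               qv[1, 1] + sum(rev(wv[, 2])))
  # mean-based variant
  expect_equal(calcColonyValue(colony, "gv", combineWorkers = "mean",
                               simParamBee = sp), qv[1, 1] + mean(wv[, 2]))
  # user mapping: queen only
  expect_equal(calcColonyValue(colony, "gv", FUN = function(q, w, cl) q[1, 1],
                               simParamBee = sp), qv[1, 1])
  queenless <- createColony(baseVirginQueens(sim, 2)[2], simParamBee = sp)
  expect_error(calcColonyValue(queenless, "gv", simParamBee = sp), "queenless")
})

test_that("colony values rank an apiary for selection", {
  sim <- newTestSim(nFounders = 8, seed = 99)
  sp <- sim$sp
  addTraitA(nQtlPerChr = 5, mean = c(0, 0), var = c(1, 1), varE = c(0.5, 0.5),
            simParamBee = sp)
  vq <- baseVirginQueens(sim)
  apiary <- createMultiColony(vq[1:3], simParamBee = sp)
  dca <- createDrones(vq[4:8], nInd = 20, simParamBee = sp)
  grp <- pullDroneGroupsFromDCA(dca, 3, nFathers = 5, simParamBee = sp)
  apiary <- buildUp(cross(apiary, drones = grp$groups, simParamBee = sp),
                    nWorkers = 10, nDrones = 2, simParamBee = sp)
  vals <- calcColonyValue(apiary, "gv", simParamBee = sp)
  expect_length(vals, 3)
  best <- selectColonies(apiary, 1, use = vals)
  expect_equal(best$colonies[[1]]$id, names(which.max(vals)))
})
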