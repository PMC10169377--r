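# csd locus: window configuration, founder editing, brood homozygosity.

test_that("csd window length is log2 of the allele count", {
  set.seed(20)
  founders <- simulateFounderGenomes(nCar = 4, nChr = 3, nSegSites = 30)
  sp <- newSimParamBee(founders, nCsdAlleles = 32, seed = 20)
  expect_equal(sp$genome$csd$len, 5L)
  expect_equal(sp$genome$csd$chr, 3L) # the real locus sits on chromosome 3
  # the window has zero internal genetic width
  win <- sp$genome$csd$start:(sp$genome$csd$start + 4L)
  expect_equal(length(unique(sp$genome$mapPos[[3]][win])), 1L)

  sp2 <- newSimParamBee(founders, nCsdAlleles = 2, seed = 20)
  expect_equal(sp2$genome$csd$len, 1L)

  expect_error(newSimParamBee(founders, nCsdAlleles = 31), "power of two")
  expect_error(newSimParamBee(founders, nCsdAlleles = 8, csdChr = 7),
               "outside the genome")
})

test_that("csd editing installs the requested alleles at uniform frequency", {
  set.seed(21)
  founders <- simulateFounderGenomes(nCar = 10, nChr = 1, nSegSites = 30)
  sp <- newSimParamBee(founders, nCsdAlleles = 4, seed = 21)
  edited <- editCsdAlleles(founders, simParamBee = sp)
  words <- getCsdAlleles(edited, simParamBee = sp)
  tab <- table(words)
  expect_length(tab, 4)                 # exactly 4 distinct words
  expect_true(all(tab == 5))            # 20 haplotypes / 4 alleles
  # every founder heterozygous
  byInd <- matrix(words, nrow = 2)
  expect_true(all(byInd[1, ] != byInd[2, ]))
  # window sites all still segregating
  csd <- sp$genome$csd
  win <- csd$start:(csd$start + csd$len - 1)
  m <- edited$haplo[[csd$chr]][, win, drop = FALSE]
  expect_true(all(colMeans(m) > 0 & colMeans(m) < 1))
})

test_that("more csd alleles than founder haplotypes warns and saturates", {
  set.seed(22)
  founders <- simulateFounderGenomes(nCar = 10, nChr = 1, nSegSites = 30)
  sp <- newSimParamBee(founders, nCsdAlleles = 32, seed = 22)
  expect_warning(edited <- editCsdAlleles(founders, simParamBee = sp),
                 "not all alleles")
  words <- getCsdAlleles(edited, simParamBee = sp)
  expect_length(unique(words), 20) # all 20 haplotypes distinct
})

test_that("with two csd alleles every founder carries both", {
  set.seed(23)
  founders <- simulateFounderGenomes(nCar = 5, nChr = 1, nSegSites = 30)
  sp <- newSimParamBee(founders, nCsdAlleles = 2, seed = 23)
  edited <- editCsdAlleles(founders, simParamBee = sp)
  words <- getCsdAlleles(edited, simParamBee = sp)
  byInd <- matrix(words, nrow = 2)
  expect_true(all(apply(byInd, 2, function(w) setequal(w, unique(words)))))
  expect_error(editCsdAlleles(founders, nCsdAlleles = 1, simParamBee = sp),
               "at least 2")
})

test_that("getCsdAlleles reports two words for diploids, one for drones", {
  sim <- newTestSim(seed = 24)
  vq <- baseVirginQueens(sim, 2)
  w <- getCsdAlleles(vq, simParamBee = sim$sp)
  expect_length(w, 4)
  expect_equal(names(w), c(paste(vq$id[1], 1:2, sep = "_"),
                           paste(vq$id[2], 1:2, sep = "_")))
  # living females are heterozygous
  expect_true(w[1] != w[2] && w[3] != w[4])
  expect_true(all(isCsdHeterozygous(vq, simParamBee = sim$sp)))

  drones <- createDrones(vq[1], nInd = 3, simParamBee = sim$sp)
  wd <- getCsdAlleles(drones, simParamBee = sim$sp)
  expect_length(wd, 3)
  expect_true(all(wd %in% w[1:2])) # drone words come from the mother's pair
  expect_error(isCsdHeterozygous(drones, simParamBee = sim$sp), "diploid")

  # matrix form carries chromosome_locus labels
  m <- getCsdAlleles(vq[1], collapse = FALSE, simParamBee = sim$sp)
  csd <- sim$sp$genome$csd
  expect_equal(colnames(m), paste(csd$chr, csd$start:(csd$start + csd$len - 1),
                                  sep = "_"))
})

test_that("pHomBrood matches the allele-matching formula", {
  sim <- newTestSim(nFounders = 6, seed = 25)
  sp <- sim$sp
  basePop <- baseVirginQueens(sim)
  queenVq <- basePop[1]  # words {w0, w1} under round-robin editing
  qw <- unname(getCsdAlleles(queenVq, simParamBee = sp))

  sameLine <- createDrones(basePop[3], nInd = 60, simParamBee = sp)  # words in {w0, w1}
  otherLine <- createDrones(basePop[2], nInd = 60, simParamBee = sp) # words in {w2, w3}

  # fathers {A, A, C}: two matching one maternal allele, one disjoint -> 1/3
  fA <- dronesWithWord(sameLine, qw[1], sp)
  fC <- dronesWithWord(otherLine,
                       unname(getCsdAlleles(basePop[2], simParamBee = sp))[1], sp)
  colony <- createColony(queenVq, simParamBee = sp)
  colony <- cross(colony, drones = c(fA[1:2], fC[1]), simParamBee = sp)
  expect_equal(pHomBrood(colony), 1 / 3)

  # disjoint father words -> no homozygous brood expected
  queenVq2 <- basePop[5] # words {w0, w1}
  colony2 <- createColony(queenVq2, simParamBee = sp)
  unmated <- otherLine[which(isDrone(otherLine, sp))[1:5]]
  colony2 <- cross(colony2, drones = unmated, simParamBee = sp)
  expect_equal(pHomBrood(colony2), 0)

  # a virgin queen has no fathers
  expect_error(pHomBrood(createColony(basePop[6], simParamBee = sp)),
               "no mated queen")
})

test_that("pHomBrood is bounded by 1/2 over random mating configurations", {
  sim2 <- newTestSim(nFounders = 8, seed = 27)
  sp2 <- sim2$sp
  base2 <- baseVirginQueens(sim2)
  dca2 <- createDrones(base2[5:8], nInd = 15, simParamBee = sp2)
  for (i in 1:4) {
    k <- sample(2:6, 1)
    grp <- pullDroneGroupsFromDCA(dca2, 1, nFathers = k, simParamBee = sp2)
    dca2 <- grp$dca
    col <- cross(createColony(base2[i], simParamBee = sp2),
                 drones = grp$groups[[1]], simParamBee = sp2)
    p <- pHomBrood(col)
    expect_gte(p, 0); expect_lte(p, 0.5)
  }
})

test_that("realized homozygous brood follows the binomial oracle", {
  sim <- newTestSim(nFounders = 6, seed = 28)
  sp <- sim$sp
  basePop <- baseVirginQueens(sim)
  qw <- unname(getCsdAlleles(basePop[1], simParamBee = sp))
  # all fathers carry one maternal word -> pHomBrood = 1/2 * P(match) = 0.5
  sameLine <- createDrones(basePop[3], nInd = 80, simParamBee = sp)
  fA <- dronesWithWord(sameLine, qw[1], sp)
  colony <- cross(createColony(basePop[1], simParamBee = sp),
                  drones = fA[1:5], simParamBee = sp)
  expect_equal(pHomBrood(colony), 0.5)

  set.seed(29)
  survived <- replicate(60, nInd(createWorkers(colony, 40, sp)$workers))
  # survivors ~ Binomial(40, 0.5); mean within 3 SE
  se <- sqrt(40 * 0.5 * 0.5 / 60) # SE of the mean count over 60 replicates
  expect_lt(abs(mean(survived) - 20), 3 * se)
  # the counter accumulated every removal
  expect_equal(nHomBrood(colony), sum(40 - survived))
})

test_that("nHomBrood accumulates additively across brood creations", {
  sim <- newTestSim(seed = 30)
  sp <- sim$sp
  colony <- matedColony(sim, disjointCsd = FALSE)
  expect_equal(nHomBrood(colony), 0) # nothing created yet
  r1 <- createWorkers(colony, 30, sp)
  afterFirst <- nHomBrood(colony)
  expect_equal(afterFirst, r1$nRemoved)
  r2 <- createWorkers(colony, 30, sp)
  expect_equal(nHomBrood(colony), r1$nRemoved + r2$nRemoved)
})

test_that("disjoint csd alleles mean every egg survives", {
  sim <- newTestSim(seed = 31)
  sp <- sim$sp
  colony <- matedColony(sim, disjointCsd = TRUE)
  expect_equal(pHomBrood(colony), 0)
  out <- createWorkers(colony, 50, sp)
  expect_equal(nInd(out$workers), 50)
  expect_equal(out$nRemoved, 0)
  expect_true(all(isCsdHeterozygous(out$workers, simParamBee = sp)))
})
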