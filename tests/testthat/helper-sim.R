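# Shared fixtures, built in code. Dimensions are deliberately small: a few
# founders, 1-2 chromosomes, tens of sites — enough to exercise every code
# path while keeping the suite fast.

# A fresh simulation context: founders with edited csd alleles plus the
# registered SimParamBee.
newTestSim <- function(nFounders = 6, nChr = 2, nSegSites = 30,
                       nCsdAlleles = 4, seed = 101, ...) {
  set.seed(seed)
  founders <- simulateFounderGenomes(nCar = nFounders, nChr = nChr,
                                     nSegSites = nSegSites)
  sp <- newSimParamBee(founders, nCsdAlleles = nCsdAlleles, seed = seed, ...)
  founders <- editCsdAlleles(founders, simParamBee = sp)
  sp$founders <- founders
  list(founders = founders, sp = sp)
}

# Base virgin queens of a test sim (csd alleles already edited).
baseVirginQueens <- function(sim, nInd = NULL) {
  createVirginQueens(sim$founders, nInd, simParamBee = sim$sp)
}

# A mated, optionally built-up colony. With `disjointCsd = TRUE` the drone
# mothers are chosen so no father csd word matches the queen's (with the
# 4-allele round-robin editing, odd-numbered founders carry words {w0, w1}
# and even-numbered founders {w2, w3}).
matedColony <- function(sim, nFathers = 5, disjointCsd = TRUE,
                        buildUp = FALSE, nWorkers = NULL, nDrones = NULL) {
  sp <- sim$sp
  basePop <- baseVirginQueens(sim)
  queenVq <- basePop[1]
  droneMothers <- if (disjointCsd) basePop[c(2, 4)] else basePop[c(3, 5)]
  drones <- createDrones(droneMothers, nInd = 3 * nFathers, simParamBee = sp)
  grp <- pullDroneGroupsFromDCA(drones, 1, nFathers = nFathers, simParamBee = sp)
  colony <- createColony(queenVq, simParamBee = sp)
  colony <- cross(colony, drones = grp$groups[[1]], simParamBee = sp)
  if (buildUp) {
    colony <- buildUp(colony, nWorkers = nWorkers, nDrones = nDrones,
                      simParamBee = sp)
  }
  colony
}

# Drones filtered to those carrying a given csd word.
dronesWithWord <- function(drones, word, sp) {
  w <- getCsdAlleles(drones, simParamBee = sp)
  drones[which(unname(w) == word)]
}

# Founders over one chromosome with a chosen genetic length, built from an
# explicit haplotype matrix so the map is fully under test control.
flatFounders <- function(nSites = 200, morgans = 1, nInd = 2, seed = 11) {
  set.seed(seed)
  hap <- matrix(rbinom(2 * nInd * nSites, 1, 0.5), nrow = 2 * nInd)
  # repair monomorphic columns by flipping one random haplotype
  for (j in which(colMeans(hap) %in% c(0, 1))) {
    i <- sample.int(nrow(hap), 1)
    hap[i, j] <- 1L - hap[i, j]
  }
  bp <- 1e6
  importHaplotypes(hap, chr = rep(1L, nSites),
                   pos = seq(0, bp - 1, length.out = nSites),
                   bpLength = bp, recombRate = morgans / bp)
}
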