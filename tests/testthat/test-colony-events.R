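# Colony container semantics and the event operations.

test_that("a new colony starts empty, unflagged, and unproductive", {
  sim <- newTestSim(seed = 50)
  vq <- baseVirginQueens(sim, 1)
  colony <- createColony(vq, simParamBee = sim$sp)
  expect_equal(nQueens(colony), 0)
  expect_equal(nWorkers(colony), 0)
  expect_equal(nDrones(colony), 0)
  expect_equal(nVirginQueens(colony), 1)
  expect_true(all(is.na(colony$location)))
  expect_false(isProductive(colony) || hasSwarmed(colony) || hasSplit(colony) ||
                 hasCollapsed(colony))
  out <- capture.output(print(colony))
  expect_true(any(grepl("queen: NA", out)))
  # only a female can head a colony
  drones <- createDrones(baseVirginQueens(sim, 2)[2], nInd = 2, simParamBee = sim$sp)
  expect_error(createColony(drones[1], simParamBee = sim$sp), "virgin queen or a queen")
  emptyPop <- drones[integer(0)]
  expect_error(createColony(emptyPop, simParamBee = sim$sp),
               "exactly one female")
})

test_that("get leaves the colony unchanged while pull removes", {
  sim <- newTestSim(seed = 51)
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 30, nDrones = 5)
  w1 <- getCastePop(colony, "workers")
  w2 <- getCastePop(colony, "workers")
  expect_identical(w1$id, w2$id)
  expect_equal(nWorkers(colony), 30)

  res <- pullCastePop(colony, "workers", 10)
  expect_equal(nInd(res$pulled), 10)
  expect_equal(nWorkers(res$colony), 20)
  expect_setequal(c(res$pulled$id, res$colony$workers$id), w1$id)
  expect_error(pullCastePop(res$colony, "workers", 100), "cannot pull")
  expect_error(pullCastePop(colony, "virginQueens", 1), "cannot pull")
})

test_that("add, remove, and replace manage caste membership", {
  sim <- newTestSim(seed = 52)
  sp <- sim$sp
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 20, nDrones = 5)
  colony2 <- addCastePop(colony, "workers", 10, simParamBee = sp)
  expect_equal(nWorkers(colony2), 30)

  colony3 <- removeCastePop(colony2, "drones")
  expect_equal(nDrones(colony3), 0)

  old <- colony3$workers$id
  colony4 <- replaceCastePop(colony3, "workers", 8, simParamBee = sp)
  expect_equal(nWorkers(colony4), 8)
  expect_length(intersect(colony4$workers$id, old), 0) # all fresh brood

  # caste mismatch is refused
  drones <- createDrones(colony, 3, sp)
  expect_error(addCastePop(colony, "workers", drones, simParamBee = sp),
               "must have caste")
})

test_that("buildUp tops up to targets, is idempotent, and flips production", {
  sim <- newTestSim(seed = 53)
  sp <- sim$sp
  colony <- matedColony(sim, disjointCsd = TRUE)
  expect_false(isProductive(colony))
  colony <- buildUp(colony, nWorkers = 25, nDrones = 6, simParamBee = sp)
  expect_equal(nWorkers(colony), 25)
  expect_equal(nDrones(colony), 6)
  expect_true(isProductive(colony))

  before <- list(w = colony$workers$id, d = colony$drones$id)
  colony <- buildUp(colony, nWorkers = 25, nDrones = 6, simParamBee = sp)
  expect_identical(colony$workers$id, before$w) # top-up adds nothing
  expect_identical(colony$drones$id, before$d)

  vqCol <- createColony(baseVirginQueens(sim, 2)[2], simParamBee = sp)
  expect_error(buildUp(vqCol, simParamBee = sp), "mated queen")
})

test_that("swarm partitions workers and rears daughters in the remnant", {
  sim <- newTestSim(seed = 54, nVirginQueens = 4)
  sp <- sim$sp
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 30, nDrones = 6)
  queenId <- colony$queen$id
  workerIds <- colony$workers$id
  res <- swarm(colony, p = 0.4, simParamBee = sp)

  expect_equal(nWorkers(res$swarm), 12) # round(0.4 * 30)
  expect_equal(nWorkers(res$remnant), 18)
  expect_setequal(c(res$swarm$workers$id, res$remnant$workers$id), workerIds)
  expect_equal(res$swarm$queen$id, queenId)
  expect_equal(nDrones(res$swarm), 0)
  expect_equal(nDrones(res$remnant), 6)
  expect_equal(nQueens(res$remnant), 0)
  expect_gt(nVirginQueens(res$remnant), 0)
  expect_true(all(res$remnant$virginQueens$mother == queenId))
  expect_true(hasSwarmed(res$swarm) && hasSwarmed(res$remnant))
  expect_false(isProductive(res$swarm) || isProductive(res$remnant))
  # identity follows the queen; the remnant is a new hive
  expect_equal(res$swarm$id, colony$id)
  expect_false(res$remnant$id == colony$id)
  expect_error(swarm(colony, p = 1.5, simParamBee = sp), "within")
})

test_that("split keeps the queen productive and sends workers away", {
  sim <- newTestSim(seed = 55, nVirginQueens = 3)
  sp <- sim$sp
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 30, nDrones = 4)
  res <- split(colony, p = 0.3, simParamBee = sp)
  expect_equal(nWorkers(res$split), 9)
  expect_equal(nWorkers(res$remnant), 21)
  expect_equal(res$remnant$queen$id, colony$queen$id)
  expect_equal(res$remnant$id, colony$id)
  expect_equal(nDrones(res$remnant), 4)
  expect_true(isProductive(res$remnant)) # unchanged by the split
  expect_false(isProductive(res$split))
  expect_true(hasSplit(res$split) && hasSplit(res$remnant))
  expect_gt(nVirginQueens(res$split), 0)
  expect_true(all(res$split$virginQueens$mother == colony$queen$id))
})

test_that("supersede replaces the queen with her daughters", {
  sim <- newTestSim(seed = 56, nVirginQueens = 3)
  sp <- sim$sp
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 15, nDrones = 3)
  queenId <- colony$queen$id
  res <- supersede(colony, simParamBee = sp)
  expect_equal(nQueens(res), 0)
  expect_equal(nFathers(res), 0)
  expect_gt(nVirginQueens(res), 0)
  expect_true(all(res$virginQueens$mother == queenId))
  expect_true(isProductive(res)) # workers keep working
  expect_true(hasSuperseded(res))
  queenless <- createColony(baseVirginQueens(sim, 2)[2], simParamBee = sp)
  expect_error(supersede(queenless, simParamBee = sp), "queenless")
})

test_that("collapse freezes a colony but keeps its members countable", {
  sim <- newTestSim(seed = 57)
  sp <- sim$sp
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 12, nDrones = 3)
  dead <- collapse(colony)
  expect_true(hasCollapsed(dead))
  expect_false(isProductive(dead))
  expect_equal(nWorkers(dead), 12) # individuals stay for post-mortem study
  expect_equal(nDrones(dead), 3)
  expect_error(collapse(dead), "already collapsed")
  expect_error(buildUp(dead, simParamBee = sp), "not allowed")
  expect_error(swarm(dead, simParamBee = sp), "not allowed")
  expect_error(createWorkers(dead, 5, sp), "not allowed")
})

test_that("downsize removes a worker share plus all drones and virgin queens", {
  sim <- newTestSim(seed = 58)
  sp <- sim$sp
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 20, nDrones = 5)
  colony <- addCastePop(colony, "virginQueens", 2, simParamBee = sp)
  res <- downsize(colony, p = 0.85, simParamBee = sp)
  expect_equal(nWorkers(res), 3) # 20 - round(0.85 * 20)
  expect_equal(nDrones(res), 0)
  expect_equal(nVirginQueens(res), 0)
  expect_equal(res$queen$id, colony$queen$id) # the queen winters with the colony
  expect_false(isProductive(res))
})

test_that("combine merges the weak colony into the strong one", {
  sim <- newTestSim(seed = 59)
  sp <- sim$sp
  strong <- matedColony(sim, buildUp = TRUE, nWorkers = 20, nDrones = 4)
  weak <- matedColony(sim, buildUp = TRUE, nWorkers = 10, nDrones = 2)
  res <- combine(strong, weak)
  expect_equal(nWorkers(res), 30)
  expect_equal(nDrones(res), 6)
  expect_equal(res$queen$id, strong$queen$id)
  expect_equal(res$id, strong$id)
  expect_false(anyDuplicated(res$workers$id) > 0)
  expect_error(combine(strong, collapse(weak)), "not allowed")
})

test_that("reQueen installs a new head female", {
  sim <- newTestSim(seed = 60)
  sp <- sim$sp
  colony <- matedColony(sim, buildUp = TRUE, nWorkers = 10, nDrones = 2)
  donor <- matedColony(sim)
  res <- reQueen(colony, donor$queen, fathers = donor$fathers, simParamBee = sp)
  expect_equal(res$queen$id, donor$queen$id)
  expect_equal(nFathers(res), nFathers(donor))
  expect_equal(nVirginQueens(res), 0)

  vq <- baseVirginQueens(sim, 3)[3]
  res2 <- reQueen(colony, vq, simParamBee = sp)
  expect_equal(nQueens(res2), 0)
  expect_equal(res2$virginQueens$id, vq$id)

  workers <- getCastePop(colony, "workers")
  expect_error(reQueen(colony, workers[1], simParamBee = sp), "cannot requeen")
  expect_error(reQueen(collapse(colony), vq, simParamBee = sp), "not allowed")
})

test_that("worker conservation and flag algebra hold over random event traces", {
  sim <- newTestSim(seed = 61, nVirginQueens = 2)
  sp <- sim$sp
  set.seed(62)
  for (trace in 1:40) {
    colony <- matedColony(sim, buildUp = TRUE, nWorkers = sample(10:25, 1),
                          nDrones = 3)
    for (step in 1:3) {
      op <- sample(c("swarm", "split", "downsize", "supersede", "buildUp"), 1)
      before <- nWorkers(colony)
      if (op == "swarm") {
        res <- swarm(colony, simParamBee = sp)
        expect_equal(nWorkers(res$swarm) + nWorkers(res$remnant), before)
        expect_false(isProductive(res$swarm) || isProductive(res$remnant))
        colony <- res$swarm # the queen's colony continues
      } else if (op == "split") {
        res <- split(colony, simParamBee = sp)
        expect_equal(nWorkers(res$split) + nWorkers(res$remnant), before)
        expect_false(isProductive(res$split))
        colony <- res$remnant
      } else if (op == "downsize") {
        colony <- downsize(colony, simParamBee = sp)
        expect_false(isProductive(colony))
      } else if (op == "supersede") {
        colony <- supersede(colony, simParamBee = sp)
      } else {
        colony <- buildUp(colony, nWorkers = 15, nDrones = 3, simParamBee = sp)
        expect_true(isProductive(colony))
      }
      # a productive colony is never collapsed
      expect_false(isProductive(colony) && hasCollapsed(colony))
      if (nQueens(colony) == 0) break # supersedure/swarm left it queenless
    }
  }
})
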