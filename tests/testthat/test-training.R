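test_that("zero learning rate freezes the loss history", {
  ph <- generatePhantom(phantomParams(side = 16L, seed = 1L), 1)
  spec <- tinySpec(16L)  # no dropout/batch-norm: fully deterministic
  cfg <- trainingConfig(learningRate = 0, maxEpochs = 8L, patience = 3L,
                        seed = 1L)
  model <- trainModel(spec, list(ph), cfg)
  expect_true(all(abs(model@history - model@history[1]) < 1e-12))
  # constant loss trips the plateau rule after exactly `patience` epochs
  expect_length(model@history, 1 + 3)
})

test_that("the plateau rule fires exactly per its definition", {
  expect_equal(plateauEpoch(rep(1, 30), patience = 10), 11)
  expect_equal(plateauEpoch(rep(1, 30), patience = 3), 4)
  expect_true(is.na(plateauEpoch(seq(1, 0.1, by = -0.1), patience = 5)))
  # a spike creates non-improving epochs until a new best undercuts it
  tr <- c(1.0, 0.9, 0.8, 0.85, 0.83, 0.795, 0.81, 0.81)
  # bests: e3=0.8; e4,e5 wait; e6 improves (0.795); e7,e8 wait
  expect_equal(plateauEpoch(tr, patience = 2), 5)
  # the later best at e6 resets patience, so 3 never accumulates here
  expect_true(is.na(plateauEpoch(tr, patience = 3)))
  # min-delta: an improvement smaller than minDelta does not reset patience
  expect_equal(plateauEpoch(c(1, 1 - 5e-5, 1 - 6e-5), patience = 2,
                            minDelta = 1e-4), 3)
})

test_that("training reduces the loss on a small phantom", {
  ph <- generatePhantom(phantomParams(side = 16L, seed = 2L), 1)
  model <- trainModel(tinySpec(16L), list(ph),
                      trainingConfig(maxEpochs = 30L, patience = 30L,
                                     seed = 3L))
  expect_lt(tail(model@history, 1), model@history[1])
})

test_that("training run is reproducible under its seed", {
  ph <- generatePhantom(phantomParams(side = 16L, seed = 4L), 1)
  cfg <- trainingConfig(maxEpochs = 5L, patience = 5L, seed = 11L)
  m1 <- trainModel(tinySpec(16L), list(ph), cfg)
  m2 <- trainModel(tinySpec(16L), list(ph), cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@weights, m2@weights)
})

test_that("shape mismatches and empty sets are rejected", {
  ph <- generatePhantom(phantomParams(side = 32L, seed = 5L), 1)
  expect_error(trainModel(tinySpec(16L), list(ph)), "input side")
  expect_error(trainModel(tinySpec(16L), list()), "empty")
})

test_that("probability binarization handles boundary thresholds", {
  p <- matrix(0.9, 16, 16)
  expect_true(all(maskLabels(binarizeProbability(p, 0.5)) == 1))
  p2 <- matrix(runif(256, 0, 0.99), 16, 16)
  expect_true(all(maskLabels(binarizeProbability(p2, 1.0)) == 0))
})

test_that("LOO plans have exact cardinality and training sizes", {
  plan <- makeLooPlan(40, strategyNames(), groupSize = 40L)
  expect_equal(nLaunches(plan), 440)
  expect_true(all(launches(plan)$nTrain == 79))
  # per strategy, exactly one launch per original
  tab <- table(launches(plan)$strategy, launches(plan)$heldOutId)
  expect_true(all(tab == 1))
  expect_equal(nLaunches(makeLooPlan(2, "classic")), 2)
  expect_error(makeLooPlan(1, "classic"), "nOriginals")
  expect_error(makeLooPlan(40, character(0)), "strategy")
})

test_that("fold manifests are leakage-free", {
  ds <- generateDataset(6, phantomParams(side = 32L, seed = 6L))
  for (held in c("001", "004", "006")) {
    fold <- foldTrainingSet(ds, "classic", held, groupSize = 6L, seed = 2L)
    expect_equal(nrow(fold$manifest), 5 + 6)
    expect_false(any(fold$manifest$sourceId == held))
    expect_false(any(fold$manifest$id == held))
  }
  expect_error(foldTrainingSet(ds, "classic", "099", 6L), "not among")
})

test_that("runLoo produces one scored row per launch and resumes", {
  ds <- generateDataset(2, phantomParams(side = 16L, seed = 7L))
  plan <- makeLooPlan(2, "classic", groupSize = 2L)
  cfg <- trainingConfig(maxEpochs = 2L, patience = 2L, seed = 1L)
  outDir <- tempfile()
  res <- runLoo(plan, tinySpec(16L), ds, cfg, seed = 3L, outDir = outDir)
  expect_equal(nrow(res), 2)
  expect_true(all(res$dice >= 0 & res$dice <= 1, na.rm = TRUE))
  expect_true(all(res$tp + res$fp + res$tn + res$fn == 16 * 16))
  # cached results are reused verbatim
  t0 <- Sys.time()
  res2 <- runLoo(plan, tinySpec(16L), ds, cfg, seed = 3L, outDir = outDir)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  expect_equal(res2$dice, res$dice)
})
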