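test_that("splits have the documented sizes and are reproducible", {
  sim <- tinySimulation(n = 1000, seed = 1, nLabels = 2)
  sp <- splitMolecules(sim$molecules, seed = 4)
  expect_equal(vapply(sp, nMolecules, numeric(1)),
               c(train = 700, val = 150, test = 150))

  sim10 <- tinySimulation(n = 10, seed = 1, nLabels = 2)
  sp10 <- splitMolecules(sim10$molecules, seed = 4)
  expect_equal(vapply(sp10, nMolecules, numeric(1)),
               c(train = 7, val = 2, test = 1))
  expect_error(splitMolecules(sim10$molecules[1:5]), "at least 10")

  sp2 <- splitMolecules(sim$molecules, seed = 4)
  expect_identical(moleculeIds(sp2$train), moleculeIds(sp$train))
  expect_identical(moleculeIds(sp2$test), moleculeIds(sp$test))
})

test_that("splits are disjoint and exhaustive across random (n, seed) pairs", {
  set.seed(99)
  base <- tinySimulation(n = 400, seed = 2, nLabels = 2)$molecules
  for (k in 1:25) {
    n <- sample(10:400, 1)
    sd <- sample(1e6, 1)
    sp <- splitMolecules(base[seq_len(n)], seed = sd)
    ids <- c(moleculeIds(sp$train), moleculeIds(sp$val),
             moleculeIds(sp$test))
    expect_equal(sort(ids), sort(moleculeIds(base[seq_len(n)])))
    expect_equal(anyDuplicated(ids), 0)
  }
})

test_that("early stopping follows the patience rule exactly", {
  # no improvement after epoch 2 with patience 5: stop at epoch 7
  trace <- c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)
  for (ep in seq_along(trace)) {
    es <- admetfusion:::bestAndStop(trace[seq_len(ep)], patience = 5L)
    expect_equal(es$bestEpoch, if (ep == 1) 1L else 2L)
    expect_equal(es$stop, ep >= 7)
  }
  # strictly decreasing loss never stops early
  dec <- seq(1, 0.1, length.out = 30)
  expect_false(admetfusion:::bestAndStop(dec, 5L)$stop)
  expect_equal(admetfusion:::bestAndStop(dec, 5L)$bestEpoch, 30L)
})

test_that("training early-stops within budget and restores the best epoch", {
  sim <- tinySimulation(n = 200, seed = 6, nLabels = 3)
  splits <- splitMolecules(sim$molecules, seed = 6)
  stats <- fitNormalization(splits$train)
  splits <- lapply(splits, applyNormalization, stats = stats)
  tc <- TrainConfig(learningRate = 1e-2, maxEpochs = 30, patience = 5,
                    nSeeds = 1, seeds = 1L)
  rr <- trainFusionModel(ModelConfig("dnn", nLabels = 3), splits, tc,
                         seed = 1)
  expect_lte(rr@stopEpoch, 30)
  expect_lte(rr@bestEpoch, rr@stopEpoch)
  if (rr@stopEpoch < 30)
    expect_equal(rr@stopEpoch - rr@bestEpoch, 5)
  # restored weights reproduce the recorded best validation loss
  bdVal <- admetfusion:::makeBatchData(splits$val, rr@model)
  reLoss <- admetfusion:::evalLoss(rr@model, bdVal, tc)
  expect_equal(reLoss, rr@valLoss[rr@bestEpoch], tolerance = 1e-10)
  # losses are non-negative
  expect_true(all(rr@trainLoss >= 0) && all(rr@valLoss >= 0))

  # determinism: same seed, same trace
  rr2 <- trainFusionModel(ModelConfig("dnn", nLabels = 3), splits, tc,
                          seed = 1)
  expect_identical(rr2@valLoss, rr@valLoss)
})

test_that("a small network memorizes 32 molecules", {
  sim <- tinySimulation(n = 40, seed = 3, nLabels = 4, noise = 0)
  mol <- applyNormalization(sim$molecules, fitNormalization(sim$molecules))
  splits <- list(train = mol[1:32], val = mol[33:40])
  tc <- TrainConfig(learningRate = 1e-2, maxEpochs = 150, patience = 149L,
                    batchSize = 32)
  rr <- trainFusionModel(ModelConfig("dnn", headDepth = 2,
                                     activation = "relu", nLabels = 4),
                         splits, tc, seed = 1)
  expect_lt(tail(rr@trainLoss, 1), 0.05)
})

test_that("multi-seed replication aggregates and formats like the report", {
  sim <- tinySimulation(n = 150, seed = 8, nLabels = 2)
  splits <- splitMolecules(sim$molecules, seed = 8)
  stats <- fitNormalization(splits$train)
  splits <- lapply(splits, applyNormalization, stats = stats)
  tc <- TrainConfig(learningRate = 1e-2, maxEpochs = 8, patience = 4,
                    nSeeds = 2, seeds = c(1L, 2L))
  msr <- multiSeedRun(ModelConfig("dnn", nLabels = 2), splits, tc)
  expect_length(msr$runs, 2)
  expect_length(msr$auroc, 2)
  expect_equal(msr$mean, mean(msr$auroc))
  expect_match(msr$summary, "^\\d+\\.\\d \\(\\d+\\.\\d\\)$")

  # repeating one seed twice collapses the spread to zero
  tc0 <- TrainConfig(learningRate = 1e-2, maxEpochs = 8, patience = 4,
                     nSeeds = 2, seeds = c(1L, 1L))
  msr0 <- multiSeedRun(ModelConfig("dnn", nLabels = 2), splits, tc0)
  expect_equal(sd(msr0$auroc), 0)
  expect_match(formatMeanSD(c(0.823, 0.823)), "82.3 \\(0.0\\)")
})

test_that("degenerate training configurations are rejected", {
  expect_error(TrainConfig(patience = 30L, maxEpochs = 30L), "patience")
  expect_error(TrainConfig(nSeeds = 3L, seeds = 1L), "seeds")
  expect_error(TrainConfig(splitRatio = c(1, 2)), "3 entries")
})
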