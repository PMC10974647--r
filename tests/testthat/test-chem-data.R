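test_that("JSON records parse with filters excluded and unknowns warned", {
  dir <- withr::local_tempdir()
  f1 <- writeToyJSON(file.path(dir, "a.json"), "drug_b", "CCO")
  f2 <- writeToyJSON(file.path(dir, "b.json"), "drug_a", "CCN",
                     extraProps = list(lipinski_rule_of_five = TRUE))
  mol <- readMoleculeJSON(c(f1, f2))
  expect_equal(nMolecules(mol), 2)
  expect_equal(moleculeIds(mol), c("drug_a", "drug_b"))  # sorted by id
  expect_false("lipinski_rule_of_five" %in% colnames(featureTable(mol)))
  expect_equal(ncol(featureTable(mol)), 13)
  expect_equal(ncol(labelMatrix(mol)), 24)

  f3 <- writeToyJSON(file.path(dir, "c.json"), "drug_c", "CCC",
                     extraProps = list(mystery_descriptor = 1))
  expect_warning(readMoleculeJSON(f3), "mystery_descriptor")

  bad <- file.path(dir, "broken.json")
  writeLines("{not json", bad)
  expect_error(readMoleculeJSON(bad), "broken.json")
})

test_that("records with any missing feature are excluded, idempotently", {
  dir <- withr::local_tempdir()
  f1 <- writeToyJSON(file.path(dir, "a.json"), "a", "CCO")
  f2 <- writeToyJSON(file.path(dir, "b.json"), "b", "CCN", drop = "pka")
  f3 <- writeToyJSON(file.path(dir, "c.json"), "c", "CCS", drop = "logs")
  mol <- readMoleculeJSON(c(f1, f2, f3))
  expect_message(kept <- excludeIncomplete(mol), "dropped 2")
  expect_equal(moleculeIds(kept), "a")
  expect_silent(again <- excludeIncomplete(kept))
  expect_identical(moleculeIds(again), moleculeIds(kept))

  empty <- mol[integer(0)]
  expect_equal(nMolecules(excludeIncomplete(empty)), 0)

  sim <- tinySimulation(n = 100, nLabels = 21)
  expect_equal(nMolecules(excludeIncomplete(sim$molecules)), 100)
})

test_that("label merging reduces 24 raw labels to 21 finals with OR", {
  schema <- defaultFeatureSchema()
  expect_length(rawLabels(schema), 24)
  expect_length(finalLabels(schema), 21)

  dir <- withr::local_tempdir()
  f <- writeToyJSON(file.path(dir, "a.json"), "a", "CCO", labelValue = 0)
  mol <- readMoleculeJSON(f)
  lab <- labelMatrix(mol)
  lab[1, "human_intestinal_absorption"] <- 1
  lab[1, "caco2_permeability"] <- 0
  mol@labels <- lab
  merged <- mergeLabels(mol)
  expect_equal(ncol(labelMatrix(merged)), 21)
  expect_equal(unname(labelMatrix(merged)[1, "human_intestinal_absorption"]), 1)
  expect_equal(unname(labelMatrix(merged)[1, "p_glycoprotein_inhibitor"]), 0)
  expect_equal(unname(labelMatrix(merged)[1, "herg_inhibition"]), 0)

  # AND semantics are selectable
  molAnd <- mol
  molAnd@schema <- defaultFeatureSchema(mergeOp = "and")
  expect_equal(
    unname(labelMatrix(mergeLabels(molAnd))[1, "human_intestinal_absorption"]),
    0)

  # missing merge source is a hard error
  broken <- mol
  broken@labels <- lab[, setdiff(colnames(lab), "caco2_permeability"),
                       drop = FALSE]
  expect_error(mergeLabels(broken), "caco2_permeability")
})

test_that("normalization is fit on train only and applied exactly once", {
  sim <- tinySimulation(n = 120, nLabels = 4)
  splits <- splitMolecules(sim$molecules, seed = 2)
  stats <- fitNormalization(splits$train)
  trainN <- applyNormalization(splits$train, stats)
  num <- names(stats@center)
  X <- as.matrix(featureTable(trainN)[, num])
  expect_true(all(abs(colMeans(X)) < 1e-9))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-9))

  # no leakage: test-split means are not re-centred to zero
  testN <- applyNormalization(splits$test, stats)
  Xt <- as.matrix(featureTable(testN)[, num])
  expect_gt(max(abs(colMeans(Xt))), 1e-3)

  # double application differs from single application
  twice <- applyNormalization(trainN, stats)
  expect_false(isTRUE(all.equal(featureTable(twice), featureTable(trainN))))

  # degenerate fits are hard errors naming the offender
  expect_error(fitNormalization(sim$molecules[1]), "at least 2")
  const <- sim$molecules
  const@features$pka <- 7
  expect_error(fitNormalization(const), "pka")
})

test_that("tabular round trip preserves records", {
  sim <- tinySimulation(n = 25, nLabels = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  writeMoleculeTable(sim$molecules, path)
  back <- readMoleculeTable(path)
  expect_equal(moleculeIds(back), moleculeIds(sim$molecules))
  expect_equal(smilesStrings(back), smilesStrings(sim$molecules))
  expect_equal(as.matrix(featureTable(back)),
               as.matrix(featureTable(sim$molecules)), tolerance = 1e-12)
  expect_equal(labelMatrix(back), labelMatrix(sim$molecules))

  statsPath <- withr::local_tempfile(fileext = ".json")
  stats <- fitNormalization(sim$molecules)
  writeNormalizationStats(stats, statsPath)
  stats2 <- readNormalizationStats(statsPath)
  expect_equal(stats2@center, stats@center)
  expect_equal(stats2@scale, stats@scale)
})
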