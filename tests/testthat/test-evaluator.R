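test_that("threshold metrics reproduce hand-computed confusion counts", {
  # TP=2 FP=1 FN=2 TN=6: precision 2/3, recall 1/2, F1 the harmonic mean
  # 2*(2/3 * 1/2)/(2/3 + 1/2) = 4/7
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.2, 0.3, 0.7, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  m <- binaryMetrics(probs, labels)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 1 / 2)
  expect_equal(unname(m["f1"]), 4 / 7)
  expect_equal(unname(m["accuracy"]), 8 / 11)

  perfect <- binaryMetrics(labels, labels)
  expect_equal(unname(perfect[c("accuracy", "auroc", "f1", "precision",
                                "recall")]),
               rep(1, 5))

  # the imbalance pathology: an all-positive predictor on 99:1 labels
  lab99 <- c(rep(1, 99), 0)
  allPos <- binaryMetrics(rep(1, 100), lab99)
  expect_equal(unname(allPos["accuracy"]), 0.99)
  expect_equal(unname(allPos["recall"]), 1)

  # undefined ratios are reported as NA, never as 0
  noneCalled <- binaryMetrics(rep(0, 4), c(1, 0, 1, 0))
  expect_true(is.na(noneCalled["precision"]))
})

test_that("AUROC equals the concordant-pair probability", {
  expect_equal(aurocScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)

  # O(n^2) pair-counting oracle on random instances, ties counted half
  pairAUC <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  set.seed(42)
  for (k in 1:200) {
    n <- sample(4:50, 1)
    s <- round(runif(n), sample(1:2, 1))     # coarse grid forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(aurocScore(s, y), pairAUC(s, y), tolerance = 1e-12)
  }

  # rank invariance and the no-signal limit
  set.seed(1)
  s <- rnorm(500)
  y <- rbinom(500, 1, 0.5)
  expect_equal(aurocScore(s, y), aurocScore(plogis(3 * s), y))
  yBig <- rbinom(10000, 1, 0.5)
  expect_lt(abs(aurocScore(rnorm(10000), yBig) - 0.5), 0.02)
  expect_warning(a1 <- aurocScore(1:4, rep(1, 4)), "one class")
  expect_true(is.na(a1))
})

test_that("F1 relates to precision and recall as the harmonic mean", {
  set.seed(7)
  for (k in 1:50) {
    m <- binaryMetrics(runif(40), rbinom(40, 1, 0.4))
    if (anyNA(m[c("precision", "recall", "f1")])) next
    p <- m[["precision"]]; r <- m[["recall"]]
    expect_equal(m[["f1"]], 2 * p * r / (p + r), tolerance = 1e-12)
    expect_gte(m[["f1"]], 0)
    expect_lte(m[["f1"]], min(2 * p, 2 * r))
    if (abs(p - r) < 1e-12) expect_equal(m[["f1"]], p)
  }
})

test_that("ensemble voting majority and 3:3 tie-break reproduce the rules", {
  mk <- function(p) matrix(p, 1, 1, dimnames = list(NULL, "y"))
  # clear 4:2 majority wins regardless of probabilities
  clear <- lapply(c(0.9, 0.8, 0.7, 0.6, 0.1, 0.2), mk)
  expect_equal(as.vector(ensembleVote(clear)$calls), 1)
  # 3:3 tie, mean probability 0.61 -> positive
  tiePos <- lapply(c(0.9, 0.9, 0.86, 0.4, 0.4, 0.2), mk)
  expect_equal(mean(vapply(tiePos, as.vector, numeric(1))), 0.61)
  expect_equal(as.vector(ensembleVote(tiePos)$calls), 1)
  # 3:3 tie, mean probability 0.42 -> negative
  tieNeg <- lapply(c(0.8, 0.62, 0.6, 0.2, 0.2, 0.1), mk)
  expect_equal(mean(vapply(tieNeg, as.vector, numeric(1))), 0.42)
  expect_equal(as.vector(ensembleVote(tieNeg)$calls), 0)

  # order invariance and the identical-model reduction
  set.seed(5)
  mats <- lapply(1:6, function(i)
    matrix(runif(40), 10, 4, dimnames = list(NULL, letters[1:4])))
  ev1 <- ensembleVote(mats)
  ev2 <- ensembleVote(rev(mats))
  expect_identical(ev1$calls, ev2$calls)
  same <- lapply(1:6, function(i) mats[[1]])
  expect_identical(ensembleVote(same)$calls,
                   (mats[[1]] >= 0.5) * 1)
  expect_error(ensembleVote(list(mats[[1]], mats[[2]][1:5, ])),
               "mismatched shapes")
})

test_that("CYP450 aggregation reproduces the abundance-weighted scores", {
  cfg <- CypAggregationConfig()
  expect_equal(unname(cfg@weights), c(0.12, 0.04, 0.30))
  P <- rbind(c(1, 1, 0), c(0, 0, 1), c(0, 0, 0.9))
  colnames(P) <- c("cyp2c9", "cyp2d6", "cyp3a4")
  agg <- cypAggregate(P, cfg)
  expect_equal(agg$score[1], 0.16 / 0.46, tolerance = 1e-9)
  expect_equal(agg$score[2], 0.30 / 0.46, tolerance = 1e-9)
  expect_equal(agg$call[1:2], c(0, 1))

  direct <- cypAggregate(P, CypAggregationConfig(method = "cyp3a4_direct"))
  expect_equal(direct$score, P[, "cyp3a4"])
  expect_equal(direct$call[3], 1)

  # equal weights reduce to the plain mean; a one-hot weight to passthrough
  eq <- CypAggregationConfig(weights = c(cyp2c9 = 1, cyp2d6 = 1,
                                         cyp3a4 = 1))
  expect_equal(cypAggregate(P, eq)$score, rowMeans(P))
  oh <- CypAggregationConfig(weights = c(cyp2c9 = 0, cyp2d6 = 0,
                                         cyp3a4 = 1))
  expect_equal(cypAggregate(P, oh)$score, P[, "cyp3a4"])

  expect_error(cypAggregate(P[, 1:2], cfg), "cyp3a4")

  # the synthesis classifier learns a separable aggregation rule
  set.seed(9)
  n <- 300
  Ps <- cbind(cyp2c9 = runif(n), cyp2d6 = runif(n), cyp3a4 = runif(n))
  y <- as.numeric(Ps[, "cyp3a4"] > 0.5)
  syn <- cypAggregate(Ps, CypAggregationConfig(method = "dnn_synthesis"),
                      referenceLabels = y)
  expect_gt(aurocScore(syn$score, y), 0.95)
  expect_error(cypAggregate(Ps, CypAggregationConfig(
    method = "dnn_synthesis")), "referenceLabels")
})

test_that("matched proportion counts exact agreements", {
  expect_equal(matchedProportion(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(matchedProportion(c(1, 0, 1), c(0, 1, 0)), 0)
  calls <- c(rep(1, 53), rep(0, 31))
  ref <- c(rep(1, 53), rep(1, 31))
  expect_equal(round(matchedProportion(calls, ref), 3), 0.631)
  expect_error(matchedProportion(1:3, 1:4), "length")
})

test_that("metrics reports aggregate per-label values into macro means", {
  set.seed(11)
  probs <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  labels <- matrix(rbinom(60, 1, 0.5), 20, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  rep <- metricsReport(probs, labels)
  expect_equal(nrow(rep@perLabel), 3)
  expect_equal(rep@macro[["auroc"]], mean(rep@perLabel$auroc))
  expect_true(all(rep@macro >= 0 & rep@macro <= 1))
})
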