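# Shared tiny fixtures for the architecture tests.
fusionFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- tinySimulation(n = 30, seed = 5, nLabels = 4)
    mol <- applyNormalization(sim$molecules, fitNormalization(sim$molecules))
    vocab <- tinyVocab(smilesStrings(mol), vocabSize = 40)
    enc <- tinyEncoder(vocab, H = 8, layers = 1, heads = 2)
    cache <<- list(mol = mol, vocab = vocab, enc = enc)
    cache
  }
})

test_that("default configuration carries the reference dimensions", {
  cfg <- ModelConfig()
  expect_equal(fusedWidth(cfg), 30)
  expect_equal(cfg@hiddenSize, 768)
  expect_equal(concatWidth(cfg), 798)
  expect_equal(cfg@boolDim, 10)
  expect_equal(cfg@nLabels, 21)
  expect_equal(cfg@pipeHeadSize, 13)
  cfg64 <- ModelConfig("concat", hiddenSize = 64)
  expect_equal(concatWidth(cfg64), 94)
})

test_that("all six architectures emit valid, deterministic probabilities", {
  fx <- fusionFixture()
  for (arch in ARCHITECTURES) {
    cfg <- ModelConfig(arch, boolDim = 4, intDim = 4, floatDim = 4,
                       hiddenSize = 8, nLabels = 4)
    m <- buildFusionModel(cfg, encoder = fx$enc, seed = 7)
    pm <- predictFusion(m, fx$mol)
    expect_equal(dim(pm@probs), c(30, 4))
    expect_true(all(pm@probs > 0 & pm@probs < 1))
    pm2 <- predictFusion(m, fx$mol)
    expect_identical(pm@probs, pm2@probs)
    # closed-form parameter count matches the actual tree
    expect_equal(admetfusion:::nParams(m@params),
                 countFusionParams(cfg))
  }
})

test_that("a zero output head predicts exactly 0.5 everywhere", {
  fx <- fusionFixture()
  cfg <- ModelConfig("dnn", nLabels = 4)
  m <- buildFusionModel(cfg, seed = 1)
  m@params$head[[1]]$W[] <- 0
  m@params$head[[1]]$b[] <- 0
  pm <- predictFusion(m, fx$mol)
  expect_true(all(pm@probs == 0.5))
})

test_that("zeroing the encoder branch reduces concat to the DNN function", {
  fx <- fusionFixture()
  ccfg <- ModelConfig("concat", boolDim = 4, intDim = 4, floatDim = 4,
                      hiddenSize = 8, nLabels = 4)
  mc <- buildFusionModel(ccfg, encoder = fx$enc, seed = 7)
  W <- fusedWidth(ccfg)
  mc@params$head[[1]]$W[(W + 1):(W + 8), ] <- 0
  dcfg <- ModelConfig("dnn", boolDim = 4, intDim = 4, floatDim = 4,
                      hiddenSize = 8, nLabels = 4)
  md <- buildFusionModel(dcfg, seed = 1)
  md@params$emb <- mc@params$emb
  md@params$intProj <- mc@params$intProj
  md@params$floatProj <- mc@params$floatProj
  md@params$head[[1]]$W <- mc@params$head[[1]]$W[1:W, , drop = FALSE]
  md@params$head[[1]]$b <- mc@params$head[[1]]$b
  expect_equal(predictFusion(mc, fx$mol)@probs,
               predictFusion(md, fx$mol)@probs, tolerance = 1e-12)
})

test_that("pipe composes: oracle stage-1 features reproduce the DNN", {
  fx <- fusionFixture()
  pcfg <- ModelConfig("pipe", boolDim = 4, intDim = 4, floatDim = 4,
                      hiddenSize = 8, nLabels = 4)
  mp <- buildFusionModel(pcfg, encoder = fx$enc, seed = 7)
  pm <- predictFusion(mp, fx$mol)
  expect_equal(dim(attr(pm, "stage1")), c(30, 13))
  expect_equal(dim(pm@probs), c(30, 4))
  # inject the true features into stage 2 by copying its weights into a
  # plain DNN: predictions must coincide exactly
  dcfg <- ModelConfig("dnn", boolDim = 4, intDim = 4, floatDim = 4,
                      hiddenSize = 8, nLabels = 4)
  md <- buildFusionModel(dcfg, seed = 1)
  md@params$emb <- mp@params$emb
  md@params$intProj <- mp@params$intProj
  md@params$floatProj <- mp@params$floatProj
  md@params$head <- mp@params$head
  bd <- admetfusion:::makeBatchData(fx$mol, md)
  b <- admetfusion:::sliceBatch(bd, 1:30)
  direct <- admetfusion:::fusionForward(md, b)$probs
  # now force stage 1 of the pipe to output those same features
  bp <- admetfusion:::makeBatchData(fx$mol, mp)
  bps <- admetfusion:::sliceBatch(bp, 1:30)
  fwp <- admetfusion:::fusionForward(mp, bps, needCache = TRUE)
  grp <- admetfusion:::dnnGroupsFwd(mp@params, b$xb, b$xi, b$xf)
  fused <- cbind(grp$eb, grp$gi, grp$gf)
  viaPipe <- admetfusion:::sigmoidStable(
    admetfusion:::headFwd(fused, mp@params$head, "none")$y)
  expect_equal(viaPipe, direct, tolerance = 1e-12)
})

test_that("fusion gradients match finite differences (incl. pipe end-to-end)", {
  fx <- fusionFixture()
  for (arch in c("dnn", "concat", "pipe", "dnn_a", "pipe_a")) {
    cfg <- ModelConfig(arch, boolDim = 4, intDim = 4, floatDim = 4,
                       hiddenSize = 8, nLabels = 4, headDepth = 2)
    model <- buildFusionModel(cfg, encoder = fx$enc, seed = 9)
    bd <- admetfusion:::makeBatchData(fx$mol, model)
    b <- admetfusion:::sliceBatch(bd, 1:8)
    lossOf <- function(m) {
      fw <- admetfusion:::fusionForward(m, b)
      admetfusion:::batchLoss(m, b, fw, 1)$loss
    }
    fw <- admetfusion:::fusionForward(model, b, needCache = TRUE)
    bl <- admetfusion:::batchLoss(model, b, fw, 1)
    bw <- admetfusion:::fusionBackward(model, b, fw, bl$dLogits,
                                       bl$dStage1)
    paths <- list(list("head", 1L, "W"), list("emb"),
                  list("intProj", "W"))
    if (arch %in% c("pipe", "pipe_a"))
      paths <- c(paths, list(list("stage1", "W")))
    for (p in paths) {
      err <- fdCheck(model@params, bw$fusion, p, function(pp) {
        m2 <- model
        m2@params <- pp
        lossOf(m2)
      })
      expect_lt(err, 1e-4)
    }
    if (!is.null(bw$encoder)) {
      err <- fdCheck(fx$enc@params, bw$encoder,
                     list("layers", 1L, "Wq", "W"), function(pp) {
        m2 <- model
        m2@encoder@params <- pp
        lossOf(m2)
      })
      expect_lt(err, 1e-4)
    }
  }
})

test_that("self-attention weights behave like a softmax over three groups", {
  set.seed(3)
  g <- matrix(rnorm(50), 5, 10)
  ab <- admetfusion:::attentionBlockFwd(list(g, g, g))
  # identical Q=K=V group vectors give uniform 1/3 attention
  expect_equal(as.vector(ab$A), rep(1 / 3, 5 * 9), tolerance = 1e-12)
  # weights sum to 1 per query
  g2 <- list(matrix(rnorm(50), 5), matrix(rnorm(50), 5),
             matrix(rnorm(50), 5))
  ab2 <- admetfusion:::attentionBlockFwd(g2)
  for (i in 1:3)
    expect_equal(rowSums(ab2$A[, i, ]), rep(1, 5), tolerance = 1e-12)
  # a dominant group saturates the softmax: its weight tends to 1
  g3 <- list(matrix(abs(rnorm(50)) * 100, 5), matrix(rnorm(50), 5) * 0.01,
             matrix(rnorm(50), 5) * 0.01)
  ab3 <- admetfusion:::attentionBlockFwd(g3)
  expect_true(all(ab3$A[, 1, 1] > 0.999))
  # outputs pass through tanh: bounded in (-1, 1)
  expect_true(all(abs(ab2$out[[1]]) < 1))
})

test_that("architecture preconditions are enforced", {
  fx <- fusionFixture()
  expect_error(buildFusionModel(ModelConfig("encoder", hiddenSize = 8)),
               "requires an encoder")
  expect_error(buildFusionModel(ModelConfig("concat", hiddenSize = 16),
                                encoder = fx$enc), "hidden size")
  expect_error(buildFusionModel(ModelConfig("dnn_a", boolDim = 4,
                                            intDim = 6, floatDim = 4)),
               "equal group widths")
  expect_error(ModelConfig("transformerXL"), "unknown architecture")
})
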