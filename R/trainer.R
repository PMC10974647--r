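## Training protocol: 7:1.5:1.5 splits, summed per-label binary
## cross-entropy (plus MSE on the pipe's stage-1 numeric targets), AdamW,
## early stopping on validation loss with patience 5, at most 30 epochs,
## five-seed replication.

#' Split a molecule set into train/validation/test
#'
#' Membership is a seeded shuffle. The validation size rounds half-up,
#' the test size rounds down, and the training split takes the remainder
#' (so n = 1000 under 7:1.5:1.5 gives 700/150/150, and n = 10 gives
#' 7/2/1).
#'
#' @param mol a [MoleculeSet-class] with at least 10 records.
#' @param ratio numeric(3) train/val/test fractions (normalized to sum 1).
#' @param seed integer shuffle seed.
#' @return named list of three disjoint, exhaustive [MoleculeSet-class]
#'   objects: `train`, `val`, `test`.
#' @export
splitMolecules <- function(mol, ratio = c(7, 1.5, 1.5) / 10, seed = 1L) {
  n <- nMolecules(mol)
  if (n < 10L) stop("splitMolecules: need at least 10 records, got ", n)
  ratio <- ratio / sum(ratio)
  nVal <- floor(n * ratio[2] + 0.5)
  nTest <- floor(n * ratio[3])
  nTrain <- n - nVal - nTest
  set.seed(deriveSeed(seed, 41L))
  ord <- sample.int(n)
  list(train = mol[ord[seq_len(nTrain)]],
       val = mol[ord[nTrain + seq_len(nVal)]],
       test = mol[ord[nTrain + nVal + seq_len(nTest)]])
}

## Total loss for one forward pass: summed per-label BCE (mean over the
## batch) plus, for pipe architectures, the stage-1 feature losses.
batchLoss <- function(model, batch, fw, pipeLossWeight) {
  bce <- bceWithLogits(fw$logits, batch$y)
  loss <- bce$loss
  dStage1 <- NULL
  if (!is.null(fw$stage1) && !is.null(batch$featTarget)) {
    tgt <- batch$featTarget
    numCols <- 2:ncol(tgt)
    mse <- mseLoss(fw$stage1[, numCols, drop = FALSE],
                   tgt[, numCols, drop = FALSE])
    pb <- pmin(pmax(fw$stage1[, 1], 1e-7), 1 - 1e-7)
    yb <- tgt[, 1]
    bloss <- -mean(yb * log(pb) + (1 - yb) * log(1 - pb))
    loss <- loss + pipeLossWeight * (mse$loss + bloss)
    dStage1 <- matrix(0, nrow(tgt), ncol(tgt))
    dStage1[, numCols] <- pipeLossWeight * mse$dPred
    ## d/dp of mean BCE on the probability scale; fusionBackward applies
    ## the sigmoid jacobian
    dStage1[, 1] <- pipeLossWeight * (-(yb / pb) + (1 - yb) / (1 - pb)) /
      length(yb)
  }
  list(loss = loss, dLogits = bce$dLogits, dStage1 = dStage1)
}

evalLoss <- function(model, bd, trainConfig, batchSize = 128L) {
  n <- bd$n
  tot <- 0
  for (idx in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    b <- sliceBatch(bd, idx)
    fw <- fusionForward(model, b)
    tot <- tot + batchLoss(model, b, fw, trainConfig@pipeLossWeight)$loss *
      length(idx)
  }
  tot / n
}

## Early-stopping rule on a validation-loss trace: the best epoch is the
## first strict minimum; training stops once `patience` epochs have
## passed without improvement.
bestAndStop <- function(valLoss, patience) {
  best <- which.min(valLoss)
  list(bestEpoch = as.integer(best),
       stop = length(valLoss) - best >= patience)
}

rebuildModel <- function(model, pars) {
  enc <- model@encoder
  if (!is.null(enc) && !is.null(pars$encoder))
    enc <- new("SmilesEncoder", config = enc@config, vocab = enc@vocab,
               params = pars$encoder, vocabHash = enc@vocabHash)
  new("FusionModel", config = model@config, params = pars$fusion,
      encoder = enc)
}

#' Train one fusion model
#'
#' Minimizes summed per-label binary cross-entropy (plus the pipe
#' stage-1 MSE/BCE terms weighted by `pipeLossWeight`) with AdamW. Early
#' stopping fires when the validation loss has not improved for
#' `patience` epochs; the best-validation weights are restored. A
#' non-finite loss aborts with a diagnostic.
#'
#' @param config a [ModelConfig-class].
#' @param splits list with `train` and `val` [MoleculeSet-class] objects
#'   (normalized features).
#' @param trainConfig a [TrainConfig-class].
#' @param seed integer seed (initialization and batch order).
#' @param encoder optional [SmilesEncoder-class] for encoder-based
#'   architectures.
#' @return A [RunRecord-class].
#' @export
trainFusionModel <- function(config, splits, trainConfig = TrainConfig(),
                             seed = 1L, encoder = NULL) {
  schema <- featureSchema(splits$train)
  model <- buildFusionModel(config, encoder = encoder,
                            nInt = length(schema@intFeatures),
                            nFloat = length(schema@floatFeatures),
                            seed = seed)
  trainEnc <- !is.null(model@encoder) && !trainConfig@freezeEncoder
  pars <- list(fusion = model@params)
  if (trainEnc) pars$encoder <- model@encoder@params
  state <- adamwInit(pars)
  bdTrain <- makeBatchData(splits$train, model)
  bdVal <- makeBatchData(splits$val, model)
  n <- bdTrain$n
  set.seed(deriveSeed(seed, 42L))
  trainLoss <- numeric(0)
  valLoss <- numeric(0)
  bestEpoch <- 0L
  bestPars <- pars
  for (ep in seq_len(trainConfig@maxEpochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / trainConfig@batchSize))
    epLoss <- 0
    for (idx in batches) {
      b <- sliceBatch(bdTrain, idx)
      cur <- rebuildModel(model, pars)
      fw <- fusionForward(cur, b, needCache = TRUE)
      bl <- batchLoss(cur, b, fw, trainConfig@pipeLossWeight)
      if (!is.finite(bl$loss))
        stop("trainFusionModel: non-finite loss at epoch ", ep,
             " (architecture ", config@architecture, ")")
      bw <- fusionBackward(cur, b, fw, bl$dLogits, bl$dStage1)
      grads <- list(fusion = bw$fusion)
      if (trainEnc) grads$encoder <- bw$encoder
      upd <- adamwStep(pars, grads, state, lr = trainConfig@learningRate,
                       weightDecay = trainConfig@weightDecay)
      pars <- upd$params
      state <- upd$state
      epLoss <- epLoss + bl$loss * length(idx)
    }
    trainLoss[ep] <- epLoss / n
    valLoss[ep] <- evalLoss(rebuildModel(model, pars), bdVal, trainConfig)
    es <- bestAndStop(valLoss, trainConfig@patience)
    if (es$bestEpoch == ep) {
      bestEpoch <- ep
      bestPars <- pars
    }
    if (es$stop) break
  }
  new("RunRecord", seed = as.integer(seed), trainLoss = trainLoss,
      valLoss = valLoss, bestEpoch = bestEpoch,
      stopEpoch = length(valLoss), model = rebuildModel(model, bestPars),
      testMetrics = list())
}

#' Multi-seed replication of a training run
#'
#' Trains the same architecture on the same splits once per seed
#' (independent initializations and batch orders), evaluates each run on
#' the test split, and reports per-seed macro AUROC with the
#' "mean (sd)" summary string used for reporting.
#'
#' @param config a [ModelConfig-class].
#' @param splits list with `train`, `val`, `test` [MoleculeSet-class]
#'   objects.
#' @param trainConfig a [TrainConfig-class]; its `seeds` are used.
#' @param encoder optional shared pre-trained [SmilesEncoder-class].
#' @return list with `runs` (list of [RunRecord-class]), `auroc`
#'   (per-seed macro AUROC), `mean`, `sd` and `summary` (e.g.
#'   `"82.3 (0.9)"`).
#' @export
multiSeedRun <- function(config, splits, trainConfig = TrainConfig(),
                         encoder = NULL) {
  runs <- lapply(trainConfig@seeds, function(s) {
    rr <- trainFusionModel(config, splits, trainConfig, seed = s,
                           encoder = encoder)
    pm <- predictFusion(rr@model, splits$test)
    rep <- metricsReport(pm, labelMatrix(splits$test))
    rr@testMetrics <- list(report = rep, predictions = pm)
    rr
  })
  auc <- vapply(runs, function(r) r@testMetrics$report@macro[["auroc"]],
                numeric(1))
  list(runs = runs, auroc = auc, mean = mean(auc), sd = sd(auc),
       summary = formatMeanSD(auc))
}

#' Format replicate values as "mean (sd)" on the percent scale
#'
#' @param x numeric vector of values in `[0,1]`.
#' @param digits decimal places.
#' @return character scalar, e.g. `"82.3 (0.9)"`.
#' @export
formatMeanSD <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
          mean(x) * 100, (if (length(x) > 1) sd(x) else 0) * 100)
}
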