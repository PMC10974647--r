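## Per-label evaluation metrics, six-model ensemble voting with the 3:3
## tie-break, and the three CYP450-substrate aggregation methods.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a random positive scores above a random
#' negative, with ties counted one half; computed from average ranks.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric predictions (any monotone scale).
#' @param labels binary 0/1 vector.
#' @return numeric in `[0,1]`, or `NA` (with a warning) when only one
#'   class is present.
#' @examples
#' aurocScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
aurocScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("aurocScore: only one class present; AUROC undefined")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based binary classification metrics for one label
#'
#' Confusion counts at `threshold` give accuracy, precision, recall and
#' F1; AUROC is threshold-free. Ratios with zero denominators are
#' reported as `NA`, not 0.
#'
#' @param probs numeric predicted probabilities.
#' @param labels binary 0/1 vector.
#' @param threshold decision threshold.
#' @return named numeric: n, prevalence, accuracy, auroc, f1, precision,
#'   recall.
#' @export
binaryMetrics <- function(probs, labels, threshold = 0.5) {
  keep <- !is.na(probs) & !is.na(labels)
  probs <- probs[keep]; labels <- labels[keep]
  pred <- as.numeric(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  n <- tp + fp + fn + tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  auroc <- if (sum(labels == 1) > 0 && sum(labels == 0) > 0)
    aurocScore(probs, labels) else NA_real_
  c(n = n, prevalence = mean(labels == 1),
    accuracy = if (n > 0) (tp + tn) / n else NA_real_,
    auroc = auroc, f1 = f1, precision = precision, recall = recall)
}

#' Per-label metrics report for a prediction matrix
#'
#' @param predictions a [PredictionMatrix-class] or probability matrix.
#' @param labels binary label matrix aligned with the predictions.
#' @param threshold decision threshold.
#' @return A [MetricsReport-class]; macro means are taken over labels
#'   with defined values.
#' @export
metricsReport <- function(predictions, labels, threshold = 0.5) {
  probs <- if (is(predictions, "PredictionMatrix")) predictions@probs
           else as.matrix(predictions)
  stopifnot(nrow(probs) == nrow(labels), ncol(probs) == ncol(labels))
  per <- t(vapply(seq_len(ncol(probs)), function(j)
    suppressWarnings(binaryMetrics(probs[, j], labels[, j], threshold)),
    numeric(7)))
  per <- as.data.frame(per)
  per$label <- if (!is.null(colnames(probs))) colnames(probs) else
    sprintf("label_%d", seq_len(ncol(probs)))
  per <- per[, c("label", "n", "prevalence", "accuracy", "auroc", "f1",
                 "precision", "recall")]
  macro <- vapply(c("accuracy", "auroc", "f1", "precision", "recall"),
                  function(m) mean(per[[m]], na.rm = TRUE), numeric(1))
  new("MetricsReport", perLabel = per, macro = macro)
}

#' Majority vote over model predictions with mean-probability tie-break
#'
#' Each model's probability is binarized at `threshold`; the majority
#' call wins per cell. When the vote is tied (e.g. 3:3 with six models),
#' the cell's final value is 1 exactly when the mean of the models'
#' probabilities reaches `threshold`. Invariant to model ordering; with
#' identical models it reduces to thresholding.
#'
#' @param predictions list of [PredictionMatrix-class] objects (or plain
#'   matrices) with identical shapes and label order.
#' @param threshold decision threshold.
#' @return list with `calls` (binary matrix), `meanProbs` and `votes`.
#' @export
ensembleVote <- function(predictions, threshold = 0.5) {
  mats <- lapply(predictions, function(p)
    if (is(p, "PredictionMatrix")) p@probs else as.matrix(p))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ensembleVote: prediction matrices have mismatched shapes")
  labs <- lapply(mats, colnames)
  if (!all(vapply(labs, identical, logical(1), labs[[1]])))
    stop("ensembleVote: label order differs across models")
  k <- length(mats)
  votes <- Reduce(`+`, lapply(mats, function(m) (m >= threshold) * 1))
  meanProbs <- Reduce(`+`, mats) / k
  calls <- (votes > k / 2) * 1
  tie <- votes == k / 2
  calls[tie] <- (meanProbs[tie] >= threshold) * 1
  list(calls = calls, meanProbs = meanProbs, votes = votes)
}

#' Fraction of exactly matching binary calls
#'
#' @param calls,reference aligned binary vectors.
#' @return numeric in `[0,1]`.
#' @export
matchedProportion <- function(calls, reference) {
  if (length(calls) != length(reference))
    stop("matchedProportion: length mismatch")
  mean(calls == reference)
}

## Tiny MLP (3 -> 8 -> 1, tanh hidden) used by the dnn_synthesis
## aggregation; trained full-batch with AdamW and patience-5 early
## stopping on a held-out 15% of the rows.
trainSynthesisNet <- function(X, y, seed = 1L, maxEpochs = 200L,
                              patience = 5L, lr = 1e-2) {
  set.seed(deriveSeed(seed, 51L))
  n <- nrow(X)
  nVal <- max(1L, floor(0.15 * n))
  ord <- sample.int(n)
  vi <- ord[seq_len(nVal)]
  ti <- ord[-seq_len(nVal)]
  pars <- list(W1 = initLinear(ncol(X), 8L), W2 = initLinear(8L, 1L))
  state <- adamwInit(pars)
  fwd <- function(p, x) {
    h <- tanh(linFwd(x, p$W1))
    list(h = h, z = linFwd(h, p$W2))
  }
  best <- Inf; bestPars <- pars; bestEp <- 0L
  for (ep in seq_len(maxEpochs)) {
    f <- fwd(pars, X[ti, , drop = FALSE])
    bl <- bceWithLogits(f$z, matrix(y[ti], ncol = 1))
    b2 <- linBwd(bl$dLogits, f$h, pars$W2)
    dh <- b2$dx * (1 - f$h^2)
    b1 <- linBwd(dh, X[ti, , drop = FALSE], pars$W1)
    upd <- adamwStep(pars, list(W1 = b1$grad, W2 = b2$grad), state, lr = lr)
    pars <- upd$params; state <- upd$state
    vf <- fwd(pars, X[vi, , drop = FALSE])
    vl <- bceWithLogits(vf$z, matrix(y[vi], ncol = 1))$loss
    if (vl < best) { best <- vl; bestPars <- pars; bestEp <- ep }
    if (ep - bestEp >= patience) break
  }
  bestPars
}

#' Aggregate CYP450 subtype substrate predictions to one substrate call
#'
#' Three methods: `dnn_synthesis` trains a small classifier mapping the
#' concatenated subtype probabilities to one logit (requires reference
#' labels); `cyp3a4_direct` uses the 3A4 probability as the call;
#' `weighted_soft_vote` scores each molecule with the abundance-weighted
#' mean of the subtype probabilities (weights 2C9 = 0.12, 2D6 = 0.04,
#' 3A4 = 0.30, normalized by their sum so scores stay in `[0,1]`).
#'
#' @param subtypeProbs matrix or data.frame with one column per subtype;
#'   column names must cover `names(config@weights)`.
#' @param config a [CypAggregationConfig-class].
#' @param referenceLabels binary vector, required for `dnn_synthesis`
#'   (training target).
#' @param seed seed for the synthesis classifier.
#' @return list with `score` (numeric, AUROC-ready) and `call` (0/1 at
#'   the config threshold).
#' @examples
#' cfg <- CypAggregationConfig()
#' p <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3,
#'             dimnames = list(NULL, c("cyp2c9", "cyp2d6", "cyp3a4")))
#' cypAggregate(p, cfg)$score  # 0.348 and 0.652 (weighted means)
#' @export
cypAggregate <- function(subtypeProbs, config = CypAggregationConfig(),
                         referenceLabels = NULL, seed = 1L) {
  P <- as.matrix(subtypeProbs)
  need <- names(config@weights)
  miss <- setdiff(need, colnames(P))
  if (length(miss))
    stop("cypAggregate: missing subtype column(s): ",
         paste(miss, collapse = ", "))
  P <- P[, need, drop = FALSE]
  score <- switch(config@method,
    weighted_soft_vote =
      as.vector(P %*% config@weights) / sum(config@weights),
    cyp3a4_direct = P[, grep("3a4", need, value = TRUE)[1]],
    dnn_synthesis = {
      if (is.null(referenceLabels))
        stop("cypAggregate: dnn_synthesis needs referenceLabels to train on")
      pars <- trainSynthesisNet(P, referenceLabels, seed = seed)
      as.vector(sigmoidStable(linFwd(tanh(linFwd(P, pars$W1)), pars$W2)))
    })
  list(score = score, call = as.numeric(score >= config@threshold))
}
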