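## Transformer encoder over BPE-tokenized SMILES, with a RoBERTa-style
## masked-language-model pretraining objective. Forward and backward
## passes are explicit; token batches use the layout row = (b-1)*T + t so
## each sequence occupies a contiguous block of rows.

initEncoderParams <- function(config) {
  H <- config@hiddenSize
  Fw <- config@ffSize
  V <- config@vocabSize
  layers <- lapply(seq_len(config@nLayers), function(l) list(
    Wq = initLinear(H, H), Wk = initLinear(H, H), Wv = initLinear(H, H),
    Wo = initLinear(H, H),
    ln1 = list(g = rep(1, H), b = rep(0, H)),
    ff1 = initLinear(H, Fw), ff2 = initLinear(Fw, H),
    ln2 = list(g = rep(1, H), b = rep(0, H))))
  list(tokEmb = matrix(rnorm(V * H, 0, 0.02), V, H),
       posEmb = matrix(rnorm(config@maxLen * H, 0, 0.02), config@maxLen, H),
       lnE = list(g = rep(1, H), b = rep(0, H)),
       layers = layers,
       mlmHead = initLinear(H, V))
}

#' Initialize a SMILES transformer encoder
#'
#' @param config an [EncoderConfig-class] (its `vocabSize` must match the
#'   vocabulary).
#' @param vocab a [TokenVocab-class].
#' @param seed integer seed for weight initialization.
#' @return A [SmilesEncoder-class] with random weights.
#' @export
initEncoder <- function(config, vocab, seed = 1L) {
  if (config@vocabSize != vocabSize(vocab))
    stop("initEncoder: config vocabSize (", config@vocabSize,
         ") does not match vocabulary (", vocabSize(vocab), ")")
  set.seed(deriveSeed(seed, 11L))
  new("SmilesEncoder", config = config, vocab = vocab,
      params = initEncoderParams(config), vocabHash = vocabHash(vocab))
}

## Forward pass. ids/mask: B x T (0-based ids). Returns pooled B x H,
## hidden (B*T) x H, and (optionally) the caches needed for backward.
encForward <- function(params, config, ids, mask, needCache = FALSE) {
  B <- nrow(ids)
  Tn <- ncol(ids)
  H <- config@hiddenSize
  nh <- config@nHeads
  dh <- H / nh
  flat <- as.vector(t(ids)) + 1L                  # row = (b-1)*T + t
  X0 <- params$tokEmb[flat, , drop = FALSE] +
    params$posEmb[rep(seq_len(Tn), B), , drop = FALSE]
  lnEc <- layerNormFwd(X0, params$lnE$g, params$lnE$b)
  X <- lnEc$y
  keyBias <- t(apply(mask, 1, function(m) ifelse(m == 1, 0, -1e9)))
  caches <- if (needCache) vector("list", config@nLayers)
  for (l in seq_len(config@nLayers)) {
    lp <- params$layers[[l]]
    Q <- linFwd(X, lp$Wq); K <- linFwd(X, lp$Wk); V <- linFwd(X, lp$Wv)
    Ctx <- matrix(0, B * Tn, H)
    Al <- if (needCache) vector("list", B * nh)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      kb <- keyBias[b, ]
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dh)
        S <- sweep(S, 2, kb, `+`)
        A <- softmaxRows(S)
        Ctx[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
        if (needCache) Al[[(b - 1L) * nh + h]] <- A
      }
    }
    O <- linFwd(Ctx, lp$Wo)
    R1 <- X + O
    ln1c <- layerNormFwd(R1, lp$ln1$g, lp$ln1$b)
    X1 <- ln1c$y
    F1 <- linFwd(X1, lp$ff1)
    G <- geluFwd(F1)
    F2 <- linFwd(G, lp$ff2)
    R2 <- X1 + F2
    ln2c <- layerNormFwd(R2, lp$ln2$g, lp$ln2$b)
    if (needCache)
      caches[[l]] <- list(Xin = X, Q = Q, K = K, V = V, A = Al, Ctx = Ctx,
                          ln1 = ln1c, X1 = X1, F1 = F1, G = G, ln2 = ln2c)
    X <- ln2c$y
  }
  clsRows <- (seq_len(B) - 1L) * Tn + 1L
  pooled <- if (config@pooling == "cls") {
    X[clsRows, , drop = FALSE]
  } else {
    mw <- mask / rowSums(mask)
    out <- matrix(0, B, H)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      out[b, ] <- colSums(X[rows, , drop = FALSE] * mw[b, ])
    }
    out
  }
  list(hidden = X, pooled = pooled, B = B, Tn = Tn,
       caches = caches, lnE = if (needCache) lnEc, flat = flat,
       mask = mask)
}

## Map a gradient on the pooled vector (B x H) to one on the full hidden
## state ((B*T) x H).
poolBackward <- function(dPooled, fw, config) {
  B <- fw$B; Tn <- fw$Tn
  dX <- matrix(0, B * Tn, config@hiddenSize)
  if (config@pooling == "cls") {
    dX[(seq_len(B) - 1L) * Tn + 1L, ] <- dPooled
  } else {
    mw <- fw$mask / rowSums(fw$mask)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      dX[rows, ] <- outer(mw[b, ], dPooled[b, ])
    }
  }
  dX
}

## Backward pass from a gradient dX on the top hidden state. Returns the
## parameter-gradient tree (same shape as params).
encBackward <- function(params, config, fw, dX) {
  B <- fw$B; Tn <- fw$Tn
  H <- config@hiddenSize; nh <- config@nHeads; dh <- H / nh
  grads <- zerosLike(params)
  for (l in rev(seq_len(config@nLayers))) {
    lp <- params$layers[[l]]
    cc <- fw$caches[[l]]
    g2 <- layerNormBwd(dX, cc$ln2, lp$ln2$g)
    grads$layers[[l]]$ln2 <- g2$grad
    dR2 <- g2$dx
    dF2 <- dR2
    bw2 <- linBwd(dF2, cc$G, lp$ff2)
    grads$layers[[l]]$ff2 <- bw2$grad
    dG <- bw2$dx
    dF1 <- geluBwd(dG, cc$F1)
    bw1 <- linBwd(dF1, cc$X1, lp$ff1)
    grads$layers[[l]]$ff1 <- bw1$grad
    dX1 <- dR2 + bw1$dx
    g1 <- layerNormBwd(dX1, cc$ln1, lp$ln1$g)
    grads$layers[[l]]$ln1 <- g1$grad
    dR1 <- g1$dx
    bwo <- linBwd(dR1, cc$Ctx, lp$Wo)
    grads$layers[[l]]$Wo <- bwo$grad
    dCtx <- bwo$dx
    dQ <- matrix(0, B * Tn, H); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- cc$A[[(b - 1L) * nh + h]]
        dCtxbh <- dCtx[rows, cols, drop = FALSE]
        Vbh <- cc$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dCtxbh, Vbh)
        dV[rows, cols] <- crossprod(A, dCtxbh)
        dS <- softmaxRowsBwd(dA, A) / sqrt(dh)
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE])
      }
    }
    bq <- linBwd(dQ, cc$Xin, lp$Wq); grads$layers[[l]]$Wq <- bq$grad
    bk <- linBwd(dK, cc$Xin, lp$Wk); grads$layers[[l]]$Wk <- bk$grad
    bv <- linBwd(dV, cc$Xin, lp$Wv); grads$layers[[l]]$Wv <- bv$grad
    dX <- dR1 + bq$dx + bk$dx + bv$dx
  }
  gE <- layerNormBwd(dX, fw$lnE, params$lnE$g)
  grads$lnE <- gE$grad
  dX0 <- gE$dx
  ## scatter into embeddings
  for (r in seq_along(fw$flat))
    grads$tokEmb[fw$flat[r], ] <- grads$tokEmb[fw$flat[r], ] + dX0[r, ]
  posIdx <- rep(seq_len(Tn), B)
  for (r in seq_along(posIdx))
    grads$posEmb[posIdx[r], ] <- grads$posEmb[posIdx[r], ] + dX0[r, ]
  grads
}

#' Corrupt token sequences for masked-language-model training
#'
#' Every real, non-special position is selected independently with
#' `maskRate`; selected positions become `[MASK]`, a random non-special
#' token, or stay unchanged at the policy proportions. Original ids at
#' selected positions are recorded as targets.
#'
#' @param ids,mask matrices from [encodeSmiles()].
#' @param vocab a [TokenVocab-class].
#' @param policy a [MaskingPolicy-class].
#' @return list with `ids` (corrupted), `targetMask` (logical matrix of
#'   selected positions) and `targets` (original ids there).
#' @export
maskTokens <- function(ids, mask, vocab, policy) {
  sp <- specialIds(vocab)
  eligible <- mask == 1 & !matrix(ids %in% sp, nrow(ids))
  sel <- eligible & matrix(runif(length(ids)) < policy@maskRate, nrow(ids))
  u <- matrix(runif(length(ids)), nrow(ids))
  corrupted <- ids
  doMask <- sel & u < policy@propMask
  doRand <- sel & u >= policy@propMask &
    u < policy@propMask + policy@propRandom
  corrupted[doMask] <- sp[["mask"]]
  nRand <- sum(doRand)
  if (nRand > 0) {
    lo <- length(sp)                      # first non-special id
    corrupted[doRand] <- sample(lo:(vocabSize(vocab) - 1L), nRand,
                                replace = TRUE)
  }
  list(ids = corrupted, targetMask = sel, targets = ids[sel])
}

## Softmax cross-entropy over masked positions. logits: M x V,
## targets: 0-based ids.
mlmLoss <- function(logits, targets) {
  P <- softmaxRows(logits)
  idx <- cbind(seq_along(targets), targets + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dLogits <- P
  dLogits[idx] <- dLogits[idx] - 1
  list(loss = loss, dLogits = dLogits / length(targets),
       correct = sum(max.col(P) == targets + 1L))
}

#' Pre-train an encoder with the masked-language-model objective
#'
#' Cross-entropy is computed over masked positions only. The loss trace
#' (mean per epoch) and the masked-token prediction accuracy of the final
#' epoch are returned with the updated encoder. Fully deterministic for a
#' fixed seed.
#'
#' @param encoder a [SmilesEncoder-class].
#' @param corpus character vector of SMILES.
#' @param policy a [MaskingPolicy-class].
#' @param epochs,batchSize,learningRate training settings (AdamW).
#' @param seed integer seed (shuffling + masking).
#' @return list with `encoder`, `lossTrace` and `maskedAccuracy`.
#' @export
pretrainEncoder <- function(encoder, corpus, policy = MaskingPolicy(),
                            epochs = 3L, batchSize = 32L,
                            learningRate = 1e-3, seed = 1L) {
  config <- encoder@config
  enc <- encodeSmiles(corpus, encoder@vocab, maxLen = config@maxLen)
  params <- encoder@params
  state <- adamwInit(params)
  n <- nrow(enc$ids)
  lossTrace <- numeric(epochs)
  accLast <- NA_real_
  set.seed(deriveSeed(seed, 21L))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batchSize))
    epLoss <- 0; epN <- 0; hits <- 0; tot <- 0
    for (idx in batches) {
      Tb <- max(enc$lengths[idx])
      ids <- enc$ids[idx, seq_len(Tb), drop = FALSE]
      msk <- enc$mask[idx, seq_len(Tb), drop = FALSE]
      mt <- maskTokens(ids, msk, encoder@vocab, policy)
      if (!any(mt$targetMask)) next
      fw <- encForward(params, config, mt$ids, msk, needCache = TRUE)
      tsel <- as.vector(t(mt$targetMask))     # row layout (b-1)*T + t
      Hm <- fw$hidden[tsel, , drop = FALSE]
      targets <- as.vector(t(ids))[tsel]
      logits <- linFwd(Hm, params$mlmHead)
      ls <- mlmLoss(logits, targets)
      bwh <- linBwd(ls$dLogits, Hm, params$mlmHead)
      dX <- matrix(0, nrow(fw$hidden), config@hiddenSize)
      dX[tsel, ] <- bwh$dx
      grads <- encBackward(params, config, fw, dX)
      grads$mlmHead <- bwh$grad
      upd <- adamwStep(params, grads, state, lr = learningRate)
      params <- upd$params
      state <- upd$state
      m <- length(targets)
      epLoss <- epLoss + ls$loss * m; epN <- epN + m
      hits <- hits + ls$correct; tot <- tot + m
    }
    lossTrace[ep] <- epLoss / max(epN, 1)
    accLast <- hits / max(tot, 1)
  }
  new("SmilesEncoder", config = config, vocab = encoder@vocab,
      params = params, vocabHash = encoder@vocabHash) -> encOut
  list(encoder = encOut, lossTrace = lossTrace, maskedAccuracy = accLast)
}

#' Majority-token baseline for masked-token prediction
#'
#' Accuracy of always predicting the most frequent non-special token of
#' the corpus; the floor any useful MLM must beat.
#'
#' @param corpus character vector of SMILES.
#' @param vocab a [TokenVocab-class].
#' @return numeric scalar in `[0,1]`.
#' @export
majorityTokenBaseline <- function(corpus, vocab) {
  enc <- encodeSmiles(corpus, vocab, maxLen = 512L)
  sp <- specialIds(vocab)
  ids <- enc$ids[enc$mask == 1]
  ids <- ids[!ids %in% sp]
  max(table(ids)) / length(ids)
}

#' Embed SMILES strings with a (pre-)trained encoder
#'
#' @param smiles character vector.
#' @param encoder a [SmilesEncoder-class].
#' @param batchSize molecules per forward pass.
#' @return numeric matrix n x H (one pooled hidden vector per molecule).
#' @export
embedSmiles <- function(smiles, encoder, batchSize = 64L) {
  config <- encoder@config
  enc <- encodeSmiles(smiles, encoder@vocab, maxLen = config@maxLen)
  n <- length(smiles)
  out <- matrix(0, n, config@hiddenSize)
  for (idx in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    Tb <- max(enc$lengths[idx])
    fw <- encForward(encoder@params, config,
                     enc$ids[idx, seq_len(Tb), drop = FALSE],
                     enc$mask[idx, seq_len(Tb), drop = FALSE])
    out[idx, ] <- fw$pooled
  }
  out
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint bundles the weights, the encoder configuration, the
#' vocabulary and its hash; loading verifies the hash.
#'
#' @param encoder a [SmilesEncoder-class].
#' @param path file path (`.rds`).
#' @export
writeEncoderCheckpoint <- function(encoder, path) {
  saveRDS(list(params = encoder@params,
               config = list(nLayers = encoder@config@nLayers,
                             nHeads = encoder@config@nHeads,
                             hiddenSize = encoder@config@hiddenSize,
                             ffSize = encoder@config@ffSize,
                             maxLen = encoder@config@maxLen,
                             vocabSize = encoder@config@vocabSize,
                             pooling = encoder@config@pooling),
               tokens = encoder@vocab@tokens,
               merges = encoder@vocab@merges,
               specials = encoder@vocab@specials,
               vocabHash = encoder@vocabHash), path)
  invisible(path)
}

#' @rdname writeEncoderCheckpoint
#' @export
readEncoderCheckpoint <- function(path) {
  ck <- readRDS(path)
  vocab <- new("TokenVocab", tokens = ck$tokens, merges = ck$merges,
               specials = ck$specials)
  if (!identical(vocabHash(vocab), ck$vocabHash))
    stop("readEncoderCheckpoint: vocabulary hash mismatch")
  cfg <- do.call(EncoderConfig, ck$config)
  new("SmilesEncoder", config = cfg, vocab = vocab, params = ck$params,
      vocabHash = ck$vocabHash)
}
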