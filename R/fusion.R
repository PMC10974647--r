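## The six fusion architectures as interchangeable multi-label predictors:
##
##   dnn     - physicochemical features only: Boolean -> 10-d embedding,
##             5 integers -> 10-d affine, 7 floats -> 10-d affine,
##             concatenated to a 30-d fused vector, affine head -> 21.
##   encoder - SMILES only: pooled transformer hidden vector (H = 768 at
##             defaults), affine head -> 21.
##   concat  - fused 30-d physchem vector and H-d hidden vector
##             concatenated (798 at defaults), affine head -> 21.
##   pipe    - encoder hidden vector -> stage-1 head predicting the 13
##             physicochemical descriptors, fed as inputs to the DNN
##             stage -> 21.
##   dnn_a / pipe_a - attention variants: the three 10-d group vectors
##             form a length-3 sequence for dot-product self-attention
##             (Q = K = V = the group vectors) followed by tanh.
##
## Heads are plain affine stacks (no hidden nonlinearity) by default;
## tanh appears only inside the attention block. `activation = "relu"` on
## the ModelConfig opts into nonlinear heads.

#' Build a fusion model
#'
#' @param config a [ModelConfig-class].
#' @param encoder a [SmilesEncoder-class] (required for encoder, concat,
#'   pipe and pipe_a architectures).
#' @param nInt,nFloat number of integer / float descriptors (5 and 7 for
#'   the default schema).
#' @param seed integer seed for weight initialization.
#' @return A [FusionModel-class].
#' @export
buildFusionModel <- function(config, encoder = NULL, nInt = 5L,
                             nFloat = 7L, seed = 1L) {
  arch <- config@architecture
  needsEnc <- arch %in% c("encoder", "concat", "pipe", "pipe_a")
  if (needsEnc && is.null(encoder))
    stop("architecture '", arch, "' requires an encoder")
  if (needsEnc && encoder@config@hiddenSize != config@hiddenSize)
    stop("encoder hidden size (", encoder@config@hiddenSize,
         ") does not match ModelConfig hiddenSize (", config@hiddenSize, ")")
  if (arch %in% c("dnn_a", "pipe_a") &&
      !(config@boolDim == config@intDim && config@intDim == config@floatDim))
    stop("attention architectures need equal group widths")
  set.seed(deriveSeed(seed, 31L))
  headIn <- switch(arch,
    dnn = , dnn_a = , pipe = , pipe_a = fusedWidth(config),
    encoder = config@hiddenSize,
    concat = concatWidth(config))
  head <- list()
  w <- headIn
  if (config@headDepth > 1L)
    for (d in seq_len(config@headDepth - 1L)) {
      head[[d]] <- initLinear(w, headIn)
      w <- headIn
    }
  head[[config@headDepth]] <- initLinear(w, config@nLabels)
  params <- list(head = head)
  if (arch != "encoder") {
    params$emb <- matrix(rnorm(2 * config@boolDim, 0, 0.5), 2,
                         config@boolDim)
    params$intProj <- initLinear(nInt, config@intDim)
    params$floatProj <- initLinear(nFloat, config@floatDim)
  }
  if (arch %in% c("pipe", "pipe_a"))
    params$stage1 <- initLinear(config@hiddenSize, config@pipeHeadSize)
  new("FusionModel", config = config, params = params,
      encoder = if (needsEnc) encoder else NULL)
}

## ---- building blocks -------------------------------------------------------

headFwd <- function(x, head, activation) {
  caches <- list()
  for (d in seq_along(head)) {
    caches[[d]] <- list(x = x)
    x <- linFwd(x, head[[d]])
    if (activation == "relu" && d < length(head)) {
      caches[[d]]$pre <- x
      x <- pmax(x, 0)
    }
  }
  list(y = x, caches = caches)
}

headBwd <- function(dy, head, hc, activation) {
  grads <- vector("list", length(head))
  for (d in rev(seq_along(head))) {
    if (activation == "relu" && d < length(head))
      dy <- dy * (hc$caches[[d]]$pre > 0)
    bw <- linBwd(dy, hc$caches[[d]]$x, head[[d]])
    grads[[d]] <- bw$grad
    dy <- bw$dx
  }
  list(dx = dy, grad = grads)
}

## Boolean soft embedding: p in [0,1] mixes the two embedding rows, so a
## hard 0/1 input reduces to a table lookup and the pipe's predicted
## probability stays differentiable.
dnnGroupsFwd <- function(params, xb, xi, xf) {
  P2 <- cbind(1 - xb, xb)
  eb <- P2 %*% params$emb
  gi <- linFwd(xi, params$intProj)
  gf <- linFwd(xf, params$floatProj)
  list(eb = eb, gi = gi, gf = gf, P2 = P2)
}

dnnGroupsBwd <- function(params, gc, deb, dgi, dgf, xi, xf) {
  dEmb <- crossprod(gc$P2, deb)
  dxb <- as.vector(deb %*% (params$emb[2, ] - params$emb[1, ]))
  bi <- linBwd(dgi, xi, params$intProj)
  bf <- linBwd(dgf, xf, params$floatProj)
  list(grad = list(emb = dEmb, intProj = bi$grad, floatProj = bf$grad),
       dxb = dxb, dxi = bi$dx, dxf = bf$dx)
}

## Self-attention over the three group vectors (a length-3 sequence).
## Returns the attended, tanh-activated groups plus the attention weights
## (B x 3 x 3, rows = queries) for inspection.
attentionBlockFwd <- function(g) {
  d <- ncol(g[[1]])
  B <- nrow(g[[1]])
  S <- array(0, c(B, 3, 3))
  for (i in 1:3) for (j in 1:3)
    S[, i, j] <- rowSums(g[[i]] * g[[j]]) / sqrt(d)
  A <- array(0, c(B, 3, 3))
  for (i in 1:3) {
    m <- pmax(S[, i, 1], pmax(S[, i, 2], S[, i, 3]))
    e <- exp(S[, i, ] - m)
    A[, i, ] <- e / rowSums(e)
  }
  Z <- vector("list", 3)
  O <- vector("list", 3)
  for (i in 1:3) {
    Z[[i]] <- A[, i, 1] * g[[1]] + A[, i, 2] * g[[2]] + A[, i, 3] * g[[3]]
    O[[i]] <- tanh(Z[[i]])
  }
  list(out = O, A = A, Z = Z, g = g)
}

attentionBlockBwd <- function(dO, cache) {
  g <- cache$g; A <- cache$A
  d <- ncol(g[[1]]); B <- nrow(g[[1]])
  dg <- lapply(1:3, function(i) matrix(0, B, d))
  dA <- array(0, c(B, 3, 3))
  dZ <- vector("list", 3)
  for (i in 1:3) {
    dZ[[i]] <- dO[[i]] * (1 - tanh(cache$Z[[i]])^2)
    for (j in 1:3) {
      dA[, i, j] <- rowSums(dZ[[i]] * g[[j]])
      dg[[j]] <- dg[[j]] + A[, i, j] * dZ[[i]]
    }
  }
  for (i in 1:3) {
    rs <- dA[, i, 1] * A[, i, 1] + dA[, i, 2] * A[, i, 2] +
      dA[, i, 3] * A[, i, 3]
    for (j in 1:3) {
      dS <- A[, i, j] * (dA[, i, j] - rs) / sqrt(d)
      dg[[i]] <- dg[[i]] + dS * g[[j]]
      dg[[j]] <- dg[[j]] + dS * g[[i]]
    }
  }
  dg
}

## ---- batches ---------------------------------------------------------------

## Assemble the numeric inputs (and token encodings where needed) for a
## molecule set, in the schema's canonical feature order.
makeBatchData <- function(mol, model) {
  schema <- featureSchema(mol)
  f <- featureTable(mol)
  arch <- model@config@architecture
  out <- list(n = nMolecules(mol),
              y = labelMatrix(mol))
  if (arch != "encoder") {
    out$xb <- as.numeric(f[[schema@boolFeatures[1]]])
    out$xi <- as.matrix(f[, schema@intFeatures, drop = FALSE])
    out$xf <- as.matrix(f[, schema@floatFeatures, drop = FALSE])
  }
  if (arch %in% c("pipe", "pipe_a")) {
    out$featTarget <- cbind(as.numeric(f[[schema@boolFeatures[1]]]),
                            as.matrix(f[, schema@intFeatures, drop = FALSE]),
                            as.matrix(f[, schema@floatFeatures, drop = FALSE]))
  }
  if (!is.null(model@encoder)) {
    enc <- encodeSmiles(smilesStrings(mol), model@encoder@vocab,
                        maxLen = model@encoder@config@maxLen)
    out$ids <- enc$ids
    out$mask <- enc$mask
    out$lengths <- enc$lengths
  }
  out
}

sliceBatch <- function(bd, idx) {
  out <- list(n = length(idx))
  if (!is.null(bd$xb)) {
    out$xb <- bd$xb[idx]
    out$xi <- bd$xi[idx, , drop = FALSE]
    out$xf <- bd$xf[idx, , drop = FALSE]
  }
  if (!is.null(bd$featTarget))
    out$featTarget <- bd$featTarget[idx, , drop = FALSE]
  if (!is.null(bd$ids)) {
    Tb <- max(bd$lengths[idx])
    out$ids <- bd$ids[idx, seq_len(Tb), drop = FALSE]
    out$mask <- bd$mask[idx, seq_len(Tb), drop = FALSE]
  }
  if (!is.null(bd$y) && ncol(bd$y)) out$y <- bd$y[idx, , drop = FALSE]
  out
}

## ---- forward / backward ----------------------------------------------------

## Forward pass for any architecture. Returns logits, probabilities,
## pipe stage-1 predictions, attention weights, and caches for backward.
fusionForward <- function(model, batch, needCache = FALSE) {
  cfg <- model@config
  arch <- cfg@architecture
  p <- model@params
  cache <- list()
  if (arch %in% c("encoder", "concat", "pipe", "pipe_a")) {
    fw <- encForward(model@encoder@params, model@encoder@config,
                     batch$ids, batch$mask, needCache = needCache)
    pooled <- fw$pooled
    cache$enc <- fw
  }
  stage1 <- NULL
  attn <- NULL
  if (arch %in% c("pipe", "pipe_a")) {
    s1 <- linFwd(pooled, p$stage1)
    stage1 <- s1
    stage1[, 1] <- sigmoidStable(s1[, 1])       # Boolean column
    cache$s1raw <- s1
    xb <- stage1[, 1]
    xi <- stage1[, 2:6, drop = FALSE]
    xf <- stage1[, 7:13, drop = FALSE]
  } else if (arch != "encoder") {
    xb <- batch$xb; xi <- batch$xi; xf <- batch$xf
  }
  if (arch != "encoder") {
    gc <- dnnGroupsFwd(p, xb, xi, xf)
    cache$groups <- gc
    cache$xin <- list(xb = xb, xi = xi, xf = xf)
    if (arch %in% c("dnn_a", "pipe_a")) {
      ab <- attentionBlockFwd(list(gc$eb, gc$gi, gc$gf))
      cache$attn <- ab
      attn <- ab$A
      fused <- cbind(ab$out[[1]], ab$out[[2]], ab$out[[3]])
    } else {
      fused <- cbind(gc$eb, gc$gi, gc$gf)
    }
  }
  headIn <- switch(arch,
    encoder = pooled,
    concat = cbind(fused, pooled),
    fused)
  hf <- headFwd(headIn, p$head, cfg@activation)
  cache$head <- hf
  list(logits = hf$y, probs = sigmoidStable(hf$y), stage1 = stage1,
       attention = attn, cache = cache)
}

## Backward pass: dLogits is the gradient on the output logits;
## dStage1 (optional, pipe only) is an extra gradient applied directly to
## the stage-1 predictions (sigmoid-transformed Boolean column scale).
## Returns list(fusion = <grad tree>, encoder = <grad tree or NULL>).
fusionBackward <- function(model, batch, fw, dLogits, dStage1 = NULL) {
  cfg <- model@config
  arch <- cfg@architecture
  p <- model@params
  cc <- fw$cache
  hb <- headBwd(dLogits, p$head, cc$head, cfg@activation)
  grads <- list(head = hb$grad)
  dPooled <- NULL
  if (arch == "encoder") {
    dPooled <- hb$dx
  } else {
    W <- fusedWidth(cfg)
    dFused <- hb$dx[, seq_len(W), drop = FALSE]
    if (arch == "concat")
      dPooled <- hb$dx[, (W + 1):ncol(hb$dx), drop = FALSE]
    b1 <- cfg@boolDim
    b2 <- b1 + cfg@intDim
    if (arch %in% c("dnn_a", "pipe_a")) {
      dO <- list(dFused[, 1:b1, drop = FALSE],
                 dFused[, (b1 + 1):b2, drop = FALSE],
                 dFused[, (b2 + 1):W, drop = FALSE])
      dg <- attentionBlockBwd(dO, cc$attn)
      deb <- dg[[1]]; dgi <- dg[[2]]; dgf <- dg[[3]]
    } else {
      deb <- dFused[, 1:b1, drop = FALSE]
      dgi <- dFused[, (b1 + 1):b2, drop = FALSE]
      dgf <- dFused[, (b2 + 1):W, drop = FALSE]
    }
    gb <- dnnGroupsBwd(p, cc$groups, deb, dgi, dgf, cc$xin$xi, cc$xin$xf)
    grads$emb <- gb$grad$emb
    grads$intProj <- gb$grad$intProj
    grads$floatProj <- gb$grad$floatProj
    if (arch %in% c("pipe", "pipe_a")) {
      ## gradient on stage-1 predictions: from stage 2 plus any direct
      ## stage-1 loss term
      dS1 <- cbind(gb$dxb, gb$dxi, gb$dxf)
      if (!is.null(dStage1)) dS1 <- dS1 + dStage1
      ## Boolean column goes back through its sigmoid
      pb <- fw$stage1[, 1]
      dS1[, 1] <- dS1[, 1] * pb * (1 - pb)
      bs1 <- linBwd(dS1, cc$enc$pooled, p$stage1)
      grads$stage1 <- bs1$grad
      dPooled <- bs1$dx
    }
  }
  encGrads <- NULL
  if (!is.null(dPooled) && !is.null(model@encoder)) {
    dX <- poolBackward(dPooled, cc$enc, model@encoder@config)
    encGrads <- encBackward(model@encoder@params, model@encoder@config,
                            cc$enc, dX)
  }
  list(fusion = grads, encoder = encGrads)
}

#' Predict label probabilities for a molecule set
#'
#' Runs the model's forward pass in batches and returns an n x nLabels
#' probability matrix. Deterministic for fixed weights.
#'
#' @param model a [FusionModel-class].
#' @param mol a normalized [MoleculeSet-class].
#' @param labelNames column names for the output (defaults to the label
#'   columns of `mol` when present).
#' @param batchSize molecules per forward pass.
#' @return A [PredictionMatrix-class]. For pipe architectures the
#'   stage-1 physicochemical predictions are attached as attribute
#'   `stage1`; for attention architectures the attention weights are
#'   attached as attribute `attention`.
#' @export
predictFusion <- function(model, mol, labelNames = NULL, batchSize = 64L) {
  bd <- makeBatchData(mol, model)
  n <- bd$n
  probs <- matrix(0, n, model@config@nLabels)
  stage1 <- NULL
  attn <- NULL
  for (idx in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    fw <- fusionForward(model, sliceBatch(bd, idx))
    probs[idx, ] <- fw$probs
    if (!is.null(fw$stage1)) {
      if (is.null(stage1)) stage1 <- matrix(0, n, ncol(fw$stage1))
      stage1[idx, ] <- fw$stage1
    }
  }
  if (is.null(labelNames)) {
    labelNames <- if (ncol(labelMatrix(mol)) == ncol(probs))
      colnames(labelMatrix(mol)) else sprintf("label_%d", seq_len(ncol(probs)))
  }
  pm <- PredictionMatrix(probs, tag = model@config@architecture,
                         labelNames = labelNames)
  attr(pm, "stage1") <- stage1
  pm
}

#' Closed-form parameter count of a fusion model
#'
#' Computed from the configuration alone; the test suite checks it
#' against the actual parameter tree.
#'
#' @param config a [ModelConfig-class].
#' @param nInt,nFloat descriptor group sizes.
#' @return integer count of fusion-layer parameters (encoder excluded).
#' @export
countFusionParams <- function(config, nInt = 5L, nFloat = 7L) {
  arch <- config@architecture
  headIn <- switch(arch,
    dnn = , dnn_a = , pipe = , pipe_a = fusedWidth(config),
    encoder = config@hiddenSize,
    concat = concatWidth(config))
  head <- 0L
  w <- headIn
  if (config@headDepth > 1L)
    for (d in seq_len(config@headDepth - 1L)) {
      head <- head + w * headIn + headIn
      w <- headIn
    }
  head <- head + w * config@nLabels + config@nLabels
  total <- head
  if (arch != "encoder")
    total <- total + 2L * config@boolDim +
      (nInt * config@intDim + config@intDim) +
      (nFloat * config@floatDim + config@floatDim)
  if (arch %in% c("pipe", "pipe_a"))
    total <- total + config@hiddenSize * config@pipeHeadSize +
      config@pipeHeadSize
  as.integer(total)
}
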