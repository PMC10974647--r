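## Low-level neural-network primitives: parameter trees (named lists of
## numeric arrays), explicit forward/backward functions, and AdamW.
## Everything is deterministic given the R RNG state; no threads, no
## external frameworks. Gradients are validated against finite differences
## in the test suite.

## Derive a reproducible child seed from (seed, salt) staying within the
## 32-bit integer range.
deriveSeed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + salt * 1009 + 12345) %% 2147483647)
}

## Fan-in scaled uniform init (Kaiming/LeCun style for linear stacks).
initMatrix <- function(nin, nout) {
  lim <- sqrt(1 / nin)
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

initLinear <- function(nin, nout) {
  list(W = initMatrix(nin, nout), b = rep(0, nout))
}

linFwd <- function(x, p) sweep(x %*% p$W, 2, p$b, `+`)

linBwd <- function(dy, x, p) {
  list(dx = dy %*% t(p$W),
       grad = list(W = crossprod(x, dy), b = colSums(dy)))
}

sigmoidStable <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

## Summed-per-label binary cross-entropy, mean over the batch, computed
## from logits for numerical stability. Returns loss and dLogits.
bceWithLogits <- function(logits, y) {
  z <- pmin(pmax(logits, -30), 30)
  loss <- sum(log1p(exp(-abs(z))) + pmax(z, 0) - z * y) / nrow(logits)
  dz <- (sigmoidStable(logits) - y) / nrow(logits)
  list(loss = loss, dLogits = dz)
}

mseLoss <- function(pred, target) {
  d <- pred - target
  list(loss = sum(d * d) / nrow(pred), dPred = 2 * d / nrow(pred))
}

geluFwd <- function(x) x * pnorm(x)

geluBwd <- function(dy, x) dy * (pnorm(x) + x * dnorm(x))

softmaxRows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

## Backward through row-wise softmax: dS = A * (dA - rowSums(dA * A)).
softmaxRowsBwd <- function(dA, A) A * (dA - rowSums(dA * A))

layerNormFwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat * rep(g, each = nrow(x)), 2, b, `+`),
       xhat = xhat, inv = inv)
}

layerNormBwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  inv <- cache$inv
  H <- ncol(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(xhat))
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, grad = list(g = dgamma, b = dbeta))
}

## ---- parameter-tree utilities ---------------------------------------------

## Apply f leaf-wise over parallel parameter trees.
treeMap <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i)
      do.call(treeMap, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

zerosLike <- function(params) treeMap(function(x) x * 0, params)

treeAdd <- function(a, b) treeMap(`+`, a, b)

treeSumSq <- function(a) {
  if (is.list(a)) sum(vapply(a, treeSumSq, numeric(1))) else sum(a * a)
}

nParams <- function(params) {
  if (is.list(params)) sum(vapply(params, nParams, numeric(1)))
  else length(params)
}

## ---- AdamW ----------------------------------------------------------------

adamwInit <- function(params) {
  list(m = zerosLike(params), v = zerosLike(params), t = 0L)
}

## Decoupled weight decay (applied to every weight leaf; biases and
## layer-norm parameters are 1-d leaves and are exempted).
adamwStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$m <- treeMap(function(m, g) beta1 * m + (1 - beta1) * g,
                     state$m, grads)
  state$v <- treeMap(function(v, g) beta2 * v + (1 - beta2) * g * g,
                     state$v, grads)
  params <- treeMap(function(p, m, v) {
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    wd <- if (is.matrix(p)) weightDecay else 0
    p - lr * (upd + wd * p)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
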