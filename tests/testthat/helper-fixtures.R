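# Shared fixtures and finite-difference utilities. Everything is built in
# code at test time; no stored data files.

tinySimulation <- function(n = 40, seed = 5, nLabels = 4,
                           labelMode = "feature_driven", noise = 0.05) {
  simulateMolecules(GeneratorConfig(nMolecules = n, seed = seed,
                                    nLabels = nLabels,
                                    labelMode = labelMode,
                                    noiseRate = noise))
}

tinyVocab <- function(smiles, vocabSize = 40) {
  trainBPE(smiles, vocabSize = vocabSize, minFrequency = 1)
}

tinyEncoder <- function(vocab, H = 8, layers = 1, heads = 2, maxLen = 48,
                        seed = 3, pooling = "cls") {
  cfg <- EncoderConfig(vocabSize = vocabSize(vocab), nLayers = layers,
                       nHeads = heads, hiddenSize = H, ffSize = 2 * H,
                       maxLen = maxLen, pooling = pooling)
  initEncoder(cfg, vocab, seed = seed)
}

getIn <- function(tree, path) {
  for (k in path) tree <- tree[[k]]
  tree
}

modifyIn <- function(tree, path, value) {
  if (length(path) == 1) {
    tree[[path[[1]]]] <- value
    return(tree)
  }
  tree[[path[[1]]]] <- modifyIn(tree[[path[[1]]]], path[-1], value)
  tree
}

# Central-difference derivative of lossFn w.r.t. a few entries of the
# parameter leaf at `path`; returns the worst relative error against the
# analytic gradient leaf.
fdCheck <- function(params, grads, path, lossFn, k = 4, eps = 1e-5) {
  p <- getIn(params, path)
  g <- getIn(grads, path)
  stopifnot(length(p) == length(g), length(p) > 0)
  idx <- sample(length(p), min(k, length(p)))
  worst <- 0
  for (i in idx) {
    q <- p
    q[i] <- p[i] + eps
    lp <- lossFn(modifyIn(params, path, q))
    q[i] <- p[i] - eps
    lm <- lossFn(modifyIn(params, path, q))
    num <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(num - g[i]) / max(1e-4, abs(num) + abs(g[i])))
  }
  worst
}

# Minimal DrugBank-style JSON record writer for parser tests.
writeToyJSON <- function(path, id, smiles, drop = character(),
                         extraProps = list(), labelValue = 1) {
  schema <- defaultFeatureSchema()
  props <- as.list(setNames(seq_along(inputFeatures(schema)),
                            inputFeatures(schema)))
  props[drop] <- NULL
  props <- c(props, extraProps)
  admet <- as.list(setNames(rep(labelValue, length(rawLabels(schema))),
                            rawLabels(schema)))
  jsonlite::write_json(list(id = id, smiles = smiles, properties = props,
                            admet = admet),
                       path, auto_unbox = TRUE)
  path
}
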