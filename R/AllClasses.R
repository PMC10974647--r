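#' @import methods
#' @importFrom stats rnorm runif rbinom sd plogis setNames quantile pnorm dnorm
#' @importFrom utils head tail read.csv write.csv modifyList packageVersion
NULL

## ---------------------------------------------------------------------------
## FeatureSchema
## ---------------------------------------------------------------------------

#' Feature and label schema for molecule records
#'
#' A `FeatureSchema` declares which physicochemical descriptors a complete
#' molecule record must carry (one Boolean, five integer, seven float
#' descriptors by default), which drug-likeness filter flags are excluded
#' from modelling, the raw ADMET label names, and the merge rules that
#' collapse semantically redundant raw labels into the final label set.
#'
#' @slot boolFeatures character vector of Boolean descriptor names.
#' @slot intFeatures character vector of integer descriptor names.
#' @slot floatFeatures character vector of float descriptor names.
#' @slot excludedFilters filter flags dropped from the inputs (they cannot
#'   be measured experimentally and invite leakage).
#' @slot rawLabels raw binary ADMET label names, pre-merge.
#' @slot mergeRules named list; each element is a character vector of raw
#'   label names collapsed into the final label named by the element.
#' @slot mergeOp `"or"` (default) or `"and"`: how merged sources combine.
#' @slot finalLabels final label names after merging.
#'
#' @examples
#' sch <- defaultFeatureSchema()
#' length(finalLabels(sch))  # 21
#' @export
setClass("FeatureSchema", representation(
  boolFeatures = "character",
  intFeatures = "character",
  floatFeatures = "character",
  excludedFilters = "character",
  rawLabels = "character",
  mergeRules = "list",
  mergeOp = "character",
  finalLabels = "character"
))

setValidity("FeatureSchema", function(object) {
  msgs <- character()
  feats <- inputFeatures(object)
  if (anyDuplicated(feats))
    msgs <- c(msgs, "duplicated input feature names")
  if (any(object@excludedFilters %in% feats))
    msgs <- c(msgs, "excluded filter names must not appear among input features")
  src <- unlist(object@mergeRules, use.names = FALSE)
  if (!all(src %in% object@rawLabels))
    msgs <- c(msgs, "merge rule sources must be raw label names")
  expect <- schemaFinalLabels(object@rawLabels, object@mergeRules)
  if (!identical(sort(object@finalLabels), sort(expect)))
    msgs <- c(msgs, "finalLabels inconsistent with rawLabels + mergeRules")
  if (!object@mergeOp %in% c("or", "and"))
    msgs <- c(msgs, "mergeOp must be 'or' or 'and'")
  if (length(msgs)) msgs else TRUE
})

schemaFinalLabels <- function(rawLabels, mergeRules) {
  src <- unlist(mergeRules, use.names = FALSE)
  out <- character()
  emitted <- character()
  for (lab in rawLabels) {
    if (lab %in% src) {
      tgt <- names(mergeRules)[vapply(mergeRules, function(s) lab %in% s, logical(1))][1]
      if (!tgt %in% emitted) {
        out <- c(out, tgt)
        emitted <- c(emitted, tgt)
      }
    } else {
      out <- c(out, lab)
    }
  }
  out
}

#' Construct a feature schema
#'
#' @param boolFeatures,intFeatures,floatFeatures descriptor names by kind.
#' @param excludedFilters filter flags excluded from the inputs.
#' @param rawLabels raw binary label names.
#' @param mergeRules named list mapping each merged final name to the raw
#'   names it absorbs.
#' @param mergeOp `"or"` or `"and"`.
#' @return A [FeatureSchema-class] object.
#' @export
FeatureSchema <- function(boolFeatures, intFeatures, floatFeatures,
                          excludedFilters = character(),
                          rawLabels = character(),
                          mergeRules = list(), mergeOp = "or") {
  new("FeatureSchema",
      boolFeatures = boolFeatures, intFeatures = intFeatures,
      floatFeatures = floatFeatures, excludedFilters = excludedFilters,
      rawLabels = rawLabels, mergeRules = mergeRules, mergeOp = mergeOp,
      finalLabels = schemaFinalLabels(rawLabels, mergeRules))
}

#' Default ADMET feature schema
#'
#' Thirteen usable descriptors (1 Boolean + 5 integer + 7 float), four
#' excluded drug-likeness filters, and 24 raw ADMET labels merged to 21:
#' human intestinal absorption absorbs Caco-2 permeability, the two
#' p-glycoprotein inhibitor assays merge, and the two hERG assays merge.
#' The raw label catalogue is a documented default in the admetSAR style;
#' override any part by calling [FeatureSchema()] directly.
#'
#' @param mergeOp how merged sources combine; `"or"` (a compound positive
#'   in any source assay is positive) is the conservative default for
#'   safety-relevant labels such as hERG inhibition.
#' @return A [FeatureSchema-class] with 21 final labels.
#' @export
defaultFeatureSchema <- function(mergeOp = "or") {
  FeatureSchema(
    boolFeatures = "bioavailability",
    intFeatures = c("physiological_charge", "hydrogen_acceptor_count",
                    "hydrogen_donor_count", "rotatable_bond_count",
                    "number_of_rings"),
    floatFeatures = c("logp", "logs", "pka", "water_solubility",
                      "polar_surface_area", "molar_refractivity",
                      "polarizability"),
    excludedFilters = c("lipinski_rule_of_five", "ghose_filter",
                        "veber_rule", "mddr_like_rule"),
    rawLabels = c(
      "human_intestinal_absorption", "caco2_permeability",
      "blood_brain_barrier", "p_glycoprotein_substrate",
      "p_glycoprotein_inhibitor_i", "p_glycoprotein_inhibitor_ii",
      "renal_organic_cation_transporter",
      "cyp450_2c9_substrate", "cyp450_2d6_substrate", "cyp450_3a4_substrate",
      "cyp450_1a2_inhibitor", "cyp450_2c9_inhibitor", "cyp450_2d6_inhibitor",
      "cyp450_2c19_inhibitor", "cyp450_3a4_inhibitor",
      "cyp_inhibitory_promiscuity",
      "herg_inhibition_i", "herg_inhibition_ii",
      "ames_toxicity", "carcinogenicity", "biodegradation",
      "honey_bee_toxicity", "tetrahymena_pyriformis_toxicity",
      "fish_toxicity"),
    mergeRules = list(
      human_intestinal_absorption = c("human_intestinal_absorption",
                                      "caco2_permeability"),
      p_glycoprotein_inhibitor = c("p_glycoprotein_inhibitor_i",
                                   "p_glycoprotein_inhibitor_ii"),
      herg_inhibition = c("herg_inhibition_i", "herg_inhibition_ii")),
    mergeOp = mergeOp)
}

## ---------------------------------------------------------------------------
## MoleculeSet
## ---------------------------------------------------------------------------

#' A set of molecule records
#'
#' Container pairing SMILES strings with a physicochemical feature table
#' and (optionally) a binary ADMET label matrix, under a declared
#' [FeatureSchema-class]. Feature columns may be incomplete (NA) until
#' [excludeIncomplete()] is applied; labels may be raw (pre-merge) or
#' final (post [mergeLabels()]).
#'
#' @slot ids character, unique record identifiers.
#' @slot smiles character, one SMILES per record.
#' @slot features data.frame of descriptor columns, one row per record.
#' @slot labels numeric matrix (entries 0/1 or NA), zero columns when the
#'   set carries no labels.
#' @slot schema the governing [FeatureSchema-class].
#' @export
setClass("MoleculeSet", representation(
  ids = "character", smiles = "character", features = "data.frame",
  labels = "matrix", schema = "FeatureSchema"
))

setValidity("MoleculeSet", function(object) {
  n <- length(object@ids)
  msgs <- character()
  if (length(object@smiles) != n) msgs <- c(msgs, "smiles length != ids length")
  if (nrow(object@features) != n) msgs <- c(msgs, "features rows != ids length")
  if (ncol(object@labels) > 0 && nrow(object@labels) != n)
    msgs <- c(msgs, "labels rows != ids length")
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicated ids")
  if (ncol(object@labels) > 0) {
    v <- object@labels
    if (!all(v %in% c(0, 1) | is.na(v)))
      msgs <- c(msgs, "label entries must be 0, 1 or NA")
    known <- c(object@schema@rawLabels, object@schema@finalLabels)
    if (!all(colnames(v) %in% known))
      msgs <- c(msgs, "label columns not declared in schema")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MoleculeSet
#'
#' @param ids record identifiers (default `mol_1..n`).
#' @param smiles SMILES strings.
#' @param features data.frame of descriptors (rows align with `smiles`).
#' @param labels binary label matrix or `NULL`.
#' @param schema a [FeatureSchema-class]; default [defaultFeatureSchema()].
#' @return A [MoleculeSet-class].
#' @export
MoleculeSet <- function(smiles, features, labels = NULL,
                        ids = sprintf("mol_%d", seq_along(smiles)),
                        schema = defaultFeatureSchema()) {
  if (is.null(labels))
    labels <- matrix(numeric(0), nrow = length(smiles), ncol = 0)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  new("MoleculeSet", ids = as.character(ids), smiles = as.character(smiles),
      features = as.data.frame(features), labels = labels, schema = schema)
}

## ---------------------------------------------------------------------------
## NormalizationStats
## ---------------------------------------------------------------------------

#' Per-feature normalization statistics
#'
#' Mean and standard deviation of each numeric descriptor, computed on the
#' training split only and applied unchanged to validation/test data.
#'
#' @slot center named numeric, per-feature means.
#' @slot scale named numeric, per-feature standard deviations (all > 0).
#' @export
setClass("NormalizationStats",
         representation(center = "numeric", scale = "numeric"))

setValidity("NormalizationStats", function(object) {
  if (!identical(names(object@center), names(object@scale)))
    return("center and scale must cover the same features")
  if (any(object@scale <= 0)) return("all scales must be > 0")
  TRUE
})

## ---------------------------------------------------------------------------
## TokenVocab
## ---------------------------------------------------------------------------

#' Byte-pair-encoding vocabulary over SMILES
#'
#' Ordered merge rules plus the token table they induce. Special tokens
#' occupy the reserved low ids 0..4 ([PAD], [UNK], [CLS], [SEP], [MASK]);
#' base single-character symbols follow, then merged tokens in the order
#' they were learned. Ids are dense `0..vocabSize-1`.
#'
#' @slot tokens character vector; position `i` holds the token with id
#'   `i - 1`.
#' @slot merges list of 2-character vectors, in learned order.
#' @slot specials named character: pad, unk, cls, sep, mask.
#' @export
setClass("TokenVocab", representation(
  tokens = "character", merges = "list", specials = "character"))

setValidity("TokenVocab", function(object) {
  msgs <- character()
  need <- c("pad", "unk", "cls", "sep", "mask")
  if (!all(need %in% names(object@specials)))
    msgs <- c(msgs, "specials must name pad/unk/cls/sep/mask")
  if (!identical(unname(object@specials[need]), object@tokens[1:5]))
    msgs <- c(msgs, "special tokens must occupy the first ids")
  if (anyDuplicated(object@tokens)) msgs <- c(msgs, "duplicate tokens")
  bad <- vapply(object@merges,
                function(m) !identical(paste0(m[1], m[2]),
                                       paste0(m, collapse = "")),
                logical(1))
  if (any(bad)) msgs <- c(msgs, "merge outputs must concatenate their pair")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Configs
## ---------------------------------------------------------------------------

#' Transformer encoder hyperparameters
#'
#' @slot nLayers,nHeads,hiddenSize,ffSize,maxLen,vocabSize integer scalars;
#'   `hiddenSize` must be divisible by `nHeads`.
#' @slot pooling `"cls"` (first-token hidden state, default) or `"mean"`
#'   (mask-weighted mean over positions).
#' @export
setClass("EncoderConfig", representation(
  nLayers = "integer", nHeads = "integer", hiddenSize = "integer",
  ffSize = "integer", maxLen = "integer", vocabSize = "integer",
  pooling = "character"))

setValidity("EncoderConfig", function(object) {
  msgs <- character()
  cnt <- c(object@nLayers, object@nHeads, object@hiddenSize,
           object@ffSize, object@maxLen, object@vocabSize)
  if (any(cnt <= 0)) msgs <- c(msgs, "all counts must be positive")
  if (object@hiddenSize %% object@nHeads != 0)
    msgs <- c(msgs, "hiddenSize must be divisible by nHeads")
  if (!object@pooling %in% c("cls", "mean"))
    msgs <- c(msgs, "pooling must be 'cls' or 'mean'")
  if (length(msgs)) msgs else TRUE
})

#' @param nLayers,nHeads,hiddenSize,ffSize,maxLen,vocabSize see slots.
#' @param pooling `"cls"` or `"mean"`.
#' @return An [EncoderConfig-class].
#' @rdname EncoderConfig-class
#' @export
EncoderConfig <- function(vocabSize, nLayers = 4L, nHeads = 8L,
                          hiddenSize = 768L, ffSize = 4L * hiddenSize,
                          maxLen = 128L, pooling = "cls") {
  new("EncoderConfig", nLayers = as.integer(nLayers),
      nHeads = as.integer(nHeads), hiddenSize = as.integer(hiddenSize),
      ffSize = as.integer(ffSize), maxLen = as.integer(maxLen),
      vocabSize = as.integer(vocabSize), pooling = pooling)
}

#' Masked-language-model corruption policy
#'
#' Each maskable position is selected independently with `maskRate`;
#' selected positions become the mask token, a random token, or stay
#' unchanged with probabilities `propMask`/`propRandom`/`propKeep`
#' (RoBERTa defaults 0.15 and 0.8/0.1/0.1).
#'
#' @slot maskRate,propMask,propRandom,propKeep numeric in `[0,1]`; the
#'   three proportions sum to 1.
#' @export
setClass("MaskingPolicy", representation(
  maskRate = "numeric", propMask = "numeric", propRandom = "numeric",
  propKeep = "numeric"))

setValidity("MaskingPolicy", function(object) {
  p <- c(object@maskRate, object@propMask, object@propRandom, object@propKeep)
  if (any(p < 0 | p > 1)) return("rates must lie in [0,1]")
  if (abs(object@propMask + object@propRandom + object@propKeep - 1) > 1e-9)
    return("proportions must sum to 1")
  TRUE
})

#' @param maskRate,propMask,propRandom,propKeep see slots.
#' @rdname MaskingPolicy-class
#' @export
MaskingPolicy <- function(maskRate = 0.15, propMask = 0.8,
                          propRandom = 0.1, propKeep = 0.1) {
  new("MaskingPolicy", maskRate = maskRate, propMask = propMask,
      propRandom = propRandom, propKeep = propKeep)
}

#' Fusion architecture configuration
#'
#' Houses the architecture dimensions: the Boolean descriptor embeds to
#' `boolDim` (10), the integer and float groups project to `intDim` and
#' `floatDim` (10 each), giving a fused 30-dimensional physicochemical
#' vector; the encoder contributes `hiddenSize` (768) so the concat fusion
#' width is 798 at defaults; the output head emits `nLabels` (21) logits.
#'
#' @slot architecture one of dnn, encoder, concat, pipe, dnn_a, pipe_a.
#' @slot boolDim,intDim,floatDim group projection widths.
#' @slot hiddenSize encoder hidden width H.
#' @slot nLabels number of output labels.
#' @slot pipeHeadSize pipe stage-1 physicochemical head width (13: the
#'   usable descriptor count).
#' @slot headDepth number of affine layers in the output head.
#' @slot activation `"none"` (plain affine stacks; tanh is used only
#'   inside the attention variants) or `"relu"`.
#' @export
setClass("ModelConfig", representation(
  architecture = "character", boolDim = "integer", intDim = "integer",
  floatDim = "integer", hiddenSize = "integer", nLabels = "integer",
  pipeHeadSize = "integer", headDepth = "integer", activation = "character"))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (!object@architecture %in% ARCHITECTURES)
    msgs <- c(msgs, paste("unknown architecture:", object@architecture))
  if (any(c(object@boolDim, object@intDim, object@floatDim,
            object@hiddenSize, object@nLabels, object@pipeHeadSize,
            object@headDepth) <= 0))
    msgs <- c(msgs, "all widths must be positive")
  if (!object@activation %in% c("none", "relu"))
    msgs <- c(msgs, "activation must be 'none' or 'relu'")
  if (length(msgs)) msgs else TRUE
})

#' Supported fusion architectures
#' @export
ARCHITECTURES <- c("dnn", "encoder", "concat", "pipe", "dnn_a", "pipe_a")

#' @param architecture see slots.
#' @param boolDim,intDim,floatDim,hiddenSize,nLabels,pipeHeadSize,headDepth,activation
#'   see slots.
#' @rdname ModelConfig-class
#' @export
ModelConfig <- function(architecture = "dnn", boolDim = 10L, intDim = 10L,
                        floatDim = 10L, hiddenSize = 768L, nLabels = 21L,
                        pipeHeadSize = 13L, headDepth = 1L,
                        activation = "none") {
  new("ModelConfig", architecture = architecture,
      boolDim = as.integer(boolDim), intDim = as.integer(intDim),
      floatDim = as.integer(floatDim), hiddenSize = as.integer(hiddenSize),
      nLabels = as.integer(nLabels), pipeHeadSize = as.integer(pipeHeadSize),
      headDepth = as.integer(headDepth), activation = activation)
}

#' Width of the fused physicochemical vector (boolDim + intDim + floatDim)
#' @param config a [ModelConfig-class].
#' @return integer width (30 at defaults).
#' @export
fusedWidth <- function(config) config@boolDim + config@intDim + config@floatDim

#' Width of the concat fusion vector (fused physchem + encoder hidden)
#' @param config a [ModelConfig-class].
#' @return integer width (798 at defaults).
#' @export
concatWidth <- function(config) fusedWidth(config) + config@hiddenSize

#' Training protocol configuration
#'
#' Defaults mirror the reference protocol: 7:1.5:1.5 splits, batch 32,
#' learning rate 5e-5, AdamW, early stopping with patience 5, at most 30
#' epochs, five seeds.
#'
#' @slot splitRatio numeric(3) summing to 1.
#' @slot batchSize,patience,maxEpochs,nSeeds integer scalars.
#' @slot learningRate,weightDecay,pipeLossWeight numeric scalars; the pipe
#'   stage-1 loss enters the total with weight `pipeLossWeight` (1).
#' @slot seeds integer vector of length `nSeeds`.
#' @slot freezeEncoder if TRUE the encoder weights stay fixed during
#'   fine-tuning; default FALSE (trainable).
#' @slot stageWise if TRUE the pipe model trains stage 1 then stage 2
#'   instead of end-to-end.
#' @export
setClass("TrainConfig", representation(
  splitRatio = "numeric", batchSize = "integer", learningRate = "numeric",
  patience = "integer", maxEpochs = "integer", nSeeds = "integer",
  seeds = "integer", weightDecay = "numeric", pipeLossWeight = "numeric",
  freezeEncoder = "logical", stageWise = "logical"))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (abs(sum(object@splitRatio) - 1) > 1e-9)
    msgs <- c(msgs, "split fractions must sum to 1")
  if (length(object@splitRatio) != 3)
    msgs <- c(msgs, "splitRatio must have 3 entries (train/val/test)")
  if (object@patience >= object@maxEpochs)
    msgs <- c(msgs, "patience must be < maxEpochs")
  if (length(object@seeds) != object@nSeeds)
    msgs <- c(msgs, "seeds length must equal nSeeds")
  if (length(msgs)) msgs else TRUE
})

#' @param splitRatio,batchSize,learningRate,patience,maxEpochs,nSeeds,seeds,weightDecay,pipeLossWeight,freezeEncoder,stageWise
#'   see slots.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(splitRatio = c(7, 1.5, 1.5) / 10, batchSize = 32L,
                        learningRate = 5e-5, patience = 5L, maxEpochs = 30L,
                        nSeeds = 5L, seeds = seq_len(nSeeds),
                        weightDecay = 0.01, pipeLossWeight = 1,
                        freezeEncoder = FALSE, stageWise = FALSE) {
  new("TrainConfig", splitRatio = splitRatio / sum(splitRatio),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      patience = as.integer(patience), maxEpochs = as.integer(maxEpochs),
      nSeeds = as.integer(nSeeds), seeds = as.integer(seeds),
      weightDecay = weightDecay, pipeLossWeight = pipeLossWeight,
      freezeEncoder = freezeEncoder, stageWise = stageWise)
}

#' Synthetic molecule generator configuration
#'
#' Controls the SMILES grammar sampler and the planted label signal. In
#' `structure_driven` mode every label is a noisy copy of the planted
#' motif indicator (a nitro-like `N(=O)=O` fragment by default), which by
#' construction is independent of all 13 descriptors; in `feature_driven`
#' mode labels follow a logistic rule on the standardized descriptors;
#' `mixed` assigns half the labels to each regime.
#'
#' @slot nMolecules,seed,nLabels,maxHeavyAtoms integer scalars.
#' @slot ringProbability,branchProbability,motifProbability,noiseRate
#'   probabilities in `[0,1]`.
#' @slot labelMode one of feature_driven, structure_driven, mixed.
#' @slot motif the planted substring.
#' @slot signalStrength L2 norm of the logistic coefficient vector in
#'   standardized feature space (feature_driven mode).
#' @export
setClass("GeneratorConfig", representation(
  nMolecules = "integer", seed = "integer", maxHeavyAtoms = "integer",
  ringProbability = "numeric", branchProbability = "numeric",
  motifProbability = "numeric", labelMode = "character",
  noiseRate = "numeric", nLabels = "integer", motif = "character",
  signalStrength = "numeric"))

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  p <- c(object@ringProbability, object@branchProbability,
         object@motifProbability, object@noiseRate)
  if (any(p < 0 | p > 1)) msgs <- c(msgs, "probabilities must lie in [0,1]")
  if (object@nMolecules < 0) msgs <- c(msgs, "nMolecules must be >= 0")
  if (!object@labelMode %in% c("feature_driven", "structure_driven", "mixed"))
    msgs <- c(msgs, "unknown labelMode")
  if (length(msgs)) msgs else TRUE
})

#' @param nMolecules,seed,maxHeavyAtoms,ringProbability,branchProbability,motifProbability,labelMode,noiseRate,nLabels,motif,signalStrength
#'   see slots.
#' @rdname GeneratorConfig-class
#' @export
GeneratorConfig <- function(nMolecules = 1000L, seed = 1L,
                            maxHeavyAtoms = 24L, ringProbability = 0.3,
                            branchProbability = 0.25,
                            motifProbability = 0.3,
                            labelMode = "feature_driven", noiseRate = 0.05,
                            nLabels = 21L, motif = "N(=O)=O",
                            signalStrength = 4) {
  new("GeneratorConfig", nMolecules = as.integer(nMolecules),
      seed = as.integer(seed), maxHeavyAtoms = as.integer(maxHeavyAtoms),
      ringProbability = ringProbability,
      branchProbability = branchProbability,
      motifProbability = motifProbability, labelMode = labelMode,
      noiseRate = noiseRate, nLabels = as.integer(nLabels), motif = motif,
      signalStrength = signalStrength)
}

## ---------------------------------------------------------------------------
## Models & results
## ---------------------------------------------------------------------------

#' A (pre-)trained SMILES transformer encoder
#'
#' @slot config an [EncoderConfig-class].
#' @slot vocab the [TokenVocab-class] the encoder was built against.
#' @slot params named list of weight matrices.
#' @slot vocabHash hash tying the weights to the vocabulary.
#' @export
setClass("SmilesEncoder", representation(
  config = "EncoderConfig", vocab = "TokenVocab", params = "list",
  vocabHash = "character"))

#' A fusion model (one of the six architectures)
#'
#' @slot config a [ModelConfig-class].
#' @slot params named list of weight matrices for the fusion layers.
#' @slot encoder a [SmilesEncoder-class], or NULL for pure-DNN models.
#' @export
setClass("FusionModel", representation(
  config = "ModelConfig", params = "list", encoder = "ANY"))

#' Per-model prediction matrix
#'
#' @slot tag model identifier (usually the architecture name).
#' @slot probs n x nLabels matrix of probabilities in `[0,1]`.
#' @slot labelNames column names of `probs`.
#' @export
setClass("PredictionMatrix", representation(
  tag = "character", probs = "matrix", labelNames = "character"))

setValidity("PredictionMatrix", function(object) {
  p <- object@probs
  if (length(p) && (min(p) < 0 || max(p) > 1))
    return("probabilities must lie in [0,1]")
  if (ncol(p) != length(object@labelNames))
    return("labelNames length must equal ncol(probs)")
  TRUE
})

#' @param tag,probs,labelNames see slots.
#' @rdname PredictionMatrix-class
#' @export
PredictionMatrix <- function(probs, tag = "model",
                             labelNames = colnames(probs)) {
  if (is.null(labelNames)) labelNames <- sprintf("label_%d", seq_len(ncol(probs)))
  colnames(probs) <- labelNames
  new("PredictionMatrix", tag = tag, probs = probs, labelNames = labelNames)
}

#' One training run (one seed)
#'
#' @slot seed integer seed of the run.
#' @slot trainLoss,valLoss epoch-wise losses.
#' @slot bestEpoch,stopEpoch best-validation epoch and stopping epoch.
#' @slot model the restored best-validation [FusionModel-class].
#' @slot testMetrics list with the held-out [MetricsReport-class] (and the
#'   prediction matrix).
#' @export
setClass("RunRecord", representation(
  seed = "integer", trainLoss = "numeric", valLoss = "numeric",
  bestEpoch = "integer", stopEpoch = "integer", model = "ANY",
  testMetrics = "list"))

#' Per-label and aggregate classification metrics
#'
#' @slot perLabel data.frame with one row per label: n, prevalence,
#'   accuracy, auroc, f1, precision, recall (NA where undefined).
#' @slot macro named numeric of macro means over defined entries.
#' @export
setClass("MetricsReport",
         representation(perLabel = "data.frame", macro = "numeric"))

#' CYP450 substrate aggregation configuration
#'
#' @slot weights named numeric hepatic abundance weights for the CYP450
#'   subtypes (defaults 2C9 = 0.12, 2D6 = 0.04, 3A4 = 0.30).
#' @slot threshold decision threshold on aggregated scores.
#' @slot method one of dnn_synthesis, cyp3a4_direct, weighted_soft_vote.
#' @export
setClass("CypAggregationConfig", representation(
  weights = "numeric", threshold = "numeric", method = "character"))

setValidity("CypAggregationConfig", function(object) {
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (!object@method %in% c("dnn_synthesis", "cyp3a4_direct",
                            "weighted_soft_vote"))
    return("unknown aggregation method")
  TRUE
})

#' @param weights,threshold,method see slots.
#' @rdname CypAggregationConfig-class
#' @export
CypAggregationConfig <- function(weights = c(cyp2c9 = 0.12, cyp2d6 = 0.04,
                                             cyp3a4 = 0.30),
                                 threshold = 0.5,
                                 method = "weighted_soft_vote") {
  new("CypAggregationConfig", weights = weights, threshold = threshold,
      method = method)
}
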