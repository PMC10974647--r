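## Accessors and show methods.

#' Number of molecules in a set
#' @param x a MoleculeSet.
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname nMolecules
#' @export
setMethod("nMolecules", "MoleculeSet", function(x) length(x@ids))

#' Record identifiers
#' @param x a MoleculeSet.
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @rdname moleculeIds
#' @export
setMethod("moleculeIds", "MoleculeSet", function(x) x@ids)

#' SMILES strings of a molecule set
#' @param x a MoleculeSet.
#' @export
setGeneric("smilesStrings", function(x) standardGeneric("smilesStrings"))

#' @rdname smilesStrings
#' @export
setMethod("smilesStrings", "MoleculeSet", function(x) x@smiles)

#' Physicochemical feature table
#' @param x a MoleculeSet.
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname featureTable
#' @export
setMethod("featureTable", "MoleculeSet", function(x) x@features)

#' Binary label matrix (zero columns when unlabelled)
#' @param x a MoleculeSet.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "MoleculeSet", function(x) x@labels)

#' Governing feature schema
#' @param x a MoleculeSet.
#' @export
setGeneric("featureSchema", function(x) standardGeneric("featureSchema"))

#' @rdname featureSchema
#' @export
setMethod("featureSchema", "MoleculeSet", function(x) x@schema)

#' All input feature names of a schema, in canonical order
#' @param schema a FeatureSchema.
#' @return character: bool, then integer, then float feature names.
#' @export
inputFeatures <- function(schema)
  c(schema@boolFeatures, schema@intFeatures, schema@floatFeatures)

#' Final (post-merge) label names of a schema
#' @param schema a FeatureSchema.
#' @export
finalLabels <- function(schema) schema@finalLabels

#' Raw (pre-merge) label names of a schema
#' @param schema a FeatureSchema.
#' @export
rawLabels <- function(schema) schema@rawLabels

#' Subset a MoleculeSet by index
#' @param x a MoleculeSet; \code{i} integer/logical index.
#' @param i,j,...,drop standard subsetting arguments (j/drop ignored).
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  lab <- if (ncol(x@labels)) x@labels[i, , drop = FALSE] else
    matrix(numeric(0), nrow = length(x@ids[i]), ncol = 0)
  new("MoleculeSet", ids = x@ids[i], smiles = x@smiles[i],
      features = x@features[i, , drop = FALSE], labels = lab,
      schema = x@schema)
})

#' Vocabulary size (number of token ids)
#' @param x a TokenVocab or SmilesEncoder.
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' @rdname vocabSize
#' @export
setMethod("vocabSize", "TokenVocab", function(x) length(x@tokens))

#' @rdname vocabSize
#' @export
setMethod("vocabSize", "SmilesEncoder", function(x) length(x@vocab@tokens))

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet with %d molecules\n", nMolecules(object)))
  cat(sprintf("  features: %d (%s...)\n", ncol(object@features),
              paste(head(colnames(object@features), 3), collapse = ", ")))
  if (ncol(object@labels))
    cat(sprintf("  labels: %d binary columns\n", ncol(object@labels)))
  else cat("  labels: none\n")
})

setMethod("show", "FeatureSchema", function(object) {
  cat(sprintf(
    "FeatureSchema: %d bool + %d int + %d float features; %d raw -> %d final labels\n",
    length(object@boolFeatures), length(object@intFeatures),
    length(object@floatFeatures), length(object@rawLabels),
    length(object@finalLabels)))
})

setMethod("show", "TokenVocab", function(object) {
  cat(sprintf("TokenVocab: %d tokens (%d merges, 5 specials)\n",
              length(object@tokens), length(object@merges)))
})

setMethod("show", "SmilesEncoder", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SmilesEncoder: %d layers, %d heads, H=%d, vocab %d, max_len %d, pooling %s\n",
    cfg@nLayers, cfg@nHeads, cfg@hiddenSize, cfg@vocabSize, cfg@maxLen,
    cfg@pooling))
})

setMethod("show", "FusionModel", function(object) {
  cat(sprintf("FusionModel <%s>: fused width %d, output %d labels%s\n",
              object@config@architecture, fusedWidth(object@config),
              object@config@nLabels,
              if (!is.null(object@encoder)) sprintf(", encoder H=%d",
                object@config@hiddenSize) else ""))
})

setMethod("show", "PredictionMatrix", function(object) {
  cat(sprintf("PredictionMatrix '%s': %d molecules x %d labels\n",
              object@tag, nrow(object@probs), ncol(object@probs)))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (macro means):\n")
  print(round(object@macro, 4))
})

setMethod("show", "RunRecord", function(object) {
  cat(sprintf("RunRecord seed=%d: stopped at epoch %d (best %d), val loss %.4f\n",
              object@seed, object@stopEpoch, object@bestEpoch,
              object@valLoss[object@bestEpoch]))
})
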