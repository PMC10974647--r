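## Reading, cleaning and normalizing molecule records.
##
## The JSON dialect accepted here is a minimal documented schema for
## DrugBank-style exports: one object (or an array of objects) per file,
## each with fields id, smiles, properties {name: value} and admet
## {name: 0/1}. Real DrugBank parsing is an adapter concern; this module
## owns the cleaning rules: drug-likeness filter flags are excluded from
## the inputs, incomplete records are dropped, and redundant raw labels
## are merged.

#' Read DrugBank-style JSON molecule records
#'
#' Each file holds one JSON object (or an array of objects) with fields
#' `id`, `smiles`, `properties` (named physicochemical values) and
#' `admet` (named 0/1 labels). Properties named among the schema's
#' excluded filters are dropped; properties unknown to the schema trigger
#' a warning and are ignored. Missing features become `NA` (use
#' [excludeIncomplete()] to drop such records). Records are returned
#' sorted by id.
#'
#' @param paths character vector of file paths.
#' @param schema a [FeatureSchema-class].
#' @return A [MoleculeSet-class] with raw (pre-merge) labels.
#' @export
readMoleculeJSON <- function(paths, schema = defaultFeatureSchema()) {
  recs <- list()
  for (p in paths) {
    obj <- tryCatch(jsonlite::read_json(p),
                    error = function(e)
                      stop("malformed JSON in file '", p, "': ",
                           conditionMessage(e), call. = FALSE))
    if (!is.null(obj$id) || !is.null(obj$smiles)) obj <- list(obj)
    recs <- c(recs, obj)
  }
  feats <- inputFeatures(schema)
  labs <- rawLabels(schema)
  n <- length(recs)
  fmat <- as.data.frame(matrix(NA_real_, n, length(feats),
                               dimnames = list(NULL, feats)))
  lmat <- matrix(NA_real_, n, length(labs), dimnames = list(NULL, labs))
  ids <- character(n)
  smi <- character(n)
  unknown <- character()
  for (i in seq_len(n)) {
    r <- recs[[i]]
    ids[i] <- if (!is.null(r$id)) as.character(r$id) else sprintf("rec_%d", i)
    smi[i] <- if (!is.null(r$smiles)) as.character(r$smiles) else NA_character_
    for (nm in names(r$properties)) {
      if (nm %in% feats) fmat[i, nm] <- as.numeric(r$properties[[nm]])
      else if (nm %in% schema@excludedFilters) next
      else unknown <- c(unknown, nm)
    }
    for (nm in names(r$admet)) {
      if (nm %in% labs) lmat[i, nm] <- as.numeric(r$admet[[nm]])
      else unknown <- c(unknown, nm)
    }
  }
  if (length(unknown))
    warning("ignoring unknown property names: ",
            paste(sort(unique(unknown)), collapse = ", "))
  ord <- order(ids)
  MoleculeSet(ids = ids[ord], smiles = smi[ord],
              features = fmat[ord, , drop = FALSE],
              labels = lmat[ord, , drop = FALSE], schema = schema)
}

#' Write / read molecule records as a delimited table
#'
#' Columns: `id`, `smiles`, one column per input feature, then one per
#' label. `readMoleculeTable(writeMoleculeTable(x))` reproduces the
#' records.
#'
#' @param mol a [MoleculeSet-class].
#' @param path output file; a `.tsv` extension selects tab separation.
#' @param schema a [FeatureSchema-class] (reader only).
#' @return the path (writer) or a [MoleculeSet-class] (reader).
#' @export
writeMoleculeTable <- function(mol, path) {
  df <- data.frame(id = moleculeIds(mol), smiles = smilesStrings(mol),
                   featureTable(mol), check.names = FALSE)
  if (ncol(labelMatrix(mol))) df <- cbind(df, labelMatrix(mol))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMoleculeTable
#' @export
readMoleculeTable <- function(path, schema = defaultFeatureSchema()) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  feats <- intersect(inputFeatures(schema), colnames(df))
  known <- c(rawLabels(schema), finalLabels(schema))
  labs <- intersect(colnames(df), known)
  labm <- if (length(labs)) as.matrix(df[, labs, drop = FALSE]) else NULL
  extra <- setdiff(colnames(df), c("id", "smiles", feats, labs))
  labGeneric <- grep("^label_", extra, value = TRUE)
  if (length(labGeneric)) {
    gm <- as.matrix(df[, labGeneric, drop = FALSE])
    labm <- if (is.null(labm)) gm else cbind(labm, gm)
  }
  sch <- schema
  if (length(labGeneric)) {
    sch <- FeatureSchema(schema@boolFeatures, schema@intFeatures,
                         schema@floatFeatures, schema@excludedFilters,
                         rawLabels = c(schema@rawLabels, labGeneric),
                         mergeRules = schema@mergeRules,
                         mergeOp = schema@mergeOp)
  }
  MoleculeSet(ids = as.character(df$id), smiles = df$smiles,
              features = df[, feats, drop = FALSE], labels = labm,
              schema = sch)
}

#' Drop records with any missing feature or label
#'
#' A record is retained only if its SMILES, every schema input feature
#' and (when the set is labelled) every label entry are present. The
#' number of dropped records is reported via `message()`. The operation
#' is idempotent.
#'
#' @param mol a [MoleculeSet-class].
#' @return the filtered [MoleculeSet-class].
#' @export
excludeIncomplete <- function(mol) {
  feats <- inputFeatures(featureSchema(mol))
  fm <- featureTable(mol)[, feats, drop = FALSE]
  ok <- !is.na(smilesStrings(mol)) & nzchar(smilesStrings(mol)) &
    rowSums(is.na(fm)) == 0
  if (ncol(labelMatrix(mol)))
    ok <- ok & rowSums(is.na(labelMatrix(mol))) == 0
  dropped <- sum(!ok)
  if (dropped > 0)
    message("excludeIncomplete: dropped ", dropped, " of ",
            nMolecules(mol), " records")
  mol[ok]
}

#' Merge semantically redundant raw labels
#'
#' Applies the schema's merge rules (by default: human intestinal
#' absorption absorbs Caco-2 permeability; p-glycoprotein inhibitor I/II
#' merge; hERG inhibition I/II merge), reducing the raw label matrix to
#' the schema's final labels. Sources combine with logical OR by default
#' (`mergeOp = "and"` on the schema selects AND).
#'
#' @param mol a [MoleculeSet-class] carrying raw labels.
#' @return the [MoleculeSet-class] with final labels.
#' @export
mergeLabels <- function(mol) {
  schema <- featureSchema(mol)
  lab <- labelMatrix(mol)
  src <- unlist(schema@mergeRules, use.names = FALSE)
  miss <- setdiff(src, colnames(lab))
  if (length(miss))
    stop("mergeLabels: merge source label(s) missing: ",
         paste(miss, collapse = ", "))
  out <- matrix(NA_real_, nrow(lab), length(finalLabels(schema)),
                dimnames = list(NULL, finalLabels(schema)))
  for (nm in finalLabels(schema)) {
    if (nm %in% names(schema@mergeRules)) {
      block <- lab[, schema@mergeRules[[nm]], drop = FALSE]
      out[, nm] <- if (schema@mergeOp == "or")
        as.numeric(rowSums(block) > 0) else as.numeric(rowSums(block) == ncol(block))
    } else {
      out[, nm] <- lab[, nm]
    }
  }
  new("MoleculeSet", ids = mol@ids, smiles = mol@smiles,
      features = mol@features, labels = out, schema = schema)
}

#' Fit z-score normalization statistics on the training split
#'
#' Means and standard deviations of the integer and float descriptors.
#' Boolean descriptors are left untouched by [applyNormalization()].
#' Fitting on fewer than two records, or on a constant feature, is an
#' error (the feature is named).
#'
#' @param mol the training-split [MoleculeSet-class].
#' @return A [NormalizationStats-class].
#' @export
fitNormalization <- function(mol) {
  schema <- featureSchema(mol)
  numFeats <- c(schema@intFeatures, schema@floatFeatures)
  X <- as.matrix(featureTable(mol)[, numFeats, drop = FALSE])
  if (nrow(X) < 2)
    stop("fitNormalization: need at least 2 records to estimate a standard deviation")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  bad <- numFeats[!is.finite(sdv) | sdv == 0]
  if (length(bad))
    stop("fitNormalization: zero-variance feature(s): ",
         paste(bad, collapse = ", "))
  new("NormalizationStats", center = mu, scale = sdv)
}

#' Apply normalization statistics to a molecule set
#'
#' @param mol a [MoleculeSet-class].
#' @param stats a [NormalizationStats-class] fitted with
#'   [fitNormalization()] on the training split.
#' @return the [MoleculeSet-class] with z-scored numeric features.
#' @export
applyNormalization <- function(mol, stats) {
  f <- featureTable(mol)
  nms <- names(stats@center)
  miss <- setdiff(nms, colnames(f))
  if (length(miss))
    stop("applyNormalization: features missing from records: ",
         paste(miss, collapse = ", "))
  f[nms] <- sweep(sweep(as.matrix(f[nms]), 2, stats@center), 2,
                  stats@scale, `/`)
  new("MoleculeSet", ids = mol@ids, smiles = mol@smiles, features = f,
      labels = mol@labels, schema = mol@schema)
}

#' Serialize normalization statistics as JSON
#' @param stats a [NormalizationStats-class].
#' @param path file path.
#' @export
writeNormalizationStats <- function(stats, path) {
  jsonlite::write_json(list(center = as.list(stats@center),
                            scale = as.list(stats@scale)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeNormalizationStats
#' @export
readNormalizationStats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NormalizationStats", center = unlist(obj$center),
      scale = unlist(obj$scale))
}
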