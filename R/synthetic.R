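## Synthetic molecule generator: grammar-valid SMILES with a planted,
## named structural motif, 13 physicochemical descriptors derived from the
## string, and binary labels with controllable dependence on either the
## descriptors (feature_driven) or the motif (structure_driven).
##
## The motif is inserted AFTER the feature-relevant scaffold composition
## is fixed, and every descriptor is computed on the scaffold with motif
## occurrences removed, so motif presence is independent of all 13
## descriptors by construction (and verified empirically in the tests).

ATOM_SYMBOLS <- c("C", "N", "O", "S", "F", "Cl")
ATOM_WEIGHTS <- c(0.52, 0.14, 0.14, 0.05, 0.08, 0.07)

sampleAtom <- function() sample(ATOM_SYMBOLS, 1L, prob = ATOM_WEIGHTS)

genRingUnit <- function(k) {
  m <- min(k, sample(5:6, 1L))
  if (runif(1) < 0.5 && m == 6L) {
    toks <- c("c1", rep("c", 4L), "c1")
  } else {
    inner <- vapply(seq_len(m - 2L), function(i)
      sample(c("C", "C", "C", "N", "O"), 1L), character(1))
    toks <- c("C1", inner, "C1")
  }
  list(tokens = toks, used = m)
}

genChain <- function(k, depth, cfg) {
  out <- character()
  while (k > 0L) {
    if (depth == 0L && k >= 5L && runif(1) < cfg@ringProbability) {
      ring <- genRingUnit(k)
      out <- c(out, ring$tokens)
      k <- k - ring$used
      next
    }
    out <- c(out, sampleAtom())
    k <- k - 1L
    if (k >= 1L && runif(1) < 0.10) {          # occasional double bond
      out <- c(out, "=", sampleAtom())
      k <- k - 1L
    }
    if (k >= 1L && depth < 2L && runif(1) < cfg@branchProbability) {
      bk <- min(k, sample(1:3, 1L))
      out <- c(out, "(", genChain(bk, depth + 1L, cfg), ")")
      k <- k - bk
    }
  }
  out
}

## Insert the motif after a random top-level atom character.
insertMotif <- function(s, motif) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - c(0, (chars == ")")[-length(chars)]))
  ok <- which(depth == 0 & chars %in% c("C", "N", "O", "S", "c"))
  ok <- ok[!(chars[ok] == "C" & c(chars[-1L], "")[ok] == "l")]
  if (!length(ok)) return(paste0(s, motif))
  at <- ok[sample.int(length(ok), 1L)]
  paste0(substr(s, 1L, at), motif, substr(s, at + 1L, nchar(s)))
}

#' Generate grammar-valid synthetic SMILES strings
#'
#' Molecules are chains over C/N/O/S/F/Cl with optional double bonds,
#' nested branches and 5-6 membered (optionally aromatic) rings. With
#' probability `motifProbability` a planted motif (nitro-like `N(=O)=O`
#' by default) is inserted at a random top-level position, independently
#' of molecule size and composition.
#'
#' @param config a [GeneratorConfig-class].
#' @return character vector of length `nMolecules`, with attribute
#'   `motif` (logical vector: was the motif planted).
#' @export
generateSmiles <- function(config) {
  set.seed(deriveSeed(config@seed, 1L))
  n <- config@nMolecules
  out <- character(n)
  hasMotif <- logical(n)
  for (i in seq_len(n)) {
    k <- sample(4:config@maxHeavyAtoms, 1L)
    s <- paste(genChain(k, 0L, config), collapse = "")
    hasMotif[i] <- runif(1) < config@motifProbability
    if (hasMotif[i]) s <- insertMotif(s, config@motif)
    out[i] <- s
  }
  attr(out, "motif") <- hasMotif
  out
}

#' Check a SMILES string against the generator's grammar
#'
#' Verifies the character set, balanced non-empty parentheses, sequentially
#' matched ring-closure digits, and that bonds are not dangling. This is a
#' grammar check, not a chemical-validity check.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
isGrammarValid <- function(smiles) {
  vapply(smiles, function(s) {
    if (!nzchar(s)) return(FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    allowed <- c("C", "N", "O", "S", "F", "l", "c", "=", "(", ")",
                 as.character(1:9))
    if (!all(chars %in% allowed)) return(FALSE)
    depth <- 0L
    prev <- ""
    open <- character()          # open ring digits
    for (ch in chars) {
      if (ch == "(") {
        if (prev %in% c("", "(", "=")) return(FALSE)
        depth <- depth + 1L
      } else if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L || prev %in% c("(", "=")) return(FALSE)
      } else if (ch == "=") {
        if (prev %in% c("", "=")) return(FALSE)
      } else if (ch %in% as.character(1:9)) {
        if (!prev %in% c("C", "N", "O", "S", "c", "l")) return(FALSE)
        if (ch %in% open) open <- setdiff(open, ch) else open <- c(open, ch)
      } else if (ch == "l") {
        if (prev != "C") return(FALSE)
      }
      prev <- ch
    }
    depth == 0L && prev != "=" && length(open) == 0L &&
      grepl("[CNOSFc]", s)
  }, logical(1), USE.NAMES = FALSE)
}

countChar <- function(s, ch) {
  lengths(regmatches(s, gregexpr(ch, s, fixed = TRUE)))
}

#' Derive the 13 physicochemical descriptors from SMILES strings
#'
#' Integer descriptors are direct counts on the scaffold (occurrences of
#' the planted motif are removed first, so descriptors are independent of
#' motif presence): heteroatom count, ring pair count, branch count,
#' halogen count, and a within-batch length decile. Float descriptors are
#' smooth functions of composition plus Gaussian jitter; the Boolean
#' bioavailability flag is a thresholded lipophilicity/polar-surface
#' composite.
#'
#' @param smiles character vector of grammar-valid SMILES.
#' @param seed integer seed for the jitter.
#' @param motif motif substring removed before counting.
#' @return data.frame with the 13 default-schema columns.
#' @export
deriveFeatures <- function(smiles, seed = 1L, motif = "N(=O)=O") {
  set.seed(deriveSeed(seed, 2L))
  s <- gsub(motif, "", smiles, fixed = TRUE)
  nC <- countChar(s, "C") - countChar(s, "Cl") + countChar(s, "c")
  nN <- countChar(s, "N")
  nO <- countChar(s, "O")
  nS <- countChar(s, "S")
  nF <- countChar(s, "F")
  nCl <- countChar(s, "Cl")
  hetero <- nN + nO + nS
  ringPairs <- lengths(regmatches(s, gregexpr("[1-9]", s))) %/% 2L
  branches <- countChar(s, "(")
  halogens <- nF + nCl
  heavy <- nC + hetero + halogens
  len <- nchar(s)
  decile <- as.integer(ceiling(10 * rank(len, ties.method = "average") /
                                 length(len)))
  n <- length(s)
  jit <- function(sd) rnorm(n, 0, sd)
  logp <- 0.4 * nC - 0.6 * hetero + 0.3 * halogens + jit(0.4)
  logs <- -0.25 * nC + 0.35 * nO + jit(0.4)
  pka <- 7 + 1.1 * nN - 0.7 * nO + jit(0.5)
  psa <- 20.2 * nO + 15.8 * nN + 25.3 * nS + jit(3)
  wsol <- pmax(0, 60 - 2.2 * heavy - 4 * logp) + jit(2)
  mr <- 4.1 * heavy + 1.9 * halogens + jit(1.5)
  polz <- 1.6 * heavy + 0.9 * halogens + jit(0.8)
  bav <- as.numeric(logp < 3.5 & psa < 90)
  data.frame(
    bioavailability = bav,
    physiological_charge = as.integer(hetero),
    hydrogen_acceptor_count = as.integer(ringPairs),
    hydrogen_donor_count = as.integer(branches),
    rotatable_bond_count = as.integer(halogens),
    number_of_rings = decile,
    logp = logp, logs = logs, pka = pka, water_solubility = wsol,
    polar_surface_area = psa, molar_refractivity = mr,
    polarizability = polz)
}

#' Assign binary labels with planted signal
#'
#' In `feature_driven` mode each label follows an independent logistic
#' rule on the standardized descriptors with coefficient norm
#' `signalStrength`; in `structure_driven` mode every label equals the
#' motif indicator; `mixed` assigns the first half of the labels to the
#' feature regime and the rest to the structure regime. Finally every
#' entry is flipped independently with probability `noiseRate`.
#'
#' @param features data.frame from [deriveFeatures()].
#' @param motifFlags logical vector of motif presence.
#' @param config a [GeneratorConfig-class].
#' @return n x nLabels 0/1 matrix with attributes `coefficients` (the
#'   logistic ground truth, or NULL) and `labelMode`.
#' @export
assignLabels <- function(features, motifFlags, config) {
  set.seed(deriveSeed(config@seed, 3L))
  n <- nrow(features)
  L <- config@nLabels
  X <- as.matrix(features)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  modes <- switch(config@labelMode,
    feature_driven = rep("f", L),
    structure_driven = rep("s", L),
    mixed = c(rep("f", floor(L / 2)), rep("s", L - floor(L / 2))))
  coefs <- NULL
  lab <- matrix(0, n, L)
  for (j in seq_len(L)) {
    if (modes[j] == "f") {
      w <- rnorm(ncol(Xs))
      w <- w / sqrt(sum(w * w)) * config@signalStrength
      coefs <- cbind(coefs, w)
      lab[, j] <- rbinom(n, 1, plogis(Xs %*% w))
    } else {
      lab[, j] <- as.numeric(motifFlags)
    }
  }
  if (config@noiseRate > 0) {
    flip <- matrix(rbinom(n * L, 1, config@noiseRate), n, L)
    lab <- abs(lab - flip)
  }
  colnames(lab) <- sprintf("label_%d", seq_len(L))
  attr(lab, "coefficients") <- coefs
  attr(lab, "labelMode") <- modes
  lab
}

#' Simulate a complete labelled molecule set
#'
#' Runs [generateSmiles()], [deriveFeatures()] and [assignLabels()] under
#' one seed and packs the result into a [MoleculeSet-class]. When
#' `nLabels` matches the schema's final label count the schema's label
#' names are used (so e.g. CYP450 columns exist for aggregation demos).
#'
#' @param config a [GeneratorConfig-class].
#' @param schema a [FeatureSchema-class] for naming.
#' @return list with `molecules` (a MoleculeSet) and `truth` (motif flags,
#'   logistic coefficients, per-label mode) for recovery tests.
#' @export
simulateMolecules <- function(config, schema = defaultFeatureSchema()) {
  smiles <- generateSmiles(config)
  motifFlags <- attr(smiles, "motif")
  feats <- deriveFeatures(as.character(smiles), seed = config@seed,
                          motif = config@motif)
  lab <- assignLabels(feats, motifFlags, config)
  truth <- list(motif = motifFlags,
                coefficients = attr(lab, "coefficients"),
                labelMode = attr(lab, "labelMode"),
                config = config)
  attributes(lab) <- attributes(lab)[c("dim", "dimnames")]
  if (config@nLabels == length(finalLabels(schema))) {
    colnames(lab) <- finalLabels(schema)
  } else {
    schema <- FeatureSchema(schema@boolFeatures, schema@intFeatures,
                            schema@floatFeatures, schema@excludedFilters,
                            rawLabels = colnames(lab),
                            mergeRules = list(), mergeOp = schema@mergeOp)
  }
  mol <- MoleculeSet(smiles = as.character(smiles), features = feats,
                     labels = lab, schema = schema)
  list(molecules = mol, truth = truth)
}
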