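## Byte-pair-encoding tokenizer over SMILES strings.
##
## The base alphabet is the set of single characters seen in the training
## corpus (multi-character atoms such as "Cl" are learned as merges, not
## special-cased). Merges are learned greedily by descending corpus pair
## frequency; frequency ties break lexicographically on the pair so a
## retrain on the same corpus is byte-identical across platforms.

SPECIAL_TOKENS <- c(pad = "[PAD]", unk = "[UNK]", cls = "[CLS]",
                    sep = "[SEP]", mask = "[MASK]")

## Greedy left-to-right, non-overlapping application of one merge to a
## symbol vector ("CCC" + merge (C,C) -> ("CC","C")).
mergePairVec <- function(x, a, b) {
  n <- length(x)
  if (n < 2L) return(x)
  hit <- which(x[-n] == a & x[-1L] == b)
  if (!length(hit)) return(x)
  keep <- hit[1L]
  if (length(hit) > 1L)
    for (h in hit[-1L]) if (h > keep[length(keep)] + 1L) keep <- c(keep, h)
  x[keep] <- paste0(a, b)
  x[-(keep + 1L)]
}

#' Train a byte-pair-encoding vocabulary on a SMILES corpus
#'
#' Starting from single characters, the most frequent adjacent symbol pair
#' is merged repeatedly until `vocabSize` tokens exist (5 specials + base
#' characters + merges) or no pair reaches `minFrequency`. Ties in pair
#' frequency break lexicographically, making training deterministic.
#'
#' @param corpus character vector of SMILES strings (non-empty).
#' @param vocabSize target total vocabulary size.
#' @param minFrequency minimum corpus frequency for a pair to merge.
#' @return A [TokenVocab-class].
#' @examples
#' v <- trainBPE(c("CCO", "CCN", "CCC"), vocabSize = 10)
#' v@merges[[1]]  # c("C", "C"): the most frequent pair
#' @export
trainBPE <- function(corpus, vocabSize = 512L, minFrequency = 2L) {
  if (length(corpus) == 0L || all(!nzchar(corpus)))
    stop("trainBPE: empty corpus")
  tab <- table(corpus)
  uniq <- names(tab)
  wt <- as.numeric(tab)
  seqs <- strsplit(uniq, "", fixed = TRUE)
  base <- sort(unique(unlist(seqs, use.names = FALSE)))
  nSpecial <- length(SPECIAL_TOKENS)
  if (vocabSize < nSpecial + length(base))
    stop("trainBPE: vocabSize smaller than specials + base alphabet (",
         nSpecial + length(base), ")")
  merges <- list()
  tokens <- c(unname(SPECIAL_TOKENS), base)
  while (length(tokens) < vocabSize) {
    lens <- lengths(seqs)
    live <- lens >= 2L
    if (!any(live)) break
    left <- unlist(lapply(seqs[live], function(s) s[-length(s)]),
                   use.names = FALSE)
    right <- unlist(lapply(seqs[live], function(s) s[-1L]),
                    use.names = FALSE)
    w <- rep(wt[live], lens[live] - 1L)
    key <- paste(left, right, sep = "\x01")
    cnt <- vapply(split(w, key), sum, numeric(1))
    cnt <- cnt[cnt >= minFrequency]
    if (!length(cnt)) break
    best <- names(cnt)[cnt == max(cnt)]
    best <- sort(best)[1L]                       # lexicographic tie-break
    pair <- strsplit(best, "\x01", fixed = TRUE)[[1L]]
    newTok <- paste0(pair[1L], pair[2L])
    merges[[length(merges) + 1L]] <- pair
    tokens <- c(tokens, newTok)
    touch <- vapply(seqs, function(s) {
      n <- length(s)
      n >= 2L && any(s[-n] == pair[1L] & s[-1L] == pair[2L])
    }, logical(1))
    seqs[touch] <- lapply(seqs[touch], mergePairVec, pair[1L], pair[2L])
  }
  new("TokenVocab", tokens = tokens, merges = merges,
      specials = SPECIAL_TOKENS)
}

tokenIds <- function(vocab) setNames(seq_along(vocab@tokens) - 1L,
                                     vocab@tokens)

specialIds <- function(vocab) {
  ids <- tokenIds(vocab)
  setNames(ids[unname(vocab@specials)], names(vocab@specials))
}

## Apply the learned merges, in order, to one string.
tokenizeOne <- function(s, vocab) {
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (m in vocab@merges) {
    if (length(x) < 2L) break
    x <- mergePairVec(x, m[1L], m[2L])
  }
  x
}

#' Encode SMILES strings to padded token-id matrices
#'
#' Each string is tokenized with the learned merges, wrapped in
#' `[CLS] ... [SEP]`, truncated at the tail (keeping `[SEP]`) when longer
#' than `maxLen`, and padded with `[PAD]` to `maxLen`. Characters outside
#' the training alphabet map to `[UNK]`.
#'
#' @param smiles character vector.
#' @param vocab a [TokenVocab-class].
#' @param maxLen maximum sequence length including specials (>= 3).
#' @return list with `ids` (n x maxLen integer matrix of 0-based token
#'   ids), `mask` (n x maxLen attention mask, 1 = real token), `lengths`
#'   (real lengths incl. specials) and `strings`.
#' @export
encodeSmiles <- function(smiles, vocab, maxLen = 128L) {
  maxLen <- as.integer(maxLen)
  if (maxLen < 3L) stop("encodeSmiles: maxLen must be >= 3")
  ids <- tokenIds(vocab)
  sp <- specialIds(vocab)
  uniq <- unique(smiles)
  enc <- lapply(uniq, function(s) {
    toks <- tokenizeOne(s, vocab)
    v <- unname(ids[toks])
    v[is.na(v)] <- sp[["unk"]]
    v <- c(sp[["cls"]], v, sp[["sep"]])
    if (length(v) > maxLen) v <- c(v[seq_len(maxLen - 1L)], sp[["sep"]])
    v
  })
  names(enc) <- uniq
  idsMat <- matrix(sp[["pad"]], nrow = length(smiles), ncol = maxLen)
  maskMat <- matrix(0L, nrow = length(smiles), ncol = maxLen)
  lens <- integer(length(smiles))
  for (i in seq_along(smiles)) {
    v <- enc[[smiles[i]]]
    idsMat[i, seq_along(v)] <- v
    maskMat[i, seq_along(v)] <- 1L
    lens[i] <- length(v)
  }
  list(ids = idsMat, mask = maskMat, lengths = lens, strings = smiles)
}

#' Decode token ids back to a SMILES string
#'
#' Special tokens are stripped; remaining tokens concatenate. For any
#' string over the training alphabet, `decodeSmiles(encodeSmiles(s))`
#' reproduces `s` exactly (provided it fits in `maxLen`).
#'
#' @param ids integer vector (0-based token ids) or the `ids` matrix row
#'   from [encodeSmiles()].
#' @param vocab a [TokenVocab-class].
#' @return character scalar.
#' @export
decodeSmiles <- function(ids, vocab) {
  toks <- vocab@tokens[as.integer(ids) + 1L]
  toks <- toks[!toks %in% vocab@specials]
  paste(toks, collapse = "")
}

#' Serialize / read a vocabulary as JSON
#' @param vocab a [TokenVocab-class].
#' @param path file path.
#' @export
writeVocab <- function(vocab, path) {
  obj <- list(tokens = vocab@tokens,
              merges = lapply(vocab@merges, identity),
              specials = as.list(vocab@specials))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeVocab
#' @export
readVocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  merges <- if (is.matrix(obj$merges)) {
    lapply(seq_len(nrow(obj$merges)), function(i) obj$merges[i, ])
  } else if (length(obj$merges)) {
    lapply(obj$merges, unlist)
  } else list()
  new("TokenVocab", tokens = obj$tokens, merges = merges,
      specials = unlist(obj$specials))
}

## Hash of the token table; ties encoder checkpoints to the vocabulary
## they were trained with.
vocabHash <- function(vocab) {
  fnvHash(paste(vocab@tokens, collapse = "\x01"))
}
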