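## Small shared helpers.

## FNV-1a style 31-bit string hash (hex). Used for vocabulary hashes and
## run-manifest digests; stability across platforms matters, cryptographic
## strength does not.
fnvHash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x01")))
  h <- 2166136261 %% 2^31
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b)) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

fileDigest <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  fnvHash(readChar(path, file.info(path)$size, useBytes = TRUE))
}
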