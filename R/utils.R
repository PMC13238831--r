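# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of nucleotide strings
#' @param x character vector of A/C/G/T sequences.
#' @return character vector.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate in frame 0, truncating to a whole number of codons.
translate_nt <- function(x) {
  n <- nchar(x) %/% 3L * 3L
  out <- character(length(x))
  ok <- n >= 3L
  if (any(ok)) {
    out[ok] <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(substr(x[ok], 1L, n[ok])),
                            no.init.codon = TRUE)
    ))
  }
  out
}

# Deterministic 31-bit hash of a string, for per-individual seed streams.
hash_id <- function(id) {
  vapply(as.character(id), function(s) {
    v <- utf8ToInt(s)
    h <- 0
    for (x in v) h <- (h * 131 + x) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a reproducible sub-seed from a master seed and a label.
derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) + as.numeric(hash_id(id))) %% 2147483647)
}

phred_char <- function(q) {
  intToUtf8(pmin(pmax(as.integer(q), 0L), 41L) + 33L, multiple = FALSE)
}

# BLOSUM62, loaded lazily from Biostrings.
blosum62 <- function() {
  if (is.null(the$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$BLOSUM62 <- e$BLOSUM62
  }
  the$BLOSUM62
}

# Split strings into per-character matrices/vectors.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
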