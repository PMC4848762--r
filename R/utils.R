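# Internal string/sequence helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

#' @noRd
.is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

#' Reverse-complement a character vector of DNA sequences.
#' @noRd
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between each string in `x` and a single reference of the
#' same length. Vectorized over `x` (one pass per reference position), which is
#' what makes anchor checks cheap on large read batches.
#' @noRd
.hamming_to_ref <- function(x, ref) {
  n <- nchar(ref)
  d <- integer(length(x))
  for (i in seq_len(n)) {
    d <- d + (substr(x, i, i) != substr(ref, i, i))
  }
  d
}

#' Pairwise Hamming distances between a batch of equal-length strings and a
#' dictionary. Returns an length(x) x length(dict) integer matrix.
#' @noRd
.hamming_matrix <- function(x, dict) {
  stopifnot(length(dict) >= 1L)
  w <- nchar(dict[1L])
  qm <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
               nrow = length(x), ncol = w, byrow = TRUE)
  out <- matrix(0L, nrow = length(x), ncol = length(dict))
  for (j in seq_along(dict)) {
    dj <- strsplit(dict[j], "", fixed = TRUE)[[1L]]
    out[, j] <- as.integer(rowSums(qm != matrix(dj, nrow = length(x),
                                                ncol = w, byrow = TRUE)))
  }
  out
}

#' Read sequences from a FASTQ file (plain or gzipped) as a character vector.
#' @noRd
.read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write a character vector of sequences as FASTQ (constant quality).
#' @noRd
.write_fastq <- function(seqs, path, names = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names)) names <- sprintf("read%d", seq_along(seqs))
  names(x) <- names
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Draw `size` items from `prob` weights as a multinomial count vector.
#' Degenerate cases (size 0 or all-zero weights) return zeros.
#' @noRd
.rmultinom1 <- function(size, prob) {
  if (size <= 0 || sum(prob) <= 0) {
    return(integer(length(prob)))
  }
  as.integer(stats::rmultinom(1L, size = size, prob = prob))
}
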