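#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `A/C/G/T` (case preserved, other
#' characters left in place after reversal).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAT"))
revcomp <- function(x) {
  .cpp_revcomp(as.character(x))
}

#' Canonical form of fixed-length k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement; shotgun reads do not observe strand, so
#' counting is done on canonical forms.
#'
#' @param x character vector of k-mers (A/C/G/T only; others give `NA`).
#' @return character vector of canonical k-mers.
#' @export
#' @examples
#' canonical_kmer(c("TTTT", "ACGT", "GGGA"))
canonical_kmer <- function(x) {
  .cpp_canonical(as.character(x))
}

#' Random DNA sequence
#'
#' @param n length in bases.
#' @return a single DNA string of length `n` with i.i.d. uniform bases,
#'   drawn from R's current RNG stream.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all k-length windows of a string (plain R; used by oracles and small jobs)
seq_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
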