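# Independent brute-force oracles used across the test files. These stay
# deliberately naive (plain string ops, full enumeration) and independent
# of the package's compiled path.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  if (s <= rc) s else rc
}

# exhaustive positional enumeration of canonical k-mer counts
oracle_count_kmers <- function(reads, k) {
  acc <- character(0)
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    wins <- substring(r, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    wins <- wins[!grepl("[^ACGT]", wins)]
    acc <- c(acc, vapply(wins, oracle_canonical, "", USE.NAMES = FALSE))
  }
  tab <- table(acc)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

# count occurrences of a k-mer (canonical sense) in a genome string
oracle_substring_count <- function(genome, kmer) {
  cnt <- function(pat) {
    # overlap-aware scan (gregexpr skips overlapping hits)
    n <- 0; start <- 1
    repeat {
      i <- regexpr(pat, substring(genome, start), fixed = TRUE)
      if (i < 0) break
      n <- n + 1
      start <- start + i
    }
    n
  }
  rc <- oracle_revcomp(kmer)
  if (kmer == rc) cnt(kmer) else cnt(kmer) + cnt(rc)
}

# two-group normal likelihood-ratio LOD with MLE variances
oracle_lod <- function(y, g) {
  n <- length(y)
  ll <- function(res, nn) -nn / 2 * (log(2 * pi * sum(res^2) / nn) + 1)
  l0 <- ll(y - mean(y), n)
  r1 <- unlist(lapply(split(y, g), function(v) v - mean(v)))
  l1 <- ll(r1, n)
  (l1 - l0) / log(10)
}

# BH step-up adjusted p-values by definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# toy read simulator-independent mismatch counter
count_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
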