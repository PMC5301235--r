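# Allele-specific rRNA expression from paired polymorphic k-mers: find
# k-mer pairs differing at one base that discriminate the parental
# alleles, then quantify their balance in RNA-seq count tables.

# all canonical single-substitution neighbours of a k-mer
.hamming1_neighbours <- function(kmer) {
  k <- nchar(kmer)
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in seq_len(k)) {
    cur <- substring(kmer, i, i)
    for (b in setdiff(bases, cur)) {
      out <- c(out, paste0(substring(kmer, 1, i - 1), b,
                           substring(kmer, i + 1, k)))
    }
  }
  unique(canonical_kmer(out))
}

#' Find polymorphic k-mer pairs tagging a SNV between genotypes
#'
#' Searches the two genotypes' count tables for pairs of k-mers whose
#' (strand-aware) aligned forms differ at exactly one base, where one
#' member is genotype-discriminating — abundant (>= `min_high`) in one
#' genotype but near-absent (<= `max_other`) in the other — and its
#' partner is abundant in the genotype the first member misses. Such
#' pairs tag a single-nucleotide variant segregating between the two
#' repeat (e.g. rDNA) pools and let RNA-seq counts be assigned to
#' alleles. Greedy by abundance; each k-mer joins at most one pair.
#'
#' @param tableA,tableB `kmer_count_table` objects with equal `k`.
#' @param min_high minimum count for "abundant".
#' @param max_other maximum count for "near-absent".
#' @return data.frame `allele_A_kmer, allele_B_kmer, count_A_inA,
#'   count_A_inB, count_B_inA, count_B_inB` (member counts in each
#'   genotype's table), one row per pair.
#' @export
find_snv_pairs <- function(tableA, tableB, min_high = 100, max_other = 10) {
  if (tableA$k != tableB$k) stop("tables must share the same k")
  getc <- function(tab, km) {
    v <- tab$counts[match(km, names(tab$counts))]
    v[is.na(v)] <- 0
    v
  }
  all_kmers <- union(names(tableA$counts), names(tableB$counts))
  cA <- getc(tableA, all_kmers)
  cB <- getc(tableB, all_kmers)
  # discriminating member: abundant in exactly one genotype
  disc <- (cA >= min_high & cB <= max_other) |
          (cB >= min_high & cA <= max_other)
  cand <- all_kmers[disc]
  cand <- cand[order(pmax(cA[disc], cB[disc]), decreasing = TRUE)]
  used <- character(0)
  rows <- list()
  have <- sort(all_kmers)
  for (x in cand) {
    if (x %in% used) next
    nb <- .hamming1_neighbours(x)
    nb <- nb[!is.na(nb)]
    nb <- nb[nb %in% have & !(nb %in% used) & nb != x]
    if (!length(nb)) next
    xa <- getc(tableA, x); xb <- getc(tableB, x)
    # partner must be abundant in the genotype where x is absent
    need_tab <- if (xa >= min_high && xb <= max_other) "B" else "A"
    pc <- if (need_tab == "B") getc(tableB, nb) else getc(tableA, nb)
    ok <- pc >= min_high
    if (!any(ok)) next
    y <- nb[ok][which.max(pc[ok])]
    # orient: allele_A_kmer is the member abundant in genotype A
    if (xa >= xb) { a_k <- x; b_k <- y } else { a_k <- y; b_k <- x }
    rows[[length(rows) + 1L]] <- data.frame(
      allele_A_kmer = a_k, allele_B_kmer = b_k,
      count_A_inA = getc(tableA, a_k), count_A_inB = getc(tableB, a_k),
      count_B_inA = getc(tableA, b_k), count_B_inB = getc(tableB, b_k))
    used <- c(used, x, y)
  }
  if (!length(rows))
    return(data.frame(allele_A_kmer = character(0),
                      allele_B_kmer = character(0),
                      count_A_inA = numeric(0), count_A_inB = numeric(0),
                      count_B_inA = numeric(0), count_B_inB = numeric(0)))
  do.call(rbind, rows)
}

#' Log2 allelic ratio of a k-mer pair
#'
#' `log2((count_B + pseudocount) / (count_A + pseudocount))` per sample; a
#' pseudocount stabilises zeros. Samples where both members are zero are
#' returned as `NA` (no information).
#'
#' @param count_A,count_B per-sample counts of the two pair members.
#' @param pseudocount added to both counts.
#' @return numeric log2 ratios.
#' @export
log2_ratio <- function(count_A, count_B, pseudocount = 0.5) {
  out <- log2((count_B + pseudocount) / (count_A + pseudocount))
  out[count_A == 0 & count_B == 0] <- NA_real_
  out
}

#' Pooled maternal:paternal expression ratio over a time course
#'
#' For each developmental stage, pools counts over all pairs and reports
#' `sum(maternal) / sum(paternal)` — the variance-minimising estimator
#' for Poisson counts. Which allele is maternal follows the cross
#' direction of each sample; reciprocal crosses are reported separately.
#' A stage with zero paternal counts is flagged infinite (maternal-only
#' expression) rather than erroring.
#'
#' @param counts data.frame with columns `sample, stage, cross, count_A,
#'   count_B` (one row per pair per sample); `cross` is `"AxB"` (A is
#'   maternal) or `"BxA"`.
#' @return data.frame `cross, stage, maternal, paternal, ratio, infinite`.
#' @export
parental_ratio_timecourse <- function(counts) {
  stopifnot(all(c("stage", "cross", "count_A", "count_B") %in% names(counts)))
  mat <- ifelse(counts$cross == "AxB", counts$count_A, counts$count_B)
  pat <- ifelse(counts$cross == "AxB", counts$count_B, counts$count_A)
  agg <- aggregate(cbind(maternal = mat, paternal = pat),
                   by = list(cross = counts$cross, stage = counts$stage),
                   FUN = sum)
  agg$ratio <- ifelse(agg$paternal > 0, agg$maternal / agg$paternal, Inf)
  agg$infinite <- agg$paternal == 0
  agg
}
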