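# Highly abundant k-mers (HAKmers): extraction, chi-square differential
# abundance testing with BH-FDR, genotype-specific classification,
# repeat-library annotation, and exact mapping to a reference.

#' Extract highly abundant k-mers (HAKmers)
#'
#' A HAKmer is a k-mer whose combined count across the two genotypes
#' reaches `min_total` (absent in one table counts as 0). The headline
#' threshold of 20,000 corresponds to ~92x combined real coverage; for
#' desk-scale simulations pass `min_total` scaled by the configured depth
#' (see [scale_min_total()]).
#'
#' @param tableA,tableB `kmer_count_table` objects with equal `k`.
#' @param min_total inclusive threshold on `count_A + count_B`.
#' @return data.frame `kmer, count_A, count_B` for qualifying k-mers.
#' @export
extract_hakmers <- function(tableA, tableB, min_total = 20000) {
  if (tableA$k != tableB$k) stop("tables must share the same k")
  if (min_total <= 0) stop("min_total must be > 0")
  keys <- union(names(tableA$counts), names(tableB$counts))
  cA <- tableA$counts[match(keys, names(tableA$counts))]
  cB <- tableB$counts[match(keys, names(tableB$counts))]
  cA[is.na(cA)] <- 0; cB[is.na(cB)] <- 0
  keep <- (cA + cB) >= min_total
  out <- data.frame(kmer = keys[keep], count_A = as.numeric(cA[keep]),
                    count_B = as.numeric(cB[keep]))
  out[order(out$kmer), , drop = FALSE]
}

#' Depth-scaled HAKmer threshold
#'
#' Transfers the abundance criterion defined at ~92x combined coverage to
#' another simulated combined depth, preserving the implied per-copy
#' abundance cutoff.
#'
#' @param combined_depth total fold-coverage of the two libraries.
#' @param reference_min_total threshold at the reference depth.
#' @param reference_depth combined depth at which `reference_min_total`
#'   was defined.
#' @return scaled threshold (numeric).
#' @export
scale_min_total <- function(combined_depth, reference_min_total = 20000,
                            reference_depth = 92) {
  reference_min_total * combined_depth / reference_depth
}

#' Chi-square test of differential k-mer abundance
#'
#' One-degree-of-freedom goodness-of-fit of the observed counts
#' `(count_A, count_B)` against the split expected from the library sizes:
#' `e_A = T L_A / (L_A + L_B)`, `e_B = T L_B / (L_A + L_B)` with
#' `T = count_A + count_B`; `chi2 = sum (obs - exp)^2 / exp`, no
#' continuity correction, p from the 1-df chi-square upper tail. Tests the
#' null hypothesis of no relationship between k-mer counts and genotype,
#' correcting for depth imbalance. Vectorised over k-mers.
#'
#' @param count_A,count_B observed counts (>= 0, not both 0).
#' @param libsize_A,libsize_B library sizes (> 0), e.g. total k-mer
#'   instances or sequenced bases per genotype.
#' @return data.frame `chi2, p`.
#' @export
chisq_differential <- function(count_A, count_B, libsize_A, libsize_B) {
  if (libsize_A <= 0 || libsize_B <= 0) stop("library sizes must be > 0")
  total <- count_A + count_B
  if (any(total <= 0)) stop("counts must not both be zero")
  pA <- libsize_A / (libsize_A + libsize_B)
  eA <- total * pA
  eB <- total * (1 - pA)
  chi2 <- (count_A - eA)^2 / eA + (count_B - eB)^2 / eB
  data.frame(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Call differentially abundant HAKmers
#'
#' Applies Benjamini-Hochberg adjustment over all tested HAKmers and calls
#' `A-gain` / `B-gain` when the adjusted p-value is below `fdr` and the
#' library-size-normalised fold change is at least `min_fold`; direction
#' is by the larger normalised count. Fold change uses counts normalised
#' to the mean library size, with the denominator floored at one raw
#' count.
#'
#' @param records data.frame from [extract_hakmers()].
#' @param libsize_A,libsize_B library sizes.
#' @param fdr FDR threshold on adjusted p-values.
#' @param min_fold minimum normalised fold change.
#' @return `records` with `chi2, p, p_adj, fold, call` columns; `call` is
#'   one of `A-gain`, `B-gain`, `nonsignificant`.
#' @export
call_differential <- function(records, libsize_A, libsize_B,
                              fdr = 0.05, min_fold = 2) {
  if (!nrow(records)) {
    records$chi2 <- records$p <- records$p_adj <- records$fold <- numeric(0)
    records$call <- character(0)
    return(records)
  }
  ts <- chisq_differential(records$count_A, records$count_B,
                           libsize_A, libsize_B)
  records$chi2 <- ts$chi2
  records$p <- ts$p
  records$p_adj <- p.adjust(ts$p, method = "BH")
  mL <- mean(c(libsize_A, libsize_B))
  nA <- records$count_A * mL / libsize_A
  nB <- records$count_B * mL / libsize_B
  lo_floor <- pmax(pmin(nA, nB), ifelse(nA <= nB, mL / libsize_A, mL / libsize_B))
  records$fold <- pmax(nA, nB) / lo_floor
  sig <- records$p_adj < fdr & records$fold >= min_fold
  records$call <- ifelse(!sig, "nonsignificant",
                         ifelse(nA > nB, "A-gain", "B-gain"))
  records
}

#' Flag genotype-specific HAKmers
#'
#' A HAKmer with extremely low abundance (<= `max_low`) in one genotype is
#' specific to the other; with the extraction threshold at 20,000 and
#' `max_low = 10` this forces a count above 19,990 in the retained
#' genotype.
#'
#' @param records data.frame with `count_A`, `count_B` (HAKmers).
#' @param max_low inclusive ceiling on the low genotype's count.
#' @return `records` with a `specific` column: `A-specific`, `B-specific`
#'   or `none`.
#' @export
classify_genotype_specific <- function(records, max_low = 10) {
  records$specific <- ifelse(
    records$count_B <= max_low, "A-specific",
    ifelse(records$count_A <= max_low, "B-specific", "none"))
  records
}

#' Build a repeat library
#'
#' @param sequences named character vector of repeat reference sequences.
#' @param classes repeat class per entry (recycled names of `sequences`
#'   when missing).
#' @return a `repeat_library` data.frame with `name, class, seq`.
#' @export
repeat_library <- function(sequences, classes = names(sequences)) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("library entries must have unique names")
  structure(data.frame(name = names(sequences), class = classes,
                       seq = toupper(unname(sequences))),
            class = c("repeat_library", "data.frame"))
}

#' Annotate k-mers against a repeat library
#'
#' Seed-and-extend matching operator standing in for a BLASTN search with
#' word size 12: a k-mer hits a library entry if (either strand) it shares
#' an exact substring of at least `min_seed` bases with the entry and
#' aligns end-to-end at the seed-anchored offset with at most
#' `max_mismatch` substitutions. The best hit has the fewest mismatches,
#' ties broken by longest seed then library order; a k-mer with no hit is
#' `"unannotated"`.
#'
#' @param kmers character vector of k-mers.
#' @param library a [repeat_library()].
#' @param min_seed minimum exact seed length.
#' @param max_mismatch maximum substitutions over the full k-mer.
#' @return data.frame `kmer, annotation, mismatches`.
#' @export
annotate_kmers <- function(kmers, library, min_seed = 12L, max_mismatch = 2L) {
  if (!nrow(library)) stop("repeat library is empty")
  subjects <- Biostrings::DNAStringSet(library$seq)
  ann <- rep("unannotated", length(kmers))
  mm_out <- rep(NA_integer_, length(kmers))
  for (i in seq_along(kmers)) {
    best_mm <- max_mismatch + 1L
    best_seed <- -1L
    best_entry <- NA_integer_
    for (orient in 1:2) {
      q <- if (orient == 1) kmers[i] else as.character(revcomp(kmers[i]))
      qd <- Biostrings::DNAString(q)
      for (j in seq_len(nrow(library))) {
        hits <- Biostrings::matchPattern(qd, subjects[[j]],
                                         max.mismatch = max_mismatch)
        if (!length(hits)) next
        for (h in seq_along(hits)) {
          # end-to-end alignment only: drop hits hanging off the entry
          if (IRanges::start(hits)[h] < 1L ||
              IRanges::end(hits)[h] > length(subjects[[j]])) next
          ref <- as.character(hits[[h]])
          eq <- strsplit(q, "")[[1]] == strsplit(ref, "")[[1]]
          mm <- sum(!eq)
          runs <- rle(eq)
          seed <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
          if (seed < min_seed) next
          if (mm < best_mm || (mm == best_mm && seed > best_seed)) {
            best_mm <- mm; best_seed <- seed; best_entry <- j
          }
        }
      }
    }
    if (!is.na(best_entry)) {
      ann[i] <- library$class[best_entry]
      mm_out[i] <- best_mm
    }
  }
  data.frame(kmer = kmers, annotation = ann, mismatches = mm_out)
}

#' Map k-mers to a reference by exact matching
#'
#' Reports every exact full-length occurrence of each k-mer on either
#' strand of the reference (1-based start coordinates), deduplicating
#' identical coordinates arising from palindromic k-mers, and aggregates
#' hits into fixed-width bins.
#'
#' @param kmers character vector of k-mers (equal length).
#' @param reference named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param bin_size bin width in bp for per-bin hit counts.
#' @param min_bin_hits bins with fewer hits are dropped from the bin
#'   table (reporting filter; 0 keeps all).
#' @return list with `hits` (data.frame `kmer, chrom, start, strand`) and
#'   `bins` (data.frame `chrom, bin_start, hits`; `bin_start` 0-based,
#'   half-open bins).
#' @export
map_kmers_to_reference <- function(kmers, reference, bin_size = 100000L,
                                   min_bin_hits = 0L) {
  if (!length(reference)) stop("reference is empty")
  ref <- if (inherits(reference, "DNAStringSet")) reference
         else Biostrings::DNAStringSet(reference)
  if (is.null(names(ref))) names(ref) <- paste0("chr", seq_along(ref))
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers must all have the same length")
  pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  pd_rev <- Biostrings::PDict(Biostrings::DNAStringSet(revcomp(kmers)))
  hits <- list()
  for (ch in seq_along(ref)) {
    mf <- Biostrings::matchPDict(pd_fwd, ref[[ch]])
    mr <- Biostrings::matchPDict(pd_rev, ref[[ch]])
    for (i in seq_along(kmers)) {
      sf <- IRanges::start(mf[[i]])
      sr <- IRanges::start(mr[[i]])
      if (length(sf))
        hits[[length(hits) + 1L]] <- data.frame(
          kmer = kmers[i], chrom = names(ref)[ch], start = sf, strand = "+")
      if (length(sr)) {
        sr <- setdiff(sr, sf)  # palindromes: one hit per coordinate
        if (length(sr))
          hits[[length(hits) + 1L]] <- data.frame(
            kmer = kmers[i], chrom = names(ref)[ch], start = sr, strand = "-")
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(kmer = character(0), chrom = character(0),
                          start = integer(0), strand = character(0))
  if (nrow(hits)) {
    hits$bin_start <- (hits$start - 1L) %/% bin_size * bin_size
    agg <- aggregate(list(hits = hits$start),
                     by = list(chrom = hits$chrom, bin_start = hits$bin_start),
                     FUN = length)
    bins <- agg[agg$hits >= min_bin_hits, ]
    bins <- bins[order(bins$chrom, bins$bin_start), ]
    rownames(bins) <- NULL
  } else {
    bins <- data.frame(chrom = character(0), bin_start = integer(0),
                       hits = integer(0))
  }
  list(hits = hits[, c("kmer", "chrom", "start", "strand")], bins = bins)
}

#' Per-class abundance totals and genotype ratios
#'
#' Sums library-size-normalised counts over all annotated k-mers of each
#' repeat class per genotype and reports the B/A ratio per class. A class
#' with zero counts in A and nonzero in B gets `ratio = Inf` and
#' `infinite = TRUE` rather than a number.
#'
#' @param records annotated HAKmer data.frame with `count_A, count_B,
#'   annotation`.
#' @param libsize_A,libsize_B library sizes for normalisation.
#' @param classes class labels to tabulate (default: all present).
#' @return data.frame `class, total_A, total_B, ratio_BA, infinite`.
#' @export
class_abundance_summary <- function(records, libsize_A, libsize_B,
                                    classes = NULL) {
  classes <- classes %||% setdiff(unique(records$annotation), "unannotated")
  missing <- setdiff(classes, records$annotation)
  if (length(missing))
    stop("unknown class label(s): ", paste(missing, collapse = ", "))
  mL <- mean(c(libsize_A, libsize_B))
  out <- do.call(rbind, lapply(classes, function(cl) {
    r <- records[records$annotation == cl, ]
    tA <- sum(r$count_A) * mL / libsize_A
    tB <- sum(r$count_B) * mL / libsize_B
    data.frame(class = cl, total_A = tA, total_B = tB,
               ratio_BA = if (tA > 0) tB / tA else Inf,
               infinite = tA == 0 && tB > 0)
  }))
  rownames(out) <- NULL
  out
}
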