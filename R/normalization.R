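# Depth normalization across a multi-line panel using conserved
# single-copy k-mers, and repeat-family copy-number estimation from
# normalized k-mer depth.

#' Assemble a panel count matrix
#'
#' Restricts a list of per-line count tables to a query k-mer set, giving
#' a k-mers x lines matrix (absent = 0) plus per-line library sizes.
#'
#' @param tables named list of `kmer_count_table` objects (one per line).
#' @param kmers query k-mer set (rows of the matrix).
#' @param library_sizes optional per-line library sizes; defaults to each
#'   table's total counted k-mer instances.
#' @return a `panel_counts`: list with `counts` (matrix), `library_sizes`,
#'   `lines`.
#' @export
panel_counts <- function(tables, kmers, library_sizes = NULL) {
  ks <- vapply(tables, `[[`, 1L, "k")
  if (length(unique(ks)) != 1L) stop("all tables must share the same k")
  lines <- names(tables) %||% vapply(tables, `[[`, "", "sample_id")
  m <- matrix(0, length(kmers), length(tables),
              dimnames = list(kmers, lines))
  for (j in seq_along(tables)) {
    v <- tables[[j]]$counts[match(kmers, names(tables[[j]]$counts))]
    v[is.na(v)] <- 0
    m[, j] <- v
  }
  libs <- library_sizes %||% vapply(tables, function(t)
    t$total_instances %||% sum(t$counts), 1)
  if (any(libs <= 0)) stop("library sizes must be > 0")
  structure(list(counts = m, library_sizes = stats::setNames(libs, lines),
                 lines = lines),
            class = "panel_counts")
}

#' Select conserved single-copy k-mers
#'
#' From candidate k-mers that are single-copy in the reference genotypes,
#' ranks each by the Pearson correlation of its per-line counts with the
#' per-line library sizes and returns the top fraction. A k-mer whose
#' counts track library size across every line behaves as single-copy and
#' conserved in all lines, making it a faithful yardstick for sequencing
#' depth.
#'
#' @param panel a `panel_counts` over the candidate k-mers.
#' @param top_frac fraction of candidates to keep (default 0.05).
#' @return character vector of selected k-mers.
#' @export
select_conserved_single_copy <- function(panel, top_frac = 0.05) {
  if (length(panel$lines) < 3) stop("need at least 3 lines for correlation")
  v <- apply(panel$counts, 1, sd)
  usable <- v > 0
  if (!any(usable)) stop("all candidate k-mers have zero variance")
  r <- cor(t(panel$counts[usable, , drop = FALSE]), panel$library_sizes)[, 1]
  n_keep <- ceiling(top_frac * nrow(panel$counts))
  names(sort(r, decreasing = TRUE))[seq_len(min(n_keep, length(r)))]
}

#' Per-line normalization factors from conserved single-copy totals
#'
#' Given the total count `C_i` of conserved single-copy k-mers in line i,
#' the factor is `f_i = mean(C) / C_i`, the multiplicative correction that
#' equalises every line's conserved single-copy total to the panel mean.
#'
#' @param totals named numeric vector of per-line totals `C_i` (> 0).
#' @return a `normalization_factors`: list with `factor` (named per-line),
#'   `totals`, `reference_total` (mean of C).
#' @export
normalization_factors <- function(totals) {
  bad <- names(totals)[totals <= 0]
  if (length(bad))
    stop("zero conserved single-copy total in line(s): ",
         paste(bad, collapse = ", "))
  ref <- mean(totals)
  structure(list(factor = ref / totals, totals = totals,
                 reference_total = ref),
            class = "normalization_factors")
}

#' Apply normalization factors to a panel
#'
#' @param panel a `panel_counts`.
#' @param factors a `normalization_factors` covering every line.
#' @return matrix of normalized (non-integral) counts, k-mers x lines.
#' @export
normalize_panel <- function(panel, factors) {
  f <- factors$factor[panel$lines]
  if (anyNA(f))
    stop("missing normalization factor for line(s): ",
         paste(panel$lines[is.na(f)], collapse = ", "))
  sweep(panel$counts, 2, f, `*`)
}

#' Estimate repeat-family copy number from k-mer depth
#'
#' Per family k-mer, copies = count / single-copy depth; the family
#' estimate is the median over its k-mers. The family k-mer set should be
#' pre-filtered to k-mers conserved across copies and free of matches to
#' other repeat classes or organelle sequence.
#'
#' @param family_kmers character vector of family k-mers.
#' @param table a `kmer_count_table` (absent k-mers count 0).
#' @param single_copy_depth the line's single-copy k-mer depth, e.g. the
#'   spectrum peak from [find_peak_and_trough()].
#' @return list with `copies` (median estimate) and `per_kmer` vector.
#' @export
estimate_copy_number <- function(family_kmers, table, single_copy_depth) {
  if (!length(family_kmers)) stop("family k-mer set is empty")
  cnt <- table$counts[match(family_kmers, names(table$counts))]
  cnt[is.na(cnt)] <- 0
  per <- cnt / single_copy_depth
  list(copies = median(per), per_kmer = stats::setNames(per, family_kmers))
}

#' Per-line relative copy levels of two repeat families
#'
#' For each line, the median normalized abundance over each family's
#' k-mers; with >= 3 lines the squared Pearson correlation between the
#' two families' per-line medians is also reported.
#'
#' @param panel a `panel_counts` whose rows include both families' k-mers.
#' @param family_a_kmers,family_b_kmers the two k-mer sets.
#' @param factors a `normalization_factors`.
#' @return list with `medians` (data.frame line, family_a, family_b) and
#'   `r_squared` (NULL with < 3 lines).
#' @export
relative_copy_levels <- function(panel, family_a_kmers, family_b_kmers,
                                 factors) {
  if (!length(family_a_kmers) || !length(family_b_kmers))
    stop("both family k-mer sets must be non-empty")
  norm <- normalize_panel(panel, factors)
  ma <- apply(norm[rownames(norm) %in% family_a_kmers, , drop = FALSE], 2, median)
  mb <- apply(norm[rownames(norm) %in% family_b_kmers, , drop = FALSE], 2, median)
  out <- data.frame(line = panel$lines, family_a = ma, family_b = mb)
  rownames(out) <- NULL
  r2 <- if (length(panel$lines) >= 3) cor(ma, mb)^2 else NULL
  list(medians = out, r_squared = r2)
}
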