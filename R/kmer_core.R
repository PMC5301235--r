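# Canonical k-mer counting, abundance spectra, genome-size estimation,
# single-copy band selection and between-genotype sharing summaries.

#' Count canonical k-mers in a read set
#'
#' Every window of length `k` containing only A/C/G/T contributes one count
#' to its canonical form (lexicographic minimum of the window and its
#' reverse complement); windows with other letters are skipped. Entries
#' with count below `min_count` are dropped, a minimum-count filter that
#' plays the role of upstream read error correction by removing
#' error-specific k-mers.
#'
#' @param reads a `read_set` (from [simulate_reads()]) or character vector
#'   of read/sequence strings.
#' @param k k-mer length, 2 to 31 (default 25; 25 is the working size
#'   throughout the package).
#' @param min_count drop k-mers with total count below this (default 1 =
#'   keep everything).
#' @param sample_id label stored in the table.
#' @return a `kmer_count_table`: list with `k`, `counts` (named numeric
#'   vector, canonical k-mers sorted lexicographically), `library_bases`
#'   (total sequenced bases), `total_instances` (k-mer windows counted
#'   before filtering) and `sample_id`.
#' @export
count_kmers <- function(reads, k = 25L, min_count = 1L, sample_id = NULL) {
  if (inherits(reads, "read_set")) {
    sample_id <- sample_id %||% reads$sample_id
    reads <- reads$reads
  }
  sample_id <- sample_id %||% "sample"
  if (!length(reads)) stop("reads must be non-empty")
  if (k < 2 || k > 31) stop("k must be between 2 and 31")
  res <- .cpp_count_kmers(reads, as.integer(k))
  counts <- res$count
  names(counts) <- res$kmer
  if (!length(counts))
    warning("no read window of length k; empty count table")
  if (min_count > 1L) counts <- counts[counts >= min_count]
  structure(list(k = as.integer(k), counts = counts,
                 library_bases = sum(nchar(reads)),
                 total_instances = res$instances,
                 sample_id = sample_id),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table '%s': k=%d, %d distinct k-mers, %.0f instances, %.0f bases\n",
              x$sample_id, x$k, length(x$counts),
              sum(x$counts), x$library_bases))
  invisible(x)
}

#' Merge k-mer count tables
#'
#' Counts are summed per canonical k-mer over the union of keys, as when
#' pooling the read sets of two genotypes into one merged spectrum.
#'
#' @param tables list of `kmer_count_table` objects with equal `k`.
#' @return a merged `kmer_count_table`.
#' @export
merge_tables <- function(tables) {
  ks <- vapply(tables, `[[`, 1L, "k")
  if (length(unique(ks)) != 1L) stop("all tables must share the same k")
  keys <- sort(unique(unlist(lapply(tables, function(t) names(t$counts)))))
  total <- stats::setNames(numeric(length(keys)), keys)
  for (t in tables) {
    idx <- match(names(t$counts), keys)
    total[idx] <- total[idx] + t$counts
  }
  structure(list(k = ks[1], counts = total,
                 library_bases = sum(vapply(tables, `[[`, 1, "library_bases")),
                 total_instances = sum(vapply(tables, function(t)
                   t$total_instances %||% sum(t$counts), 1)),
                 sample_id = paste(vapply(tables, `[[`, "", "sample_id"),
                                   collapse = "+")),
            class = "kmer_count_table")
}

#' Abundance spectrum of a count table
#'
#' @param table a `kmer_count_table`.
#' @return a `kmer_spectrum`: data.frame with columns `abundance` and
#'   `n_kmers` (number of distinct k-mers at that abundance), with the
#'   table's `k` as an attribute.
#' @export
kmer_spectrum <- function(table) {
  if (!length(table$counts)) stop("empty count table")
  tab <- table(table$counts)
  out <- data.frame(abundance = as.integer(names(tab)),
                    n_kmers = as.numeric(tab))
  out <- out[order(out$abundance), ]
  rownames(out) <- NULL
  structure(out, k = table$k, class = c("kmer_spectrum", "data.frame"))
}

# dense histogram vector over abundances 1..max
.dense_hist <- function(spectrum) {
  h <- numeric(max(spectrum$abundance))
  h[spectrum$abundance] <- spectrum$n_kmers
  h
}

#' Locate the error trough and single-copy peak of a spectrum
#'
#' The histogram is smoothed by a 3-bin moving average; the first local
#' maximum at abundance above `search_min` defines the search bound, the
#' trough is the argmin of the smoothed histogram between abundance 1 and
#' that maximum, and the peak is the argmax above the trough. A monotone
#' histogram (no local maximum) is an error.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param search_min only local maxima above this abundance qualify as
#'   peaks (guards against the abundance-1 error spike).
#' @return list with `trough` and `peak` (abundance values).
#' @export
find_peak_and_trough <- function(spectrum, search_min = 2L) {
  h <- .dense_hist(spectrum)
  n <- length(h)
  if (n < 3) stop("no peak: spectrum support too narrow")
  s <- stats::filter(h, rep(1 / 3, 3), sides = 2)
  s[1] <- mean(h[1:2]); s[n] <- mean(h[(n - 1):n])
  s <- as.numeric(s)
  locmax <- which(vapply(seq(2, n - 1), function(i)
    s[i] > s[i - 1] && s[i] >= s[i + 1], logical(1))) + 1L
  locmax <- locmax[locmax > search_min]
  if (!length(locmax)) stop("no peak: histogram is monotone")
  first_max <- locmax[1]
  trough <- which.min(s[seq_len(first_max)])
  peak <- trough + which.max(s[seq(trough + 1L, n)])
  list(trough = trough, peak = peak)
}

#' Refined single-copy k-mer depth
#'
#' The integer spectrum mode is granular (one abundance unit is several
#' percent of the depth at desk-scale coverage); the refined depth is the
#' histogram-weighted mean abundance within +/- 30% of the integer peak,
#' which tracks the single-copy component's mean while excluding
#' multi-copy mass at >= 2x.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param peaks optional result of [find_peak_and_trough()].
#' @return single-copy depth (numeric, non-integer).
#' @export
single_copy_depth <- function(spectrum, peaks = NULL) {
  peaks <- peaks %||% find_peak_and_trough(spectrum)
  win <- spectrum$abundance >= ceiling(0.7 * peaks$peak) &
    spectrum$abundance <= floor(1.3 * peaks$peak)
  sum(spectrum$abundance[win] * spectrum$n_kmers[win]) /
    sum(spectrum$n_kmers[win])
}

#' Estimate genome size from a spectrum
#'
#' Total k-mer instances above the error trough divided by the
#' single-copy depth: `size = sum_(a >= trough) a * hist(a) / depth`,
#' with the depth refined by [single_copy_depth()]. The error tail below
#' the trough is excluded. This is a spectrum-based stand-in for
#' assembler-internal estimators; its output approximates the number of
#' distinct genomic k-mer positions (~genome length for k << genome).
#'
#' @param spectrum a `kmer_spectrum`.
#' @param peaks optional result of [find_peak_and_trough()]; computed if
#'   missing.
#' @return estimated genome size in bp.
#' @export
estimate_genome_size <- function(spectrum, peaks = NULL) {
  peaks <- peaks %||% find_peak_and_trough(spectrum)
  keep <- spectrum$abundance >= peaks$trough
  sum(spectrum$abundance[keep] * spectrum$n_kmers[keep]) /
    single_copy_depth(spectrum, peaks)
}

#' Single-copy abundance band
#'
#' By default the band is `[round(lo_frac * peak), round(hi_frac * peak)]`
#' around the spectrum's single-copy peak; pass `override` to reproduce a
#' fixed band such as `c(20, 50)`. Boundaries are inclusive.
#'
#' @param spectrum a `kmer_spectrum` (ignored when `override` is given).
#' @param lo_frac,hi_frac band limits as fractions of the peak depth.
#' @param override optional fixed `c(lo, hi)` band.
#' @return integer `c(lo, hi)`.
#' @export
single_copy_band <- function(spectrum = NULL, lo_frac = 0.55, hi_frac = 1.35,
                             override = NULL) {
  if (!is.null(override)) {
    band <- as.integer(override)
  } else {
    peak <- find_peak_and_trough(spectrum)$peak
    band <- c(round(lo_frac * peak), round(hi_frac * peak))
  }
  if (band[1] >= band[2]) stop("band lower bound must be below upper bound")
  band
}

#' Select single-copy k-mers from a table
#'
#' @param table a `kmer_count_table`.
#' @param band inclusive abundance interval `c(lo, hi)`.
#' @return character vector of k-mers with count in the band.
#' @export
select_single_copy <- function(table, band) {
  names(table$counts)[table$counts >= band[1] & table$counts <= band[2]]
}

#' Shared and genotype-specific single-copy k-mers
#'
#' A single-copy k-mer of one genotype is "shared" if it is present in the
#' other genotype's table at any count >= 1 (`mode = "presence"`, the
#' default) or if it is single-copy in both (`mode = "band"`). Percentages
#' are relative to each genotype's single-copy set.
#'
#' @param tableA,tableB `kmer_count_table` objects with equal `k`.
#' @param bandA,bandB single-copy bands for each table.
#' @param mode `"presence"` or `"band"`.
#' @return data.frame with one row per genotype: single-copy set size,
#'   shared and specific counts and percentages.
#' @export
sharing_summary <- function(tableA, tableB, bandA, bandB,
                            mode = c("presence", "band")) {
  mode <- match.arg(mode)
  if (tableA$k != tableB$k) stop("tables must share the same k")
  scA <- select_single_copy(tableA, bandA)
  scB <- select_single_copy(tableB, bandB)
  otherA <- if (mode == "presence") names(tableB$counts) else scB
  otherB <- if (mode == "presence") names(tableA$counts) else scA
  shA <- sum(scA %in% otherA)
  shB <- sum(scB %in% otherB)
  data.frame(
    genotype = c(tableA$sample_id, tableB$sample_id),
    n_single_copy = c(length(scA), length(scB)),
    n_shared = c(shA, shB),
    n_specific = c(length(scA) - shA, length(scB) - shB),
    pct_shared = 100 * c(shA / max(1, length(scA)), shB / max(1, length(scB))),
    pct_specific = 100 * c(1 - shA / max(1, length(scA)),
                           1 - shB / max(1, length(scB))))
}

#' Cumulative genome fraction by k-mer abundance
#'
#' For each abundance a, the fraction of all counted k-mer instances
#' contributed by k-mers with abundance <= a; monotone non-decreasing and
#' ending at 1.
#'
#' @param spectrum a `kmer_spectrum`.
#' @return data.frame with `abundance` and `cum_fraction`.
#' @export
cumulative_contribution <- function(spectrum) {
  mass <- spectrum$abundance * spectrum$n_kmers
  data.frame(abundance = spectrum$abundance,
             cum_fraction = cumsum(mass) / sum(mass))
}
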