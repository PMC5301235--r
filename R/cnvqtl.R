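# Genetic mapping of k-mer abundance (cnvQTL): normalized k-mer abundance
# per DH line is a quantitative trait; single-marker regression gives a
# LOD score per marker, permutation sets the genome-wide threshold, and
# greedy peak calling reports mapped loci.

#' Normalized k-mer abundance as a quantitative trait
#'
#' @param panel a `panel_counts` including the k-mer.
#' @param kmer the k-mer (a row of the panel).
#' @param factors a `normalization_factors`.
#' @return named numeric per-line trait vector, with attribute `constant`
#'   flagging an all-equal trait.
#' @export
kmer_trait <- function(panel, kmer, factors) {
  if (!kmer %in% rownames(panel$counts)) stop("k-mer not in panel")
  y <- panel$counts[kmer, ] * factors$factor[panel$lines]
  attr(y, "constant") <- stats::sd(y) == 0
  y
}

# LOD matrix for many traits at once: Y lines x traits, gbin lines x
# markers in {0,1}. Assumes no missing values and non-constant traits.
.lod_matrix <- function(Y, gbin, cap = 50) {
  n <- nrow(Y)
  nB <- colSums(gbin)
  ybar <- colMeans(Y)
  sst <- colSums(Y^2) - n * ybar^2
  s1 <- crossprod(gbin, Y)                       # markers x traits
  sumy <- matrix(colSums(Y), nrow(s1), ncol(s1), byrow = TRUE)
  nBm <- matrix(nB, nrow(s1), ncol(s1))
  meanB <- s1 / nBm
  meanA <- (sumy - s1) / (n - nBm)
  ssb <- nBm * (n - nBm) / n * (meanB - meanA)^2
  rss1 <- pmax(matrix(sst, nrow(s1), ncol(s1), byrow = TRUE) - ssb, 0)
  sstm <- matrix(sst, nrow(s1), ncol(s1), byrow = TRUE)
  lod <- n / 2 * log10(sstm / rss1)
  lod[!is.finite(lod) | lod > cap] <- cap
  lod[nB == 0 | nB == n, ] <- NA_real_           # monomorphic markers
  lod
}

#' Single-marker LOD scan
#'
#' For each marker, compares the two-genotype-mean model with the single
#' mean model: `LOD = (n/2) log10(RSS0 / RSS1)` where RSS0 is the total
#' sum of squares of the trait and RSS1 the within-genotype-class sum of
#' squares. Fully informative homozygous DH genotypes make this the exact
#' marker-regression form of standard QTL interval mapping at the marker
#' positions. Missing genotypes are dropped pairwise; monomorphic markers
#' report `NA`; perfect separation (RSS1 = 0) is capped at `cap`.
#'
#' @param trait numeric per-line trait vector.
#' @param genotypes lines x markers matrix of `"A"`/`"B"` (NA allowed).
#' @param cap LOD ceiling for degenerate fits.
#' @return numeric LOD per marker (named by marker when the matrix has
#'   column names).
#' @export
lod_scan <- function(trait, genotypes, cap = 50) {
  stopifnot(length(trait) == nrow(genotypes))
  if (stats::sd(trait, na.rm = TRUE) == 0) {
    warning("constant trait: all-zero LOD")
    return(stats::setNames(numeric(ncol(genotypes)), colnames(genotypes)))
  }
  gbin <- (genotypes == "B") * 1
  if (!anyNA(gbin) && !anyNA(trait)) {
    lod <- .lod_matrix(matrix(trait, ncol = 1), gbin, cap = cap)[, 1]
  } else {
    lod <- vapply(seq_len(ncol(genotypes)), function(j) {
      ok <- !is.na(gbin[, j]) & !is.na(trait)
      g <- gbin[ok, j]; y <- trait[ok]
      if (length(unique(g)) < 2 || min(table(g)) < 2) return(NA_real_)
      n <- length(y)
      rss0 <- sum((y - mean(y))^2)
      rss1 <- sum((y[g == 0] - mean(y[g == 0]))^2) +
              sum((y[g == 1] - mean(y[g == 1]))^2)
      if (rss1 <= 0 || rss0 <= 0) return(cap)
      min(n / 2 * log10(rss0 / rss1), cap)
    }, numeric(1))
  }
  stats::setNames(lod, colnames(genotypes))
}

#' Genome-wide permutation LOD threshold
#'
#' Shuffles the trait across lines `n_perm` times, recomputes the
#' genome-wide maximum LOD for each shuffle, and returns the empirical
#' `1 - alpha` quantile (type-7 interpolation).
#'
#' @param trait numeric per-line trait vector.
#' @param genotypes lines x markers matrix of `"A"`/`"B"`.
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide type-I error rate.
#' @param seed integer seed.
#' @param cap LOD ceiling.
#' @return list with `threshold` and `max_lods` (the permuted maxima).
#' @export
permutation_threshold <- function(trait, genotypes, n_perm = 1000,
                                  alpha = 0.05, seed = NULL, cap = 50) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 100) stop("n_perm must be >= 100")
  gbin <- (genotypes == "B") * 1
  Y <- vapply(seq_len(n_perm), function(i) sample(trait),
              numeric(length(trait)))
  lods <- .lod_matrix(Y, gbin, cap = cap)
  mx <- apply(lods, 2, max, na.rm = TRUE)
  list(threshold = unname(quantile(mx, 1 - alpha, type = 7)), max_lods = mx)
}

#' Call cnvQTL peaks from a LOD scan
#'
#' Greedy selection of markers with LOD at or above
#' `max(threshold, declare_min)`, from the highest down, suppressing
#' further peaks within `min_peak_gap` cM on the same chromosome, up to
#' `max_peaks` peaks. An empty result means the k-mer could not be
#' mapped.
#'
#' @param map `data.frame(chrom, cM, id)` aligned with `lod`.
#' @param lod numeric LOD per marker.
#' @param threshold permutation (or otherwise chosen) LOD cutoff.
#' @param declare_min hard minimum LOD to declare a peak.
#' @param min_peak_gap minimum cM between peaks on one chromosome.
#' @param max_peaks maximum number of reported peaks.
#' @return data.frame `chrom, cM, marker, lod` sorted by decreasing LOD.
#' @export
call_peaks <- function(map, lod, threshold = 0, declare_min = 4,
                       min_peak_gap = 30, max_peaks = 4) {
  cutoff <- max(threshold, declare_min)
  avail <- which(!is.na(lod) & lod >= cutoff)
  peaks <- data.frame(chrom = integer(0), cM = numeric(0),
                      marker = character(0), lod = numeric(0))
  while (length(avail) && nrow(peaks) < max_peaks) {
    top <- avail[which.max(lod[avail])]
    peaks <- rbind(peaks, data.frame(chrom = map$chrom[top], cM = map$cM[top],
                                     marker = map$id[top], lod = lod[top]))
    same <- map$chrom[avail] == map$chrom[top] &
      abs(map$cM[avail] - map$cM[top]) < min_peak_gap
    avail <- avail[!same]
  }
  rownames(peaks) <- NULL
  peaks
}

#' Map a set of HAKmers by cnvQTL
#'
#' Runs trait construction, LOD scan and peak calling for each record's
#' k-mer; constant-trait k-mers are skipped (and listed). When
#' `n_perm > 0` a per-k-mer permutation threshold is computed, otherwise
#' `threshold` is used for all.
#'
#' @param records data.frame with `kmer` (and optionally `annotation`).
#' @param panel a `panel_counts` over the panel lines.
#' @param genotypes lines x markers `"A"`/`"B"` matrix.
#' @param map genetic map aligned with `genotypes` columns.
#' @param factors a `normalization_factors`.
#' @param threshold fixed LOD cutoff used when `n_perm = 0`.
#' @param n_perm permutations per k-mer (0 = use `threshold`).
#' @param seed integer seed for permutations.
#' @param ... passed to [call_peaks()].
#' @return list with `peaks` (data.frame kmer, class, chrom, cM, marker,
#'   lod, rank), `skipped` (constant-trait k-mers) and `class_summary`
#'   (peak counts by annotation class and chromosome).
#' @export
map_hakmer_set <- function(records, panel, genotypes, map, factors,
                           threshold = 0, n_perm = 0, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- list(); skipped <- character(0)
  for (i in seq_len(nrow(records))) {
    km <- records$kmer[i]
    y <- kmer_trait(panel, km, factors)
    if (attr(y, "constant")) { skipped <- c(skipped, km); next }
    lod <- lod_scan(y, genotypes)
    thr <- if (n_perm > 0)
      permutation_threshold(y, genotypes, n_perm = n_perm)$threshold
    else threshold
    pk <- call_peaks(map, lod, threshold = thr, ...)
    if (nrow(pk)) {
      pk$kmer <- km
      pk$class <- if ("annotation" %in% names(records))
        records$annotation[i] else NA_character_
      pk$rank <- seq_len(nrow(pk))
      out[[length(out) + 1L]] <- pk
    }
  }
  peaks <- if (length(out)) do.call(rbind, out)
           else data.frame(chrom = integer(0), cM = numeric(0),
                           marker = character(0), lod = numeric(0),
                           kmer = character(0), class = character(0),
                           rank = integer(0))
  peaks <- peaks[, c("kmer", "class", "chrom", "cM", "marker", "lod", "rank")]
  cs <- if (nrow(peaks))
    aggregate(list(n_peaks = peaks$kmer),
              by = list(class = peaks$class, chrom = peaks$chrom),
              FUN = length)
  else data.frame(class = character(0), chrom = integer(0),
                  n_peaks = integer(0))
  list(peaks = peaks, skipped = skipped, class_summary = cs)
}
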