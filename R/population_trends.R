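# Multi-line panel analyses: highly variable k-mer filtering, one-way
# ANOVA across evolutionary groups with Bonferroni control, Gaussian
# mixture clustering of max-scaled abundance profiles, PCA of lines, and
# domestication-trend direction tables.

#' Filter highly variable k-mers
#'
#' Keeps a k-mer if its (normalized) count is strictly above `high` in at
#' least `n_high` lines and strictly below `low` in at least `n_low`
#' other lines — the hard filter for k-mers present at high copy number
#' in part of a panel and nearly absent elsewhere.
#'
#' @param counts k-mers x lines matrix of normalized counts.
#' @param high,n_high high-abundance threshold (strict >) and minimum
#'   number of lines reaching it.
#' @param low,n_low low-abundance threshold (strict <) and minimum number
#'   of lines below it.
#' @return character vector of retained k-mer names.
#' @export
highly_variable_filter <- function(counts, high = 1000, n_high = 5,
                                   low = 10, n_low = 5) {
  if (n_high + n_low > ncol(counts))
    stop("n_high + n_low exceeds the number of lines")
  hi <- rowSums(counts > high) >= n_high
  lo <- rowSums(counts < low) >= n_low
  rownames(counts)[hi & lo]
}

#' One-way ANOVA of k-mer abundance across groups
#'
#' Fixed-effects one-way ANOVA (between df = g - 1, within df = n - g) of
#' one k-mer's per-line values against the evolutionary-group factor,
#' via `lm`. With zero within-group variance and equal group means the F
#' statistic is undefined and p is reported as 1.
#'
#' @param values numeric per-line values for one k-mer.
#' @param groups factor of group labels (>= 2 groups, each >= 2 lines).
#' @return list with `F` and `p`.
#' @export
group_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 lines each")
  if (stats::var(values) == 0) return(list(F = NA_real_, p = 1))
  fit <- anova(lm(values ~ groups))
  Fv <- fit$`F value`[1]
  if (!is.finite(Fv)) return(list(F = NA_real_, p = 1))
  list(F = Fv, p = fit$`Pr(>F)`[1])
}

#' ANOVA over a panel with Bonferroni correction
#'
#' @param counts k-mers x lines matrix.
#' @param groups factor per line.
#' @param alpha family-wise error rate; a k-mer is significant iff
#'   `p < alpha / m` with m the number of tested k-mers.
#' @return data.frame `kmer, F, p, significant`.
#' @export
panel_anova <- function(counts, groups, alpha = 0.05) {
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    a <- group_anova(counts[i, ], groups)
    c(a$F %||% NA_real_, a$p)
  }, numeric(2)))
  m <- nrow(counts)
  data.frame(kmer = rownames(counts), F = res[, 1], p = res[, 2],
             significant = res[, 2] < alpha / m)
}

#' Scale abundance profiles to row maxima
#'
#' Each k-mer's counts are divided by that k-mer's maximum, mapping every
#' profile into \[0, 1\] with row max 1; idempotent.
#'
#' @param counts k-mers x lines matrix; all-zero rows are an error.
#' @return scaled matrix.
#' @export
scale_profiles <- function(counts) {
  mx <- apply(counts, 1, max)
  bad <- rownames(counts)[mx <= 0]
  if (length(bad))
    stop("all-zero profile for k-mer(s): ", paste(head(bad, 5), collapse = ", "))
  counts / mx
}

#' Cluster scaled abundance profiles with a shared-covariance GMM
#'
#' Fits Gaussian mixtures with a common full covariance across components
#' (mclust model "EEE") for each G in `G_range` and keeps the
#' best-BIC model, mirroring model-based clustering of max-scaled k-mer
#' abundance profiles across panel lines.
#'
#' @param scaled k-mers x lines matrix from [scale_profiles()].
#' @param G_range candidate numbers of components.
#' @param seed integer seed (mclust initialisation is deterministic given
#'   the data, but the seed also covers any subsampled initialisation).
#' @return list with `G`, `assignments` (named component per k-mer),
#'   `means` (components x lines), `bic` (per candidate G) and `model`
#'   (the mclust fit).
#' @export
gmm_cluster <- function(scaled, G_range = 1:12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G_range <- G_range[G_range <= floor(nrow(scaled) / 2)]
  if (!length(G_range)) stop("too few rows for the requested G range")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(scaled, G = G_range, modelNames = "EEE",
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture model failed to fit")
  list(G = fit$G,
       assignments = stats::setNames(fit$classification, rownames(scaled)),
       means = t(fit$parameters$mean),
       bic = fit$BIC,
       model = fit)
}

#' PCA of panel lines over a k-mer set
#'
#' Centered (not scaled) principal component analysis of the lines x
#' k-mers normalized abundance matrix, via `prcomp`.
#'
#' @param counts k-mers x lines matrix (transposed internally so lines
#'   are observations).
#' @return list with `coordinates` (lines x PCs) and `var_explained`
#'   (fractions summing to 1).
#' @export
pca_lines <- function(counts) {
  m <- t(counts)
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 lines and >= 2 k-mers")
  if (all(apply(m, 2, stats::var) == 0)) stop("constant matrix")
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  list(coordinates = p$x, var_explained = p$sdev^2 / sum(p$sdev^2))
}

#' Direction of each cluster's trend across ordered groups
#'
#' A cluster's mean scaled profile is averaged within each group (groups
#' ordered from ancestral to derived); the cluster is a `decrease` if the
#' first group's mean exceeds the last group's by more than
#' `min_change_frac` of the profile's range, an `increase` if the
#' reverse, else `flat`.
#'
#' @param cluster_means components x lines matrix of mean profiles.
#' @param groups ordered factor per line.
#' @param min_change_frac fraction of the profile range that the
#'   first-to-last group change must exceed.
#' @return character vector of directions per cluster.
#' @export
cluster_directions <- function(cluster_means, groups,
                               min_change_frac = 0.2) {
  groups <- as.factor(groups)
  first <- levels(groups)[1]
  last <- levels(groups)[nlevels(groups)]
  vapply(seq_len(nrow(cluster_means)), function(i) {
    prof <- cluster_means[i, ]
    gm <- tapply(prof, groups, mean)
    rng <- max(prof) - min(prof)
    if (rng <= 0) return("flat")
    delta <- gm[[first]] - gm[[last]]
    if (delta > min_change_frac * rng) "decrease"
    else if (-delta > min_change_frac * rng) "increase"
    else "flat"
  }, character(1))
}

#' Class-by-direction trend table
#'
#' Counts annotated k-mers per repeat class in the `decrease` and
#' `increase` cluster directions (flat clusters excluded), summarising
#' which repeat classes contracted or expanded across the group ordering.
#'
#' @param assignments named component per k-mer (from [gmm_cluster()]).
#' @param directions per-cluster directions (from [cluster_directions()]).
#' @param annotations data.frame `kmer, annotation`.
#' @return contingency data.frame `class, decrease, increase`.
#' @export
group_trend_table <- function(assignments, directions, annotations) {
  dir_per_kmer <- directions[assignments[annotations$kmer]]
  keep <- dir_per_kmer %in% c("decrease", "increase")
  tab <- table(class = annotations$annotation[keep],
               direction = factor(dir_per_kmer[keep],
                                  levels = c("decrease", "increase")))
  out <- as.data.frame.matrix(tab)
  data.frame(class = rownames(out), decrease = out$decrease,
             increase = out$increase, row.names = NULL)
}
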