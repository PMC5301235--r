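toy_genotypes <- function(codes, markers = 1) {
  matrix(rep(codes, markers), length(codes), markers,
         dimnames = list(paste0("L", seq_along(codes)),
                         paste0("m", seq_len(markers))))
}

test_that("LOD scan matches the hand-computed least-squares form", {
  y <- c(1.0, 1.1, 0.9, 1.0, 2.0, 2.1, 1.9, 2.0)
  g <- toy_genotypes(c("A", "A", "A", "A", "B", "B", "B", "B"))
  lod <- lod_scan(y, g)
  expect_equal(unname(lod), 4 * log10(2.04 / 0.04), tolerance = 1e-12)
  expect_equal(unname(lod), 6.830, tolerance = 1e-3)
  # agrees with the two-group normal likelihood-ratio oracle
  expect_equal(unname(lod), oracle_lod(y, g[, 1]), tolerance = 1e-9)
})

test_that("LOD scan equals the likelihood-ratio oracle on random instances", {
  set.seed(401)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    y <- rnorm(n)
    g <- toy_genotypes(sample(c(rep("A", 3), rep("B", 3),
                                sample(c("A", "B"), n - 6, TRUE))))
    expect_equal(unname(lod_scan(y, g)), oracle_lod(y, g[, 1]),
                 tolerance = 1e-9)
  }
})

test_that("LOD degenerate cases behave as documented", {
  # identical class means: LOD exactly 0
  y <- c(1, 2, 1, 2)
  g <- toy_genotypes(c("A", "A", "B", "B"))
  expect_equal(unname(lod_scan(y, g)), 0)
  # constant trait: warning + all-zero
  expect_warning(l0 <- lod_scan(rep(3, 4), g), "constant")
  expect_equal(unname(l0), 0)
  # perfect separation capped
  expect_equal(unname(lod_scan(c(1, 1, 2, 2), g)), 50)
  expect_equal(unname(lod_scan(c(1, 1, 2, 2), g, cap = 10)), 10)
  # monomorphic marker reported missing
  gm <- toy_genotypes(c("A", "A", "A", "A"))
  gm[1, 1] <- NA
  expect_true(is.na(lod_scan(c(1, 2, 3, 4), gm)))
})

test_that("kmer_trait multiplies counts by per-line factors", {
  counts <- matrix(c(10, 20, 30), 1, 3,
                   dimnames = list("AAA", c("l1", "l2", "l3")))
  pan <- structure(list(counts = counts,
                        library_sizes = c(l1 = 1, l2 = 1, l3 = 1),
                        lines = c("l1", "l2", "l3")), class = "panel_counts")
  fac <- normalization_factors(c(l1 = 100, l2 = 200, l3 = 100))
  y <- kmer_trait(pan, "AAA", fac)
  expect_equal(as.numeric(y), c(10 * 4 / 3, 20 * 2 / 3, 30 * 4 / 3))
  fac1 <- normalization_factors(c(l1 = 1, l2 = 1, l3 = 1))
  expect_equal(as.numeric(kmer_trait(pan, "AAA", fac1)), c(10, 20, 30))
  z <- structure(list(counts = counts * 0,
                      library_sizes = pan$library_sizes,
                      lines = pan$lines), class = "panel_counts")
  expect_true(attr(kmer_trait(z, "AAA", fac1), "constant"))
})

test_that("permutation threshold is deterministic and respects alpha", {
  set.seed(411)
  map <- genetic_map(n_chrom = 2, length_cM = 50, spacing_cM = 5)
  gA <- list(genotype = "A", sequences = c(chr1 = "ACGT"))
  gB <- list(genotype = "B", sequences = c(chr1 = "ACGT"))
  dh <- simulate_dh_panel(gA, gB, map, n_lines = 100, seed = 412)
  y <- rnorm(100)
  t1 <- permutation_threshold(y, dh$genotypes, n_perm = 200, seed = 7)
  t2 <- permutation_threshold(y, dh$genotypes, n_perm = 200, seed = 7)
  expect_identical(t1$threshold, t2$threshold)
  # alpha = 1 gives the minimum permuted maximum
  t3 <- permutation_threshold(y, dh$genotypes, n_perm = 200, alpha = 1,
                              seed = 7)
  expect_equal(t3$threshold, min(t1$max_lods))
  expect_error(permutation_threshold(y, dh$genotypes, n_perm = 50), "100")
})

test_that("type-I error of the permutation cutoff is controlled", {
  set.seed(421)
  map <- genetic_map(n_chrom = 3, length_cM = 60, spacing_cM = 4)
  gA <- list(genotype = "A", sequences = c(chr1 = "ACGT"))
  gB <- list(genotype = "B", sequences = c(chr1 = "ACGT"))
  dh <- simulate_dh_panel(gA, gB, map, n_lines = 120, seed = 422)
  gbin <- (dh$genotypes == "B") * 1
  # one permutation null distribution is valid for any null trait on this
  # genotype matrix; compare fresh null traits against it
  thr <- permutation_threshold(rnorm(120), dh$genotypes, n_perm = 500,
                               seed = 423)$threshold
  n_rep <- 200
  Y <- matrix(rnorm(120 * n_rep), 120, n_rep)
  mx <- apply(kmercnv:::.lod_matrix(Y, gbin), 2, max)
  rate <- mean(mx >= thr)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("peak calling is greedy with gap suppression and peak cap", {
  map <- genetic_map(n_chrom = 2, length_cM = 100, spacing_cM = 10)
  lod <- rep(0, nrow(map))
  # chrom 1: peaks at 20 and 80 cM; chrom 2: one peak at 50 cM
  lod[map$chrom == 1 & map$cM == 20] <- 8
  lod[map$chrom == 1 & map$cM == 30] <- 6    # within 30 cM of the 20 peak
  lod[map$chrom == 1 & map$cM == 80] <- 5
  lod[map$chrom == 2 & map$cM == 50] <- 12
  pk <- call_peaks(map, lod, threshold = 3.5)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$lod, c(12, 8, 5))
  expect_setequal(pk$cM[pk$chrom == 1], c(20, 80))
  # declare_min dominates a lower permutation threshold
  pk2 <- call_peaks(map, lod, threshold = 3.5, declare_min = 9)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$chrom, 2)
  # nothing above 4: unmapped
  expect_equal(nrow(call_peaks(map, rep(3.9, nrow(map)))), 0)
  # max_peaks truncates
  expect_equal(nrow(call_peaks(map, lod, threshold = 3.5, max_peaks = 2)), 2)
})

test_that("a planted cluster maps to its locus; shared repeats map to both", {
  set.seed(431)
  fam <- repeat_family("f", random_dna(120), c(A = 60, B = 120), offset = 100)
  gA <- list(genotype = "A", sequences = c(chr1 = "ACGT"),
             family_copy_number = c(f = 60))
  gB <- list(genotype = "B", sequences = c(chr1 = "ACGT"),
             family_copy_number = c(f = 120))
  map <- genetic_map(n_chrom = 3, length_cM = 100, spacing_cM = 1)
  clus <- data.frame(family = "f", chrom = 2, cM = 50)
  dh <- simulate_dh_panel(gA, gB, map, n_lines = 280,
                          cluster_positions = clus, seed = 432)
  # Poisson counts at ~0.2 per copy around the per-line truth
  hits <- 0
  for (r in 1:50) {
    y <- rpois(280, dh$line_truth[, "f"] * 0.2)
    lod <- lod_scan(y, dh$genotypes)
    pk <- call_peaks(map, lod, threshold = 4)
    if (nrow(pk) >= 1 && pk$chrom[1] == 2 && abs(pk$cM[1] - 50) <= 10)
      hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
  # the same trait driven by clusters on two chromosomes maps to both
  clus2 <- data.frame(family = c("f", "f2"), chrom = c(2, 3), cM = c(50, 20))
  gA$family_copy_number <- c(f = 60, f2 = 60)
  gB$family_copy_number <- c(f = 120, f2 = 120)
  dh2 <- simulate_dh_panel(gA, gB, map, n_lines = 280,
                           cluster_positions = clus2, seed = 433)
  y2 <- rpois(280, (dh2$line_truth[, "f"] + dh2$line_truth[, "f2"]) * 0.2)
  pk2 <- call_peaks(map, lod_scan(y2, dh2$genotypes), threshold = 4)
  expect_setequal(unique(pk2$chrom), c(2, 3))
})

test_that("LOD grows monotonically with the planted copy-number gap", {
  set.seed(441)
  map <- genetic_map(n_chrom = 1, length_cM = 80, spacing_cM = 2)
  gA <- list(genotype = "A", sequences = c(chr1 = "ACGT"))
  gB <- list(genotype = "B", sequences = c(chr1 = "ACGT"))
  dh <- simulate_dh_panel(gA, gB, map, n_lines = 200, seed = 442)
  near <- which.min(abs(map$cM - 40))
  gvec <- dh$genotypes[, near]
  med_lod <- vapply(c(1.2, 1.5, 2), function(gap) {
    lods <- vapply(1:40, function(r) {
      y <- rpois(200, ifelse(gvec == "A", 100, 100 * gap) * 0.3)
      max(lod_scan(y, dh$genotypes), na.rm = TRUE)
    }, numeric(1))
    median(lods)
  }, numeric(1))
  expect_true(all(diff(med_lod) > 0))
})

test_that("map_hakmer_set maps family k-mers to co-located loci", {
  set.seed(451)
  fam <- repeat_family("f", random_dna(120), c(A = 50, B = 100), offset = 100)
  gA <- list(genotype = "A", sequences = c(chr1 = "ACGT"),
             family_copy_number = c(f = 50))
  gB <- list(genotype = "B", sequences = c(chr1 = "ACGT"),
             family_copy_number = c(f = 100))
  map <- genetic_map(n_chrom = 2, length_cM = 80, spacing_cM = 2)
  clus <- data.frame(family = "f", chrom = 1, cM = 40)
  dh <- simulate_dh_panel(gA, gB, map, n_lines = 200,
                          cluster_positions = clus, seed = 452)
  kms <- replicate(8, random_dna(25))
  counts <- t(vapply(kms, function(k)
    rpois(200, dh$line_truth[, "f"] * 0.5), numeric(200)))
  rownames(counts) <- kms
  colnames(counts) <- rownames(dh$genotypes)
  pan <- structure(list(counts = counts,
                        library_sizes = stats::setNames(rep(1e5, 200),
                                                        colnames(counts)),
                        lines = colnames(counts)), class = "panel_counts")
  fac <- normalization_factors(pan$library_sizes)
  res <- map_hakmer_set(data.frame(kmer = kms, annotation = "f"),
                        pan, dh$genotypes, map, fac, threshold = 4)
  expect_setequal(unique(res$peaks$kmer), kms)
  top <- res$peaks[res$peaks$rank == 1, ]
  expect_true(all(top$chrom == 1 & abs(top$cM - 40) <= 10))
  # empty record set gives an empty table
  empty <- map_hakmer_set(data.frame(kmer = character(0)), pan,
                          dh$genotypes, map, fac)
  expect_equal(nrow(empty$peaks), 0)
})
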