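mk_table <- function(counts, id = "t", bases = 1e6, k = 25L) {
  structure(list(k = k, counts = counts, library_bases = bases,
                 total_instances = sum(counts), sample_id = id),
            class = "kmer_count_table")
}

test_that("HAKmer extraction applies the combined-count threshold", {
  tA <- mk_table(c(a = 19999, b = 10000, c = 5))
  tB <- mk_table(c(b = 10000, c = 19996))
  recs <- extract_hakmers(tA, tB, min_total = 20000)
  expect_setequal(recs$kmer, c("b", "c"))  # a: 19999+0 excluded; c: 20001
  expect_equal(recs$count_A[recs$kmer == "b"], 10000)
  # brute-force filter over the key union agrees on random tables
  set.seed(201)
  kms <- sort(vapply(1:60, function(i) random_dna(25), ""))
  cA <- stats::setNames(rpois(40, 150), sample(kms, 40))
  cB <- stats::setNames(rpois(45, 150), sample(kms, 45))
  recs2 <- extract_hakmers(mk_table(cA), mk_table(cB), min_total = 300)
  keys <- union(names(cA), names(cB))
  gA <- ifelse(is.na(cA[keys]), 0, cA[keys])
  gB <- ifelse(is.na(cB[keys]), 0, cB[keys])
  expect_setequal(recs2$kmer, keys[gA + gB >= 300])
})

test_that("chi-square statistic matches the hand-computed 1-df form", {
  r <- chisq_differential(100, 50, 1e6, 1e6)
  expect_equal(r$chi2, 2 * 25^2 / 75, tolerance = 1e-12)  # 16.667
  expect_equal(r$p, pchisq(50 / 3, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p, 4.45e-5, tolerance = 5e-3)
  # null case: equal counts, equal libraries
  expect_equal(chisq_differential(70, 70, 1e6, 1e6)$chi2, 0)
  expect_equal(chisq_differential(70, 70, 1e6, 1e6)$p, 1)
  # counts proportional to library sizes are not differential
  expect_equal(chisq_differential(150, 50, 3e6, 1e6)$chi2, 0, tolerance = 1e-12)
})

test_that("differential calls require both FDR and fold criteria", {
  # BH adjustment matches the step-up oracle
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  expect_equal(oracle_bh(p), c(0.03, 0.03, 0.04))
  recs <- data.frame(kmer = c("k1", "k2", "k3"),
                     count_A = c(4000, 1800, 120),
                     count_B = c(1000, 1000, 100))
  out <- call_differential(recs, 1e6, 1e6)
  expect_equal(out$p_adj, oracle_bh(out$p))
  expect_equal(out$call[1], "A-gain")       # 4x fold, tiny p
  expect_equal(out$call[2], "nonsignificant")  # significant p but fold 1.8
  expect_lt(out$p_adj[2], 0.05)
  expect_equal(out$call[3], "nonsignificant")
  # single record: BH with m = 1 leaves p unchanged
  one <- call_differential(data.frame(kmer = "k", count_A = 130, count_B = 70),
                           1e6, 1e6)
  expect_equal(one$p_adj, one$p)
  # label swap symmetry
  swapped <- call_differential(
    data.frame(kmer = recs$kmer, count_A = recs$count_B,
               count_B = recs$count_A), 1e6, 1e6)
  expect_equal(swapped$call,
               c("A-gain" = "B-gain", "B-gain" = "A-gain",
                 nonsignificant = "nonsignificant")[out$call],
               ignore_attr = TRUE)
  # empty input passes through
  expect_equal(nrow(call_differential(recs[0, ], 1e6, 1e6)), 0)
})

test_that("genotype-specific classification uses the low-count ceiling", {
  recs <- data.frame(kmer = c("a", "b", "c"),
                     count_A = c(19991, 10000, 10),
                     count_B = c(9, 10000, 19990))
  out <- classify_genotype_specific(recs, max_low = 10)
  expect_equal(out$specific, c("A-specific", "none", "B-specific"))
  # with min_total 20000 the retained genotype must exceed 19990
  expect_gt(out$count_A[1] + out$count_B[1], 19999)
  expect_gte(out$count_A[1], 19991)
})

test_that("null chi-square calibration holds for independent repeat k-mers", {
  # Poisson-count null: many independent high-abundance k-mers from the
  # same underlying genome, unequal library sizes
  set.seed(211)
  m <- 2000
  lam <- runif(m, 250, 2500)
  LA <- 2e6; LB <- 3e6
  cA <- rpois(m, lam)
  cB <- rpois(m, lam * LB / LA)
  ts <- chisq_differential(cA, cB, LA, LB)
  fp <- mean(ts$p < 0.05)
  se <- sqrt(0.05 * 0.95 / m)
  expect_lt(abs(fp - 0.05), 3 * se)
  # BH at 5% on a pure null yields (almost) no discoveries
  expect_lte(mean(p.adjust(ts$p, "BH") < 0.05), 0.05)
})

test_that("same-genome resequencing yields no spurious calls", {
  # read-level null on a genome whose repeat is a modest fraction: finite
  # genomes give (if anything) conservative chi-square behaviour
  set.seed(212)
  unit <- random_dna(300)
  fam <- repeat_family("fam", unit, c(A = 80, B = 80), offset = 5000,
                       divergence = 0)
  g <- simulate_repeat_genome(2e5, list(fam), seed = 213)
  t1 <- count_kmers(simulate_reads(g$A, 25, 100, seed = 214), k = 25)
  t2 <- count_kmers(simulate_reads(g$A, 25, 100, seed = 215), k = 25)
  recs <- extract_hakmers(t1, t2, min_total = 500)
  expect_gte(nrow(recs), 200)
  recs <- call_differential(recs, t1$total_instances, t2$total_instances)
  # family k-mers share reads, so the raw rejection rate has few effective
  # independent draws; the decision-level property is what must hold
  expect_equal(mean(recs$p_adj < 0.05), 0)
  expect_equal(unique(recs$call), "nonsignificant")
})

test_that("planted copy-number gains are called in the right direction", {
  set.seed(221)
  unit <- random_dna(180)
  # 2x gap: direction and significance; repeat kept a small genome fraction
  fam <- repeat_family("fam", unit, c(A = 40, B = 80), offset = 5000,
                       divergence = 0)
  g <- simulate_repeat_genome(2e5, list(fam), seed = 221)
  tA <- count_kmers(simulate_reads(g$A, 25, 100, seed = 222), k = 25)
  tB <- count_kmers(simulate_reads(g$B, 25, 100, seed = 223), k = 25)
  recs <- extract_hakmers(tA, tB, min_total = 500)
  recs <- call_differential(recs, tA$total_instances, tB$total_instances)
  fam_kmers <- canonical_kmer(seq_windows(paste0(unit, unit), 25))
  in_fam <- recs$kmer %in% fam_kmers
  expect_gte(sum(in_fam), 100)
  nB_gt_nA <- with(recs[in_fam, ], count_B / sum(tB$counts) >
                     count_A / sum(tA$counts))
  expect_gte(mean(nB_gt_nA & recs$p_adj[in_fam] < 0.05), 0.95)
  # 2.5x gap clears the 2-fold call threshold for essentially every k-mer
  fam2 <- repeat_family("fam", unit, c(A = 32, B = 80), offset = 5000,
                        divergence = 0)
  g2 <- simulate_repeat_genome(2e5, list(fam2), seed = 224)
  tA2 <- count_kmers(simulate_reads(g2$A, 25, 100, seed = 225), k = 25)
  tB2 <- count_kmers(simulate_reads(g2$B, 25, 100, seed = 226), k = 25)
  recs2 <- extract_hakmers(tA2, tB2, min_total = 500)
  recs2 <- call_differential(recs2, tA2$total_instances, tB2$total_instances)
  in_fam2 <- recs2$kmer %in% fam_kmers
  expect_gte(mean(recs2$call[in_fam2] == "B-gain"), 0.95)
  expect_false(any(recs2$call[in_fam2] == "A-gain"))
})

test_that("annotation agrees with its seed-and-align contract", {
  set.seed(231)
  centc <- random_dna(156)
  knob <- random_dna(180)
  lib <- repeat_library(c(CentC_1 = centc, knob_1 = knob),
                        classes = c("CentC", "knob"))
  # exact 25-bp slice annotates with 0 mismatches
  km <- substring(centc, 40, 64)
  a1 <- annotate_kmers(km, lib)
  expect_equal(a1$annotation, "CentC")
  expect_equal(a1$mismatches, 0L)
  # reverse-complemented slice annotates identically
  expect_equal(annotate_kmers(oracle_revcomp(km), lib)$annotation, "CentC")
  # one substitution vs knob still hits knob (3+ vs everything else)
  km2 <- substring(knob, 60, 84)
  substr(km2, 13, 13) <- setdiff(c("A", "C", "G", "T"),
                                 substring(km2, 13, 13))[1]
  a2 <- annotate_kmers(km2, lib)
  expect_equal(a2$annotation, "knob")
  expect_equal(a2$mismatches, 1L)
  # three substitutions exceed max_mismatch: unannotated
  km3 <- substring(knob, 60, 84)
  for (i in c(3, 13, 23))
    substr(km3, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substring(km3, i, i))[1]
  expect_equal(annotate_kmers(km3, lib)$annotation, "unannotated")
  # random k-mers share no 12-bp seed with a toy library
  rnd <- vapply(1:20, function(i) random_dna(25), "")
  expect_true(all(annotate_kmers(rnd, lib)$annotation == "unannotated"))
})

test_that("mismatches inside the seed still require a 12-bp exact run", {
  set.seed(232)
  entry <- random_dna(100)
  lib <- repeat_library(c(e = entry), classes = "X")
  km <- substring(entry, 30, 54)
  # two substitutions splitting the k-mer into runs all shorter than 12
  substr(km, 9, 9) <- setdiff(c("A", "C", "G", "T"), substring(km, 9, 9))[1]
  substr(km, 18, 18) <- setdiff(c("A", "C", "G", "T"), substring(km, 18, 18))[1]
  expect_equal(annotate_kmers(km, lib)$annotation, "unannotated")
  # two substitutions leaving a 13-run hit with 2 mismatches
  km2 <- substring(entry, 30, 54)
  substr(km2, 2, 2) <- setdiff(c("A", "C", "G", "T"), substring(km2, 2, 2))[1]
  substr(km2, 5, 5) <- setdiff(c("A", "C", "G", "T"), substring(km2, 5, 5))[1]
  a <- annotate_kmers(km2, lib)
  expect_equal(a$annotation, "X")
  expect_equal(a$mismatches, 2L)
})

test_that("reference mapping reports all exact hits and bins them", {
  set.seed(241)
  km <- random_dna(25)
  ref <- c(chrA = paste0(random_dna(500), km, random_dna(500), km,
                         random_dna(200)),
           chrB = paste0(random_dna(300), oracle_revcomp(km),
                         random_dna(100)))
  res <- map_kmers_to_reference(km, ref, bin_size = 400)
  expect_equal(nrow(res$hits), 3)
  expect_equal(sum(res$hits$chrom == "chrA"), 2)
  expect_equal(res$hits$strand[res$hits$chrom == "chrB"], "-")
  expect_equal(sum(res$bins$hits), 3)
  # brute-force scan agrees on total count
  expect_equal(nrow(res$hits),
               oracle_substring_count(ref[[1]], km) +
                 oracle_substring_count(ref[[2]], km))
  # palindromic (even-length) k-mer: both-strand hits dedupe to one
  P <- random_dna(12)
  pal <- paste0(P, oracle_revcomp(P))
  expect_identical(pal, oracle_canonical(pal))
  ref2 <- c(chr = paste0(random_dna(100), pal, random_dna(100)))
  expect_equal(nrow(map_kmers_to_reference(pal, ref2)$hits), 1)
})

test_that("class abundance ratios recover planted copy ratios", {
  recs <- data.frame(kmer = c("a", "b", "c"),
                     count_A = c(100, 300, 0), count_B = c(100, 300, 50),
                     annotation = c("X", "X", "Y"))
  out <- class_abundance_summary(recs, 1e6, 1e6)
  expect_equal(out$ratio_BA[out$class == "X"], 1.0)
  expect_true(out$infinite[out$class == "Y"])
  expect_equal(out$ratio_BA[out$class == "Y"], Inf)
  expect_error(class_abundance_summary(recs, 1e6, 1e6, classes = "Z"),
               "unknown class")
})

test_that("planted CentC-like 1.71x class ratio is recovered from reads", {
  set.seed(251)
  centc <- random_dna(156)
  fam <- repeat_family("CentC", centc, c(A = 100, B = 171), offset = 20000)
  g <- simulate_repeat_genome(5e5, list(fam), seed = 251)
  tA <- count_kmers(simulate_reads(g$A, 20, 100, seed = 252), k = 25)
  tB <- count_kmers(simulate_reads(g$B, 20, 100, seed = 253), k = 25)
  recs <- extract_hakmers(tA, tB, min_total = 500)
  lib <- repeat_library(c(CentC_1 = centc), classes = "CentC")
  ann <- annotate_kmers(recs$kmer, lib)
  recs$annotation <- ann$annotation
  out <- class_abundance_summary(recs, tA$total_instances, tB$total_instances,
                                 classes = "CentC")
  expect_equal(out$ratio_BA, 1.71, tolerance = 0.05)
})
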