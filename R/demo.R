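# End-to-end demonstration pipeline on synthetic data: two genotypes with
# diverging repeat clusters, shotgun reads, k-mer spectra and sharing,
# differential HAKmer calls with annotation, a DH mapping population with
# cnvQTL scans, a grouped panel with normalization and trend detection,
# and allelic expression from paired polymorphic k-mers.

#' Run the full synthetic demonstration pipeline
#'
#' Generates a self-contained synthetic study — two parental genotypes
#' differing in repeat-family copy numbers, a doubled-haploid mapping
#' population, and a grouped diversity panel — then runs every analysis
#' stage and (optionally) writes the declared TSV/FASTA artifacts to
#' `outdir`. Problem sizes are desk-scale; identical seeds give identical
#' results.
#'
#' @param seed integer seed governing every stage.
#' @param outdir optional output directory for artifacts.
#' @param n_lines DH population size.
#' @param backbone_length shared backbone length (bp).
#' @param depth parental sequencing depth (fold-coverage).
#' @param line_depth per-DH-line sequencing depth.
#' @param k k-mer size.
#' @return list of stage results (see names of the returned list).
#' @export
run_demo <- function(seed = 1, outdir = NULL, n_lines = 60,
                     backbone_length = 50000L, depth = 20, line_depth = 4,
                     k = 25L) {
  set.seed(seed)
  fams <- default_repeat_families(copies = list(
    CentC = c(A = 60, B = 103),
    knob180 = c(A = 80, B = 36),
    telomere = c(A = 120, B = 96)))
  for (i in seq_along(fams))  # spread cluster loci across the backbone
    fams[[i]]$offset <- as.integer(i * backbone_length %/% (length(fams) + 1))
  genomes <- simulate_repeat_genome(backbone_length, fams, snv_rate = 0.005)
  readsA <- simulate_reads(genomes$A, depth = depth, read_len = 100L,
                           error_rate = 0.002, sample_id = "A")
  readsB <- simulate_reads(genomes$B, depth = depth, read_len = 100L,
                           error_rate = 0.002, sample_id = "B")
  tabA <- count_kmers(readsA, k = k, min_count = 2)
  tabB <- count_kmers(readsB, k = k, min_count = 2)
  specA <- kmer_spectrum(tabA); specB <- kmer_spectrum(tabB)
  size_est <- c(A = estimate_genome_size(specA),
                B = estimate_genome_size(specB))
  bandA <- single_copy_band(specA); bandB <- single_copy_band(specB)
  sharing <- sharing_summary(tabA, tabB, bandA, bandB)

  # differential HAKmers; the demo threshold admits families down to
  # ~25 copies at the configured depth (0.76 counted windows per base)
  min_total <- 25 * 2 * depth * 0.76
  recs <- extract_hakmers(tabA, tabB, min_total = min_total)
  recs <- call_differential(recs, tabA$total_instances, tabB$total_instances)
  recs <- classify_genotype_specific(recs)
  lib <- repeat_library(
    stats::setNames(vapply(fams, `[[`, "", "unit_seq"),
                    vapply(fams, `[[`, "", "name")))
  ann <- annotate_kmers(recs$kmer, lib)
  recs$annotation <- ann$annotation
  class_ratio <- class_abundance_summary(recs, tabA$total_instances,
                                         tabB$total_instances)

  # DH population: CentC cluster segregates; per-line low-pass reads
  map <- genetic_map(n_chrom = 3, length_cM = 120, spacing_cM = 2)
  clus <- data.frame(family = "CentC", chrom = 1, cM = 50)
  dh <- simulate_dh_panel(genomes$A, genomes$B, map, n_lines,
                          cluster_positions = clus)
  line_tabs <- lapply(seq_len(n_lines), function(i) {
    fam_i <- fams
    fam_i$CentC$copies <- c(L = unname(dh$line_truth[i, "CentC"]))
    fam_i$knob180$copies <- c(L = 80); fam_i$telomere$copies <- c(L = 120)
    # line genomes share the parental backbone and repeat-unit banks
    g <- simulate_repeat_genome(backbone_length, fam_i, genotypes = "L",
                                backbone = attr(genomes, "backbone"),
                                banks = attr(genomes, "banks"))
    count_kmers(simulate_reads(g$L, depth = line_depth, read_len = 100L,
                               sample_id = sprintf("DH%03d", i)), k = k)
  })
  names(line_tabs) <- rownames(dh$genotypes)
  sc_kmers <- select_single_copy(tabA, bandA)
  sc_shared <- intersect(sc_kmers, names(tabB$counts))
  cand <- sc_shared[seq_len(min(5000, length(sc_shared)))]
  pan <- panel_counts(line_tabs, cand)
  # at desk scale (few lines, ~2-3x per-k-mer line depth) correlation
  # ranking is noisy, so a generous retained fraction keeps the factor
  # totals dominated by genuinely conserved k-mers
  conserved <- select_conserved_single_copy(pan, top_frac = 0.5)
  fac <- normalization_factors(colSums(pan$counts[conserved, , drop = FALSE]))
  centc_kmers <- recs$kmer[recs$annotation == "CentC"]
  centc_kmers <- head(centc_kmers[order(-(recs$count_A + recs$count_B)[
    match(centc_kmers, recs$kmer)])], 20)
  qtl_pan <- panel_counts(line_tabs, centc_kmers,
                          library_sizes = pan$library_sizes)
  qtl <- map_hakmer_set(
    data.frame(kmer = centc_kmers, annotation = "CentC"),
    qtl_pan, dh$genotypes, map, fac, threshold = 4)

  # allelic expression: triploid endosperm-like dosage 2:1
  allelic <- simulate_allelic_counts(2, 1, per_copy_rate = 5000, n_pairs = 3)
  pooled <- sum(allelic$maternal) / sum(allelic$paternal)

  res <- list(genomes = genomes, size_est = size_est, sharing = sharing,
              records = recs, class_ratio = class_ratio, dh = dh,
              factors = fac, qtl = qtl, allelic = allelic,
              pooled_ratio = pooled, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genomes$A$sequences, file.path(outdir, "genomeA.fasta"))
    write_fasta(genomes$B$sequences, file.path(outdir, "genomeB.fasta"))
    write_count_table(tabA, file.path(outdir, "counts_A.tsv"))
    write_count_table(tabB, file.path(outdir, "counts_B.tsv"))
    write_spectrum(specA, file.path(outdir, "spectrum_A.tsv"))
    write.table(recs, file.path(outdir, "hakmers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(class_ratio, file.path(outdir, "class_ratio.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_genetic_map(map, file.path(outdir, "genetic_map.tsv"))
    write_genotypes(dh$genotypes, file.path(outdir, "genotypes.tsv"))
    write_factors(fac, file.path(outdir, "normalization_factors.tsv"))
    write.table(qtl$peaks, file.path(outdir, "cnvqtl_peaks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(allelic, file.path(outdir, "allelic_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}
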