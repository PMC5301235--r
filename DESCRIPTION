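Package: kmercnv
Title: Reference-Free k-mer Analysis of Repeat Copy-Number Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free comparative genomics from shotgun reads using
    canonical k-mer counts. Quantifies genome dissimilarity between
    genotypes, tests differential abundance of highly abundant k-mers
    (HAKmers) with chi-square tests and FDR control, classifies
    genotype-specific k-mers, annotates k-mers against a repeat library,
    normalizes multi-sample panels with conserved single-copy k-mers,
    genetically maps copy-number variation of repeat clusters (cnvQTL) in
    doubled-haploid populations via single-marker LOD scans with
    permutation thresholds, estimates repeat-family copy numbers from
    k-mer depth, detects abundance trends across evolutionary groups, and
    traces allele-specific rRNA expression with paired polymorphic
    k-mers. Includes a synthetic-data generator producing repeat-bearing
    genomes, shotgun reads, doubled-haploid panels, grouped multi-line
    panels, and triploid allelic transcript counts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
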