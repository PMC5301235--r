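---
title: "Methods: reference-free k-mer analysis of repeat copy-number variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free k-mer analysis of repeat copy-number variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`kmercnv` analyses genome divergence between genotypes directly from
shotgun reads, without an assembly or alignment step. All statistics are
built on canonical 25-mer counts: a k-mer and its reverse complement are
one unit (the lexicographic minimum of the two), because sequencing does
not observe strand. The package covers six analyses:

1. **Spectra and genome size** — abundance histograms of canonical
   k-mers, the single-copy peak, and a spectrum-based genome-size
   estimate.
2. **Differential HAKmers** — highly abundant k-mers (HAKmers) tested
   for abundance differences between two genotypes with a chi-square
   test and Benjamini–Hochberg FDR control, classified as gains or as
   genotype-specific, annotated against a repeat library, and located on
   a reference.
3. **Conserved single-copy normalization** — per-line depth correction
   for multi-line panels built from k-mers whose counts track library
   size.
4. **cnvQTL mapping** — normalized k-mer abundance treated as a
   quantitative trait in a doubled-haploid (DH) population, scanned
   marker-by-marker for LOD peaks against a permutation threshold.
5. **Population trends** — highly variable k-mers across grouped panels,
   one-way ANOVA with Bonferroni control, shared-covariance Gaussian
   mixture clustering of max-scaled profiles, and PCA of lines.
6. **Allele-specific rRNA expression** — pairs of k-mers differing at a
   single base that discriminate parental rDNA alleles, quantified in
   RNA-seq counts as pooled maternal:paternal ratios.

A synthetic-data module generates genomes, read sets, DH panels, grouped
panels and allelic transcript counts with the statistical structure these
analyses assume, so every stage is exercisable end to end
(`run_demo()`).

# Counting model

Every read window of length k containing only A/C/G/T adds one count to
its canonical form; windows containing other letters (N) are skipped
rather than randomized. k = 25 is the working size: long enough that
single-copy 25-mers are effectively unique in a multi-megabase genome,
short enough that per-window error contamination stays modest. For
error-free reads of length L at fold-coverage D, a single-copy k-mer's
expected count is

$$\lambda = D \cdot (L - k + 1) / L,$$

the coverage correction for windows lost at read ends. Sequencing errors
scatter counts into low-abundance k-mers; a minimum-count filter
(`min_count`) plays the role of upstream read error correction by
dropping them. The trough/peak detector smooths the histogram with a
3-bin moving average (robustness to sampling noise at desk-scale depth),
takes the first local maximum above a floor abundance (`search_min`,
default 2, guarding against the abundance-1 error spike), the trough as
the argmin left of it, and the peak as the argmax right of the trough.

**Genome size** is the total k-mer mass above the trough divided by the
single-copy depth. Because the integer peak is granular (one abundance
unit is ~4% of the depth at 25–30x), the divisor is refined as the
histogram-weighted mean abundance within ±30% of the integer peak
(`single_copy_depth()`); this keeps the estimate stable to ±2% when the
depth is doubled. The estimator approximates the number of distinct
genomic k-mer start positions, i.e. genome length for k ≪ genome; it is
a deliberate, stated substitute for assembler-internal estimators.

**Single-copy band**: by default `[round(0.55·peak), round(1.35·peak)]`,
inclusive. At a 37x k-mer depth this reproduces the fixed window
\[20, 50\], which can also be supplied verbatim via `override`.
Between-genotype sharing of single-copy k-mers is judged by *presence*
(count ≥ 1) in the other genotype's table by default — a genome-specific
single-copy k-mer is one the other genome lacks entirely, not one
falling outside the other genome's band — with band-membership mode
available (`mode = "band"`).

# Differential HAKmers

HAKmers are k-mers with combined two-genotype count ≥ `min_total`
(default 20,000, defined at ~92x combined coverage; at that depth it
implies roughly a 215-copy floor). `scale_min_total()` transfers the
criterion to other simulated depths; desk-scale runs that plant
30–170-copy families pass an explicitly lower threshold so those
families qualify.

The test is a 1-df goodness-of-fit of the observed counts against the
library-size-proportional expectation:

$$e_A = T\frac{L_A}{L_A+L_B},\quad e_B = T\frac{L_B}{L_A+L_B},\quad
\chi^2 = \frac{(c_A-e_A)^2}{e_A} + \frac{(c_B-e_B)^2}{e_B},$$

with T = c_A + c_B, no continuity correction. This formulation tests
"no relationship between counts and genotype" while correcting depth
imbalance. Calls require BH-adjusted p < 0.05 **and** a ≥ 2-fold change
computed on library-size-normalized counts (denominator floored at one
raw count). A HAKmer with count ≤ 10 in one genotype is
genotype-specific: with the 20,000 threshold this forces > 19,990 counts
in the retained genotype.

The chi-square model assumes counts are (approximately) independent
Poisson draws — true when any one repeat family is a negligible fraction
of the genome, as in real multi-gigabase data. On desk-scale synthetic
genomes where one family occupies 10% or more of the genome, counts are
slightly underdispersed and family k-mers share reads; the test is then
conservative, which the test suite asserts as a no-false-calls property
rather than exact calibration.

**Annotation** replaces a BLASTN search (word size 12, e-value 0.1) with
a defined operator: a k-mer hits a library entry if, on either strand,
it shares an exact substring of ≥ 12 bases with the entry and aligns
end-to-end at the seed-anchored offset with ≤ 2 substitutions. Best hit
= fewest mismatches, ties by longest seed then library order. The
operator is deterministic and exactly testable, at the cost of e-value
statistics (not needed for 25-mers against a curated library).

**Reference mapping** reports all exact full-length hits on both strands
(1-based starts), deduplicating coordinates for reverse-complement
palindromic (even-k) k-mers, and aggregates hits into 100-kb bins.

# Conserved single-copy normalization

Sequencing depth and organelle contamination differ across panel lines,
so raw counts are not comparable. From candidate k-mers single-copy in
the reference genotypes, each k-mer's per-line counts are correlated
(Pearson — the assumption is proportionality to library size) with the
per-line library sizes; the top fraction (default 5%) are "conserved
single-copy k-mers". With their per-line totals C_i, the factor is

$$f_i = \frac{\bar{C}}{C_i},$$

the multiplicative correction that equalises every line's conserved
total to the panel mean — the property the normalization exists to
provide (the identity `mean(C_i · f_i) = mean(C)` is asserted
exactly in the tests). Organelle-contaminated or shallow lines get
f_i > 1 automatically; no organelle reference is needed.

At desk scale the correlation ranking is noisy: with ~20 lines and 2–3x
per-k-mer depth, a 5% cut of 2,000 candidates retains mostly
chance-correlated k-mers and the factors degrade. `run_demo()` therefore
retains 50% of 5,000 candidates; with panels of ≥ 50 lines at realistic
candidate set sizes (the default regime of
`select_conserved_single_copy()`), the 5% default is appropriate.

**Copy number** of a repeat family is the median (deliberately not the
mean — robust to a duplicated sub-span of the unit, where the median
picks the majority mode) over family k-mers of count / single-copy
depth, the depth taken from the line's own spectrum peak. The family
k-mer set should be pre-filtered to k-mers conserved across copies and
free of hits to other repeat classes or organelle sequence. Per-copy
sequence divergence biases the estimator downward (a diverged copy stops
matching the consensus k-mer), which is why the simulator's rDNA-like
family defaults to 0.1% per-copy divergence — tandem rDNA arrays are
homogenised by concerted evolution — while satellite families default to
0.5%.

# cnvQTL mapping

Normalized abundance of one k-mer across DH lines is a quantitative
trait. DH genotypes are fully homozygous and fully informative at
markers, so single-marker regression is the exact marker-position form
of standard QTL scans (interval-mapping machinery degenerates to it):

$$\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1},$$

with RSS0 the total and RSS1 the within-genotype-class sum of squares
(equal to the two-group normal likelihood ratio with MLE variances — an
algebraic identity the tests verify to 1e-9). Missing genotypes are
dropped pairwise per marker; monomorphic markers report NA; perfect
separation (RSS1 = 0) is capped at LOD 50 for finite reporting; a
constant trait warns and reports all zeros.

The genome-wide threshold is the empirical 95th percentile (type-7
quantile) of the maximum LOD over ≥ 1,000 trait permutations. Under the
study conditions (280 lines, 10 chromosomes × 140 cM, 1 cM Haldane
markers, normal traits) this lands at ≈ 3.0; peaks are declared at
max(threshold, 4), the hard floor dominating in practice. Peak calling
is greedy: highest qualifying marker first, suppressing markers within
30 cM on the same chromosome, up to 4 peaks per k-mer — k-mers shared by
clusters on several chromosomes legitimately map to several loci, and an
empty result means "could not be mapped".

# Population trends

Highly variable k-mers satisfy two strict hard-filter predicates on
normalized counts: > 1,000 in ≥ 5 lines and < 10 in ≥ 5 other lines
(boundary values excluded, as the thresholds are written). Each passes a
one-way fixed-effects ANOVA against the ordered evolutionary groups
(on normalized counts directly, not log counts); the family-wise
Bonferroni rule p < α/m controls the 5% error over m tested k-mers
(Bonferroni significance implies BH significance, asserted as a
dominance property).

For clustering, each k-mer's profile is divided by its own maximum
(idempotent, rows in \[0, 1\]) and fitted with Gaussian mixtures sharing
one full covariance across components (mclust model "EEE", G = 1–12),
the model chosen by BIC — `gmm_cluster()` calls `mclust::Mclust()`
directly. A cluster's direction across the group ordering is decided by
a 20%-of-range rule on its mean profile (first-group mean vs last-group
mean), replacing a manual grouping step with a declared, testable one;
clusters failing it are "flat" and excluded from the trend table. PCA of
lines uses `prcomp` on centered, unscaled normalized counts.

# Allele-specific expression

A single-nucleotide variant inside an rRNA gene yields k-mer pairs
differing at exactly one aligned base (Hamming distance compared in both
orientations, since the canonical forms of SNV mates can come from
opposite strands). `find_snv_pairs()` finds pairs where one member is
abundant in one genotype but near-absent (≤ 10) in the other while its
partner is abundant in the genotype the first member misses — the
configuration that lets RNA-seq counts be assigned to parental alleles.
Pairing is greedy by abundance and each k-mer joins at most one pair.

Per sample, the allelic balance is `log2((c_B + 0.5)/(c_A + 0.5))` (the
pseudocount stabilises zeros; both-zero samples are NA), and the
per-stage summary is the pooled ratio Σ maternal / Σ paternal — the
variance-minimising estimator for Poisson counts, preferred over the
mean of per-pair ratios. A stage with zero paternal counts is flagged
infinite (maternal-only expression is a real biological outcome, not an
error). In the triploid endosperm model (2n maternal : 1n paternal,
equal per-copy transcription) the pooled ratio recovers 2.0 within
Poisson sampling error.

# The synthetic-data generator

The generator emulates exactly what the analyses assume:

* **Genomes**: a shared random backbone (uniform base composition) with
  genotype-specific SNVs at a supplied per-bp rate, and tandem repeat
  clusters inserted at fixed loci — each family a head-to-tail array of
  its unit with genotype-specific copy number. Copies are realised once
  per copy index, so two genotypes share copy i exactly and the
  higher-copy genotype appends extra copies; per-copy divergence
  (default 0.5%, 0.1% for rDNA, configurable) keeps family k-mers shared
  while copies are not identical. Dispersed placement inserts single
  copies at shared random offsets. Truth records carry 1-based inclusive
  placements and backbone-coordinate SNV positions; inserted bases plus
  backbone equals genome length exactly.
* **Reads**: uniform start positions on both strands, i.i.d.
  substitution errors, total bases ≈ depth × genome length; paired mode
  emits both mates of fixed-insert fragments. No indels, GC bias,
  quality realism or PCR duplicates — the analyses never consume
  qualities, and substitutions are the error mode that pollutes k-mer
  tables.
* **DH panels**: per chromosome, each fully homozygous line is a mosaic
  of parental blocks with Haldane crossovers
  (r = (1 − e^(−2d/100))/2, no interference); any map expansion from
  intermating is assumed baked into the supplied cM positions. A line's
  copy number of a clustered family is the covering parent's. Default
  map density of 1 marker/cM is a choice, not data-derived.
* **Grouped panels**: per-line copy numbers drawn from group-level
  negative-binomial profiles on a shared backbone; per-line depth drawn
  from a range; organelle contamination as reads from one 150-kb
  circular plasmid-like sequence.
* **Allelic counts**: maternal/paternal counts as independent
  Poisson(dosage × per-copy rate) draws per k-mer pair.

What passing tests on this generator show — and do not show: they
validate the statistical machinery under its stated assumptions
(uniform coverage, substitution-only errors, clustered repeats,
no interference). They do not certify behaviour under real-data
pathologies: coverage bias, indel/structural error modes, repeat
libraries with internal homology between classes, segregation
distortion, or reference-genome incompleteness.

# Problem sizes and determinism

Desk-scale defaults keep the full test suite and demonstration pipeline
in the minutes range: 0.2–2 Mb genomes at 20–30x for recovery tests,
280-line DH panels at marker resolution for mapping properties, panels
of 8–20 lines for normalization and trends, and `run_demo()` at a 30–50
kb backbone with 12–60 lines at 3–4x line depth. These sizes are the
package's validation conditions, chosen so that expected counts sit
where the corresponding real-data quantities sit (e.g. ≥ 200 expected
counts per genotype for power checks). Every stochastic entry point
takes an explicit seed; identical seeds give byte-identical outputs
(asserted in the tests), and k ≤ 31 keeps a k-mer in one 64-bit word in
the compiled counting core.

# Known limitations

* In-memory counting only: tables are named vectors; datasets beyond
  ~100 M distinct k-mers need disk-backed counters upstream.
* The annotation operator is not an aligner: no gaps, no e-values; it is
  designed for fixed-length k-mers against curated repeat consensi.
* Copy-number estimates inherit the single-copy depth's accuracy; on
  heavily repetitive genomes where the single-copy peak is weak, supply
  an explicit band or depth.
* The chi-square test treats counts as independent Poisson; on small
  synthetic genomes with dominant repeat families it is conservative
  (see above).
* `find_snv_pairs()` targets genotype-discriminating sites in
  high-copy families; it is not a general SNV caller.
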