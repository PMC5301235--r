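#!/usr/bin/env Rscript
# Thin command-line wrapper over the kmercnv package.
#
#   kmercnv count    --reads r.fastq[.gz] --k 25 --min-count 1 --out table.tsv
#   kmercnv spectrum --table table.tsv --out spectrum.tsv
#   kmercnv diff     --table-a a.tsv --table-b b.tsv --min-total 20000 \
#                    --fdr 0.05 --min-fold 2 --out hakmers.tsv
#   kmercnv demo     --seed 1 --outdir demo_out

suppressPackageStartupMessages(library(kmercnv))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  message("usage: kmercnv <count|spectrum|diff|demo> [options]")
  quit(status = 1)
}
cmd <- args[1]
opts <- args[-1]
getopt <- function(flag, default = NULL) {
  i <- match(flag, opts)
  if (is.na(i) || i == length(opts)) default else opts[i + 1]
}

status <- tryCatch({
  switch(
    cmd,
    count = {
      reads <- read_fastq(getopt("--reads"))
      tab <- count_kmers(reads,
                         k = as.integer(getopt("--k", 25)),
                         min_count = as.integer(getopt("--min-count", 1)))
      write_count_table(tab, getopt("--out", "counts.tsv"))
    },
    spectrum = {
      tab <- read_count_table(getopt("--table"))
      write_spectrum(kmer_spectrum(tab), getopt("--out", "spectrum.tsv"))
    },
    diff = {
      ta <- read_count_table(getopt("--table-a"))
      tb <- read_count_table(getopt("--table-b"))
      recs <- extract_hakmers(ta, tb,
                              min_total = as.numeric(getopt("--min-total", 20000)))
      recs <- call_differential(recs, ta$total_instances, tb$total_instances,
                                fdr = as.numeric(getopt("--fdr", 0.05)),
                                min_fold = as.numeric(getopt("--min-fold", 2)))
      recs <- classify_genotype_specific(
        recs, max_low = as.numeric(getopt("--max-low", 10)))
      write.table(recs, getopt("--out", "hakmers.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    },
    demo = {
      run_demo(seed = as.integer(getopt("--seed", 1)),
               outdir = getopt("--outdir", "demo_out"))
      invisible(NULL)
    },
    {
      message("unknown subcommand: ", cmd)
      quit(status = 1)
    })
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
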