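# Readers and writers for the formats the pipeline exchanges: FASTA /
# FASTQ (via Biostrings; gzip and multi-line records accepted), and
# '#'-headed TSV serialisations of count tables, spectra, genetic maps,
# genotype matrices and normalization factors. Every writer's output
# parses back to an equal in-memory object.

#' Read sequences from FASTA
#'
#' @param path FASTA file (gzip accepted); sequences are uppercased.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, format = "fasta")
  invisible(path)
}

#' Read reads from FASTQ
#'
#' @param path FASTQ file (gzip accepted).
#' @return a `read_set` with uppercased reads.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- toupper(as.character(x))
  structure(list(reads = unname(reads),
                 read_len = if (length(reads)) max(nchar(reads)) else 0L,
                 depth = NA_real_, paired = FALSE,
                 sample_id = sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))),
            class = "read_set")
}

#' Write a read set to FASTQ
#'
#' Phred+33 with a dummy quality of 'I' for every base (simulated reads
#' carry no quality model).
#'
#' @param reads a `read_set` or character vector.
#' @param path output file (`.gz` suffix compresses).
#' @export
write_fastq <- function(reads, path) {
  id <- "read"
  if (inherits(reads, "read_set")) { id <- reads$sample_id; reads <- reads$reads }
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_%d", id, seq_along(x))
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a k-mer count table to TSV
#'
#' Two sorted columns (kmer, count) under '#'-prefixed header lines
#' carrying k, sample_id, library_bases and total_instances.
#'
#' @param table a `kmer_count_table`.
#' @param path output file.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# k=%d", table$k),
               sprintf("# sample_id=%s", table$sample_id),
               sprintf("# library_bases=%.0f", table$library_bases),
               sprintf("# total_instances=%.0f", table$total_instances),
               "kmer\tcount"), con)
  write.table(data.frame(names(table$counts), format(table$counts, scientific = FALSE, trim = TRUE)),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# key=value from '#'-prefixed header lines
.read_header <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  kv <- sub("^#\\s*", "", hdr)
  kv <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                  vapply(kv, `[[`, "", 1))
}

#' Read a k-mer count table from TSV
#'
#' @param path file written by [write_count_table()].
#' @return a `kmer_count_table`.
#' @export
read_count_table <- function(path) {
  meta <- .read_header(path)
  df <- read.delim(path, comment.char = "#", header = TRUE)
  structure(list(k = as.integer(meta[["k"]]),
                 counts = stats::setNames(as.numeric(df$count), df$kmer),
                 library_bases = as.numeric(meta[["library_bases"]]),
                 total_instances = as.numeric(meta[["total_instances"]]),
                 sample_id = meta[["sample_id"]]),
            class = "kmer_count_table")
}

#' Write a spectrum to TSV
#' @param spectrum a `kmer_spectrum`.
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d", attr(spectrum, "k")), con)
  write.table(as.data.frame(spectrum), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from TSV
#' @param path file written by [write_spectrum()].
#' @return a `kmer_spectrum`.
#' @export
read_spectrum <- function(path) {
  meta <- .read_header(path)
  df <- read.delim(path, comment.char = "#")
  structure(data.frame(abundance = as.integer(df$abundance),
                       n_kmers = as.numeric(df$n_kmers)),
            k = as.integer(meta[["k"]]),
            class = c("kmer_spectrum", "data.frame"))
}

#' Write a genetic map to TSV
#' @param map `data.frame(chrom, cM, id)`.
#' @param path output file.
#' @export
write_genetic_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map from TSV
#' @param path file written by [write_genetic_map()].
#' @return `data.frame(chrom, cM, id)`.
#' @export
read_genetic_map <- function(path) {
  df <- read.delim(path, comment.char = "#")
  df$chrom <- as.integer(df$chrom)
  df
}

#' Write a genotype matrix to TSV
#'
#' Lines x markers codes `A`/`B` with a `line` first column.
#'
#' @param genotypes lines x markers matrix.
#' @param path output file.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(line = rownames(genotypes), genotypes,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#' @param path file written by [write_genotypes()].
#' @return lines x markers character matrix.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line
  m
}

#' Write normalization factors to TSV
#' @param factors a `normalization_factors`.
#' @param path output file.
#' @export
write_factors <- function(factors, path) {
  df <- data.frame(line = names(factors$factor), C = unname(factors$totals),
                   factor = unname(factors$factor))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference_total=%.10g", factors$reference_total), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read normalization factors from TSV
#' @param path file written by [write_factors()].
#' @return a `normalization_factors`.
#' @export
read_factors <- function(path) {
  df <- read.delim(path, comment.char = "#")
  normalization_factors(stats::setNames(df$C, df$line))
}
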