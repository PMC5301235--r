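# Synthetic genomes, populations, reads and transcript counts with the
# statistical structure the k-mer analyses assume: two genotypes sharing a
# backbone but differing in copy number of clustered tandem-repeat families
# and in single-base variants; shotgun reads with substitution errors; a
# doubled-haploid population segregating the repeat clusters on a genetic
# map; grouped multi-line panels with varying depth and organelle
# contamination; and triploid allelic transcript counts.

#' Describe a tandem-repeat family
#'
#' A repeat family is a sequence unit repeated head-to-tail in a cluster at
#' a fixed backbone locus (or dispersed as single copies), with a
#' genotype-specific copy number. Optional named sub-regions (e.g. the
#' 18S/ITS/26S/IGS spans of an rDNA unit) must tile the unit without
#' overlap.
#'
#' @param name family label (e.g. `"CentC"`).
#' @param unit_seq DNA string, the repeat unit (50 bp to 10 kb for
#'   clustered families; shorter motifs such as the telomere repeat are
#'   accepted).
#' @param copies named integer vector, copy number per genotype (>= 0).
#' @param chrom backbone chromosome index of the cluster locus.
#' @param offset 1-based backbone position after which the cluster is
#'   inserted, or `"dispersed"` in `placement`.
#' @param placement `"cluster"` (default) or `"dispersed"` (copies placed
#'   singly at random backbone positions).
#' @param substructure optional `data.frame(name, start, end)` of sub-region
#'   spans (1-based, inclusive) tiling the unit.
#' @param divergence per-copy substitution rate applied independently to
#'   each tandem copy, so that family k-mers are shared within the family
#'   while copies are not strictly identical. Tandem satellites are
#'   homogenised by concerted evolution, so the default is low.
#' @return an object of class `repeat_family`.
#' @export
repeat_family <- function(name, unit_seq, copies, chrom = 1L, offset = 1L,
                          placement = c("cluster", "dispersed"),
                          substructure = NULL, divergence = 0.005) {
  placement <- match.arg(placement)
  unit_seq <- toupper(unit_seq)
  if (grepl("[^ACGT]", unit_seq))
    stop("repeat unit for '", name, "' contains non-ACGT characters")
  if (any(copies < 0)) stop("copy numbers must be >= 0")
  if (is.null(names(copies))) stop("`copies` must be named by genotype")
  if (!is.null(substructure)) {
    ss <- substructure[order(substructure$start), ]
    ok <- ss$start[1] == 1 && ss$end[nrow(ss)] == nchar(unit_seq) &&
      all(ss$start[-1] == ss$end[-nrow(ss)] + 1L)
    if (!ok) stop("substructure spans must tile the unit without overlap")
  }
  structure(
    list(name = name, unit_seq = unit_seq, copies = copies,
         chrom = as.integer(chrom), offset = as.integer(offset),
         placement = placement, substructure = substructure,
         divergence = divergence),
    class = "repeat_family")
}

#' Default maize-like repeat families
#'
#' A panel of family specifications emulating the major maize repeat
#' classes: a CentC-like 156-bp centromeric satellite, a knob-like 180-bp
#' satellite, an rDNA-like 9-kb unit with gene18S/ITS1/gene5.8S/ITS2/
#' gene26S/IGS sub-spans, and the TTTAGGG telomere motif. Unit sequences
#' are drawn from R's current RNG stream, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param copies named list, per-family named copy-number vectors
#'   (genotype -> copies); families omitted from the list are dropped.
#' @param backbone_chroms number of backbone chromosomes the offsets are
#'   spread over.
#' @return list of `repeat_family` objects.
#' @export
default_repeat_families <- function(copies = list(
                                      CentC = c(A = 100, B = 171),
                                      knob180 = c(A = 200, B = 90),
                                      rDNA45S = c(A = 140, B = 180),
                                      telomere = c(A = 300, B = 240)),
                                    backbone_chroms = 1L) {
  rdna_sub <- data.frame(
    name = c("gene18S", "ITS1", "gene5.8S", "ITS2", "gene26S", "IGS"),
    start = c(1L, 1801L, 2101L, 2261L, 2561L, 6001L),
    end = c(1800L, 2100L, 2260L, 2560L, 6000L, 9000L))
  spec <- list(
    CentC = list(unit = random_dna(156), sub = NULL, div = 0.005),
    knob180 = list(unit = random_dna(180), sub = NULL, div = 0.005),
    rDNA45S = list(unit = random_dna(9000), sub = rdna_sub, div = 0.001),
    telomere = list(unit = paste(rep("TTTAGGG", 10), collapse = ""),
                    sub = NULL, div = 0))
  keep <- intersect(names(spec), names(copies))
  out <- vector("list", length(keep))
  names(out) <- keep
  for (i in seq_along(keep)) {
    nm <- keep[i]
    out[[i]] <- repeat_family(
      name = nm, unit_seq = spec[[nm]]$unit, copies = copies[[nm]],
      chrom = ((i - 1L) %% backbone_chroms) + 1L,
      offset = i * 10000L, divergence = spec[[nm]]$div)
  }
  out
}

# tandem array for one family: per-copy divergence is realised once per copy
# index so genotypes sharing a copy index share its sequence exactly
.family_copy_bank <- function(fam, max_copies) {
  unit <- fam$unit_seq
  if (max_copies == 0L) return(character(0))
  if (fam$divergence <= 0) return(rep(unit, max_copies))
  ulen <- nchar(unit)
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(max_copies), function(i) {
    nmut <- rbinom(1L, ulen, fam$divergence)
    if (nmut == 0L) return(unit)
    pos <- sample.int(ulen, nmut)
    chars <- strsplit(unit, "", fixed = TRUE)[[1L]]
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    paste(chars, collapse = "")
  }, character(1))
}

#' Simulate a pair (or set) of repeat-bearing genomes
#'
#' Builds one genome per genotype: a shared random backbone carrying
#' genotype-specific single-nucleotide variants, with each repeat family
#' inserted as a head-to-tail tandem cluster at its backbone locus (copy
#' number per genotype from the family spec). Truth records (placements in
#' final 1-based coordinates, SNV positions in backbone coordinates) are
#' returned alongside the sequences.
#'
#' @param backbone_length backbone length in bp per chromosome; must be at
#'   least 10 times the longest repeat unit.
#' @param families list of [repeat_family()] objects.
#' @param snv_rate per-bp probability that a backbone position is a SNV
#'   between the genotypes.
#' @param genotypes genotype labels; copy numbers are looked up by these
#'   names in each family spec.
#' @param n_chrom number of backbone chromosomes.
#' @param seed integer seed; identical seeds give identical output.
#' @param backbone optional named character vector of backbone
#'   chromosomes to reuse (e.g. from a previous call's `"backbone"`
#'   attribute), so derived genomes share sequence with their parents.
#' @param banks optional list (family name -> character vector of
#'   per-copy unit sequences) to reuse; extended with fresh diverged
#'   copies if more are needed.
#' @return named list of `genome_truth` objects, one per genotype, each
#'   with `sequences` (named chromosome strings), `family_copy_number`,
#'   `placements` (1-based inclusive spans in the final genome),
#'   `snv_positions` (backbone coordinates) and `backbone_length`; the
#'   list carries the shared `backbone` and per-family unit `banks` as
#'   attributes for reuse.
#' @export
simulate_repeat_genome <- function(backbone_length, families = list(),
                                   snv_rate = 0, genotypes = c("A", "B"),
                                   n_chrom = 1L, seed = NULL,
                                   backbone = NULL, banks = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(families)) {
    longest <- max(vapply(families, function(f) nchar(f$unit_seq), 1))
    if (backbone_length < 10 * longest)
      stop("backbone_length must be >= 10 x the longest repeat unit")
    for (f in families) {
      if (f$chrom > n_chrom) stop("family '", f$name, "' on missing chromosome")
      if (f$offset < 1L || f$offset > backbone_length)
        stop("family '", f$name, "' offset outside the backbone")
      if (any(is.na(f$copies[genotypes])))
        stop("family '", f$name, "' lacks a copy number for some genotype")
    }
  }
  if (is.null(backbone)) {
    backbone <- vapply(seq_len(n_chrom),
                       function(i) random_dna(backbone_length), character(1))
    names(backbone) <- paste0("chr", seq_len(n_chrom))
  } else {
    stopifnot(all(nchar(backbone) == backbone_length),
              length(backbone) == n_chrom)
  }

  # SNVs between genotypes, in backbone coordinates
  snv <- data.frame(chrom = integer(0), pos = integer(0),
                    alleleA = character(0), alleleB = character(0))
  if (snv_rate > 0) {
    for (ch in seq_len(n_chrom)) {
      pos <- which(runif(backbone_length) < snv_rate)
      if (!length(pos)) next
      ref <- substring(backbone[ch], pos, pos)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1), USE.NAMES = FALSE)
      snv <- rbind(snv, data.frame(chrom = ch, pos = pos,
                                   alleleA = ref, alleleB = alt))
    }
  }

  # one shared bank of diverged copies per family (reused if supplied)
  fam_names <- vapply(families, `[[`, character(1), "name")
  banks <- lapply(families, function(f) {
    need <- max(f$copies[genotypes])
    have <- banks[[f$name]] %||% character(0)
    if (need > length(have))
      have <- c(have, .family_copy_bank(f, need - length(have)))
    have
  })
  names(banks) <- fam_names

  # flatten placements into elements: a cluster family is one element
  # carrying all its copies; a dispersed family becomes one single-copy
  # element per copy index at shared random offsets, so genotypes with
  # fewer copies carry a prefix of the same placements
  elements <- list()
  for (f in families) {
    if (f$placement == "cluster") {
      elements[[length(elements) + 1L]] <- list(
        name = f$name, chrom = f$chrom, offset = f$offset,
        bank_from = 1L, copies = f$copies)
    } else {
      m <- max(f$copies[genotypes])
      if (m == 0) next
      offs <- sort(sample.int(backbone_length - 1L, m))
      chs <- sample.int(n_chrom, m, replace = TRUE)
      for (i in seq_len(m)) {
        cp <- stats::setNames(as.integer(f$copies[genotypes] >= i), genotypes)
        elements[[length(elements) + 1L]] <- list(
          name = f$name, chrom = chs[i], offset = offs[i],
          bank_from = i, copies = cp)
      }
    }
  }

  build_genotype <- function(g, allele_col) {
    seqs <- backbone
    if (nrow(snv) && allele_col == "alleleB") {
      for (ch in unique(snv$chrom)) {
        rows <- snv[snv$chrom == ch, ]
        chars <- strsplit(seqs[ch], "", fixed = TRUE)[[1L]]
        chars[rows$pos] <- rows[[allele_col]]
        seqs[ch] <- paste(chars, collapse = "")
      }
    }
    plc <- data.frame(family = character(0), chrom = integer(0),
                      start = integer(0), end = integer(0),
                      copies = integer(0))
    copy_number <- stats::setNames(integer(length(fam_names)), fam_names)
    for (f in families) copy_number[f$name] <- as.integer(f$copies[[g]])
    for (ch in seq_len(n_chrom)) {
      els <- Filter(function(e) e$chrom == ch, elements)
      if (!length(els)) next
      els <- els[order(vapply(els, `[[`, 1L, "offset"))]
      pieces <- character(0)
      cursor <- 1L   # backbone position of next unwritten base
      shift <- 0L    # bases inserted so far on this chromosome
      for (e in els) {
        ncop <- as.integer(e$copies[[g]])
        pieces <- c(pieces, substring(seqs[ch], cursor, e$offset))
        array_seq <- if (ncop > 0)
          paste(banks[[e$name]][seq(e$bank_from, length.out = ncop)],
                collapse = "") else ""
        alen <- nchar(array_seq)
        if (alen > 0) {
          pieces <- c(pieces, array_seq)
          plc <- rbind(plc, data.frame(
            family = e$name, chrom = ch,
            start = e$offset + shift + 1L,
            end = e$offset + shift + alen, copies = ncop))
        }
        shift <- shift + alen
        cursor <- e$offset + 1L
      }
      pieces <- c(pieces, substring(seqs[ch], cursor, backbone_length))
      seqs[ch] <- paste(pieces, collapse = "")
    }
    structure(
      list(genotype = g, sequences = seqs, family_copy_number = copy_number,
           placements = plc, snv_positions = snv,
           backbone_length = backbone_length),
      class = "genome_truth")
  }

  out <- list(build_genotype(genotypes[1], "alleleA"))
  if (length(genotypes) > 1)
    out <- c(out, lapply(genotypes[-1], build_genotype, allele_col = "alleleB"))
  names(out) <- genotypes
  attr(out, "backbone") <- backbone
  attr(out, "banks") <- banks
  out
}

#' Total length of a simulated genome
#' @param genome a `genome_truth` object.
#' @return total bp across chromosomes.
#' @export
genome_length <- function(genome) sum(nchar(genome$sequences))

#' Simulate uniform shotgun reads
#'
#' Reads are drawn uniformly from both strands of the genome with i.i.d.
#' substitution errors. Total sequenced bases approximate
#' `depth x genome length`. Paired mode emits both mates of fragments of
#' `insert_size` bp, counted together toward the depth.
#'
#' @param genome a `genome_truth` object (or any list with a `sequences`
#'   character vector).
#' @param depth target fold-coverage (> 0).
#' @param read_len read length in bp.
#' @param error_rate per-base substitution probability, in \[0, 0.05\].
#' @param paired emit read pairs from opposite fragment ends.
#' @param insert_size outer fragment length for paired mode.
#' @param seed integer seed.
#' @param sample_id label stored with the read set (defaults to the
#'   genome's genotype).
#' @return a `read_set`: list with `reads` (character vector), `read_len`,
#'   `depth`, `paired`, `sample_id`.
#' @export
simulate_reads <- function(genome, depth, read_len = 125L, error_rate = 0,
                           paired = FALSE, insert_size = 350L, seed = NULL,
                           sample_id = genome$genotype %||% "sample") {
  if (!is.null(seed)) set.seed(seed)
  if (depth <= 0) stop("depth must be > 0")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  seqs <- genome$sequences
  lens <- nchar(seqs)
  span <- if (paired) insert_size else read_len
  if (all(span > lens)) stop("read span exceeds every chromosome length")
  usable <- lens >= span
  seqs <- seqs[usable]; lens <- lens[usable]
  glen <- sum(nchar(genome$sequences))
  n_units <- round(depth * glen / (read_len * (if (paired) 2L else 1L)))
  n_units <- max(1L, n_units)
  chrom_idx <- sample.int(length(seqs), n_units, replace = TRUE,
                          prob = lens - span + 1)
  starts <- floor(runif(n_units) * (lens[chrom_idx] - span + 1)) + 1L
  frag <- substring(seqs[chrom_idx], starts, starts + span - 1L)
  flip <- runif(n_units) < 0.5
  if (paired) {
    frag[flip] <- .cpp_revcomp(frag[flip])
    r1 <- substring(frag, 1L, read_len)
    r2 <- .cpp_revcomp(substring(frag, insert_size - read_len + 1L, insert_size))
    reads <- c(rbind(r1, r2))
  } else {
    frag[flip] <- .cpp_revcomp(frag[flip])
    reads <- frag
  }
  if (error_rate > 0) reads <- .cpp_add_errors(reads, error_rate)
  structure(list(reads = reads, read_len = as.integer(read_len),
                 depth = depth, paired = paired, sample_id = sample_id),
            class = "read_set")
}

#' Build an evenly spaced genetic map
#'
#' @param n_chrom number of chromosomes.
#' @param length_cM chromosome length in centiMorgans.
#' @param spacing_cM marker spacing in centiMorgans.
#' @return `data.frame(chrom, cM, id)` with cM non-decreasing within
#'   chromosome.
#' @export
genetic_map <- function(n_chrom = 10L, length_cM = 140, spacing_cM = 1) {
  pos <- seq(0, length_cM, by = spacing_cM)
  map <- do.call(rbind, lapply(seq_len(n_chrom), function(ch)
    data.frame(chrom = ch, cM = pos)))
  map$id <- sprintf("m%02d_%07.2f", map$chrom, map$cM)
  map
}

#' Simulate a doubled-haploid mapping population
#'
#' Each line is a mosaic of fully homozygous parental blocks per
#' chromosome. Crossovers between adjacent markers occur with the Haldane
#' recombination fraction r = (1 - exp(-2 d / 100)) / 2 for d cM, with no
#' interference. A line's copy number of a clustered repeat family equals
#' that of the parent whose block covers the cluster's map position
#' (nearest marker).
#'
#' @param parentA,parentB `genome_truth` objects for the two parents.
#' @param map genetic map as from [genetic_map()].
#' @param n_lines number of DH lines (>= 2).
#' @param cluster_positions `data.frame(family, chrom, cM)` placing each
#'   segregating family on the map; defaults to no tracked families.
#' @param seed integer seed.
#' @return a `dh_panel`: list with `map`, `genotypes` (lines x markers
#'   matrix of `"A"`/`"B"`), `line_truth` (lines x families copy-number
#'   matrix) and `cluster_positions`.
#' @export
simulate_dh_panel <- function(parentA, parentB, map, n_lines,
                              cluster_positions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_lines < 2) stop("n_lines must be >= 2")
  stopifnot(all(c("chrom", "cM", "id") %in% names(map)))
  n_mark <- nrow(map)
  geno <- matrix(NA_character_, n_lines, n_mark,
                 dimnames = list(sprintf("DH%03d", seq_len(n_lines)), map$id))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    d <- diff(map$cM[idx])
    r <- (1 - exp(-2 * d / 100)) / 2
    m <- length(idx)
    cur <- ifelse(runif(n_lines) < 0.5, "A", "B")
    geno[, idx[1]] <- cur
    if (m > 1) {
      for (j in seq_len(m - 1)) {
        xo <- runif(n_lines) < r[j]
        cur <- ifelse(xo, ifelse(cur == "A", "B", "A"), cur)
        geno[, idx[j + 1]] <- cur
      }
    }
  }
  line_truth <- NULL
  if (!is.null(cluster_positions) && nrow(cluster_positions)) {
    line_truth <- matrix(0, n_lines, nrow(cluster_positions),
                         dimnames = list(rownames(geno),
                                         cluster_positions$family))
    for (i in seq_len(nrow(cluster_positions))) {
      cp <- cluster_positions[i, ]
      idx <- which(map$chrom == cp$chrom)
      near <- idx[which.min(abs(map$cM[idx] - cp$cM))]
      g <- geno[, near]
      cA <- parentA$family_copy_number[[cp$family]]
      cB <- parentB$family_copy_number[[cp$family]]
      line_truth[, i] <- ifelse(g == "A", cA, cB)
    }
  }
  structure(list(map = map, genotypes = geno, line_truth = line_truth,
                 cluster_positions = cluster_positions),
            class = "dh_panel")
}

#' A plasmid-like circular organelle sequence
#'
#' Organelle contamination in the panel simulator is modelled as reads from
#' one circular sequence distinct from the nuclear backbone.
#'
#' @param length sequence length in bp.
#' @return DNA string.
#' @export
organelle_sequence <- function(length = 150000L) random_dna(length)

#' Simulate a grouped multi-line panel
#'
#' Emulates a diversity panel (e.g. teosinte / landrace / improved
#' analogues): each line's genome is built on a shared backbone with
#' repeat-family copy numbers drawn from its group's profile; reads are
#' generated at a depth drawn from `depth_range`, and a per-line fraction
#' of reads comes from a circular organelle-like sequence.
#'
#' @param groups named integer vector, lines per group (order defines the
#'   group ordering used downstream).
#' @param families list of [repeat_family()] objects; the `copies` field of
#'   each spec is ignored in favour of the group profiles.
#' @param profiles nested list `profiles[[group]][[family]] = c(mean, size)`
#'   giving the negative-binomial mean and size of the per-line copy
#'   number (size = Inf gives the rounded mean deterministically).
#' @param backbone_length shared backbone length (bp).
#' @param depth_range fold-coverage interval sampled uniformly per line.
#' @param organelle_fraction_range interval for the per-line fraction of
#'   reads drawn from the organelle sequence.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution rate.
#' @param seed integer seed.
#' @return list with `lines` (named list of `read_set`), `truth`
#'   (data.frame: line, group, depth, organelle_fraction, one column per
#'   family), `groups` (factor per line, ordered as `names(groups)`) and
#'   `organelle` (the contaminant sequence).
#' @export
simulate_panel <- function(groups, families, profiles,
                           backbone_length = 100000L,
                           depth_range = c(5, 30),
                           organelle_fraction_range = c(0, 0.2),
                           read_len = 100L, error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(groups < 1)) stop("every group needs at least one line")
  fam_names <- vapply(families, `[[`, character(1), "name")
  backbone <- random_dna(backbone_length)
  org <- organelle_sequence()
  banks <- list()
  line_ids <- character(0)
  line_group <- character(0)
  for (g in names(groups)) {
    ids <- sprintf("%s_%02d", g, seq_len(groups[[g]]))
    line_ids <- c(line_ids, ids)
    line_group <- c(line_group, rep(g, groups[[g]]))
  }
  truth <- data.frame(line = line_ids, group = line_group,
                      depth = NA_real_, organelle_fraction = NA_real_)
  for (f in fam_names) truth[[f]] <- NA_real_
  lines <- vector("list", length(line_ids))
  names(lines) <- line_ids
  for (i in seq_along(line_ids)) {
    g <- line_group[i]
    copies <- vapply(fam_names, function(f) {
      pr <- profiles[[g]][[f]]
      if (is.null(pr)) stop("no profile for family '", f, "' in group '", g, "'")
      if (!is.finite(pr[2])) round(pr[1])
      else rnbinom(1L, mu = pr[1], size = pr[2])
    }, numeric(1))
    fams_i <- lapply(seq_along(families), function(j) {
      f <- families[[j]]
      f$copies <- stats::setNames(copies[j], "L")
      f
    })
    # shared backbone and copy banks: rebuild each line deterministically
    # from the same unit banks so family k-mers are common across lines
    for (j in seq_along(fams_i)) {
      f <- fams_i[[j]]
      need <- as.integer(copies[j])
      have <- length(banks[[f$name]])
      if (need > have) {
        banks[[f$name]] <- c(banks[[f$name]],
                             .family_copy_bank(f, need - have))
      }
    }
    seqs <- backbone
    fams_sorted <- fams_i[order(vapply(fams_i, `[[`, 1L, "offset"))]
    pieces <- character(0); cursor <- 1L
    for (f in fams_sorted) {
      ncop <- as.integer(f$copies[["L"]])
      pieces <- c(pieces, substring(backbone, cursor, f$offset))
      if (ncop > 0)
        pieces <- c(pieces, paste(banks[[f$name]][seq_len(ncop)], collapse = ""))
      cursor <- f$offset + 1L
    }
    pieces <- c(pieces, substring(backbone, cursor, backbone_length))
    gseq <- paste(pieces, collapse = "")
    depth <- runif(1L, depth_range[1], depth_range[2])
    ofrac <- runif(1L, organelle_fraction_range[1], organelle_fraction_range[2])
    gt <- structure(list(genotype = line_ids[i],
                         sequences = c(chr1 = gseq)), class = "genome_truth")
    rs <- simulate_reads(gt, depth = depth, read_len = read_len,
                         error_rate = error_rate, sample_id = line_ids[i])
    if (ofrac > 0) {
      n_nuc <- length(rs$reads)
      n_org <- round(ofrac / (1 - ofrac) * n_nuc)
      if (n_org > 0) {
        circ <- paste0(org, substring(org, 1L, read_len))
        starts <- sample.int(nchar(org), n_org, replace = TRUE)
        oreads <- substring(circ, starts, starts + read_len - 1L)
        flip <- runif(n_org) < 0.5
        oreads[flip] <- .cpp_revcomp(oreads[flip])
        if (error_rate > 0) oreads <- .cpp_add_errors(oreads, error_rate)
        rs$reads <- c(rs$reads, oreads)
      }
    }
    lines[[i]] <- rs
    truth$depth[i] <- depth
    truth$organelle_fraction[i] <- ofrac
    truth[i, fam_names] <- copies
  }
  list(lines = lines, truth = truth,
       groups = factor(line_group, levels = names(groups)),
       backbone = backbone, organelle = org)
}

#' Simulate allelic transcript counts for a triploid tissue
#'
#' Maternal and paternal counts of each polymorphic k-mer pair are drawn
#' independently as Poisson with mean `dosage x per_copy_rate`, emulating
#' allele-specific rRNA read counts in a triploid endosperm-like tissue
#' (2n maternal : 1n paternal).
#'
#' @param maternal_dosage,paternal_dosage genome dosage of each parent
#'   (>= 0, not both 0).
#' @param per_copy_rate expected counts per genome copy (> 0).
#' @param n_pairs number of polymorphic k-mer pairs.
#' @param seed integer seed.
#' @return `data.frame(pair, maternal, paternal)`.
#' @export
simulate_allelic_counts <- function(maternal_dosage, paternal_dosage,
                                    per_copy_rate, n_pairs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (maternal_dosage < 0 || paternal_dosage < 0) stop("dosages must be >= 0")
  if (maternal_dosage == 0 && paternal_dosage == 0)
    stop("at least one dosage must be positive")
  if (per_copy_rate <= 0) stop("per_copy_rate must be > 0")
  data.frame(
    pair = sprintf("pair%02d", seq_len(n_pairs)),
    maternal = rpois(n_pairs, maternal_dosage * per_copy_rate),
    paternal = rpois(n_pairs, paternal_dosage * per_copy_rate))
}
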