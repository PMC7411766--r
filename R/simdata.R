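#' Simulation configuration
#'
#' Defaults define the study conditions the package is validated against:
#' tissue class mixtures matching the published survey's composition table,
#' per-class read-length profiles (miRNA 20-25 nt, tRNA/rRNA peak 32 nt,
#' TE-piRNA 25-30 nt, mRNA-derived peak 29 nt, unannotated peak 41 nt),
#' piRNA antisense probability 0.77, 1U/10A probabilities 0.9, TE-class
#' mixture 56/35/9 (LTR/non-LTR/DNA), multi-mapping probability 0.828,
#' an mRNA-derived feature-placement distribution with a 60% 3'UTR share
#' and 96% sense orientation.
#'
#' @param seed master seed; every random choice in genome building and
#'   library simulation derives from it.
#' @param ... named overrides of any default component (merged recursively
#'   with [utils::modifyList()]).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chromosomes = c("2R" = 1200000, "2L" = 900000, "3R" = 900000,
                    "3L" = 1000000, "X" = 800000, "UNKN" = 700000),
    n_reads = 100000L,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    # NULL -> use the tissue preset of the simulated library; an explicit
    # mixture here takes precedence over presets
    class_mixture = NULL,
    size_profile = list(
      miRNA = stats::setNames(c(.08, .15, .40, .20, .12, .05), 20:25),
      tRNA_rRNA = local({
        w <- stats::setNames(rep(1, 36), 15:50)
        w["31"] <- 4; w["32"] <- 12; w["33"] <- 4
        w / sum(w)
      }),
      TE_piRNA = stats::setNames(c(.08, .14, .27, .27, .15, .09), 25:30),
      mRNA_derived = stats::setNames(c(.05, .10, .20, .35, .15, .10, .05),
                                     26:32),
      unannotated = stats::setNames(c(.04, .07, .12, .18, .24, .15, .10,
                                      .06, .04), 37:45),
      unmappable = stats::setNames(rep(1 / 21, 21), 20:40)),
    mirna = list(n_hairpins = 12L, loop_len = 150L, hairpin_weights = NULL),
    ncrna = list(n_trna = 12L, trna_len = c(72L, 90L), n_rrna = 18L,
                 rrna_len = c(400L, 2000L), weight_sdlog = 1.5),
    mrna = list(n_genes = 30L, utr5_len = 150L, cds_len = 900L,
                utr3_len = 300L,
                n_true_candidates = 5L, true_weight = 20,
                dominant_frac = 0.45, dominant_len = 29L),
    te = list(catalogue = NULL,   # NULL -> default_te_catalogue()
              copy_divergence = 0L),
    pirna = list(antisense_prob = 0.77, u1_prob = 0.9, a10_prob = 0.9,
                 te_class_mixture = c(LTR = 0.56, nonLTR = 0.35,
                                      DNA = 0.09),
                 multi_prob = 0.828,
                 cluster_shares = NULL),  # named shares of unique mappers
    mrna_derived = list(
      feature_share = c(five_prime_UTR = 0.10, CDS = 0.30,
                        three_prime_UTR = 0.60),
      sense_prob = 0.96)
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  if (!is.null(cfg$class_mixture)) {
    mix <- cfg$class_mixture
    stopifnot(abs(sum(mix) - 1) < 1e-6, all(mix >= 0))
  }
  structure(cfg, class = "sim_config")
}

#' Tissue presets for the class mixture
#'
#' Published per-tissue composition rows (percent of trimmed reads over
#' miRNA, tRNA/rRNA, TE-piRNA, mRNA-derived, unannotated, unmapped).  The
#' unmapped column becomes the simulator's `unmappable` class.
#'
#' Being averages of per-replicate percentages, the printed rows do not
#' sum exactly to 100 (they range up to ~104).  A simulation mixture must
#' be a probability vector, so each row is reconciled by the Chebyshev
#' (minimum maximum deviation) projection onto the simplex: a common
#' constant is subtracted from every class (clipping at zero) until the
#' row sums to 100.  Unlike proportional rescaling, this keeps every
#' class as close as possible to its printed value (at most ~0.8 points
#' away for the ovary row, the farthest-from-100 row).
#'
#' @return named list of class-mixture probability vectors for tissues
#'   FB-Ab, MG, OV and R.
#' @export
tissue_mixtures <- function() {
  rows <- list(
    "FB-Ab" = c(13.43, 49.89, 2.21, 15.56, 18.63, 0.29),
    "MG" = c(22.62, 52.80, 0.94, 11.45, 13.09, 1.35),
    "OV" = c(2.07, 6.24, 34.72, 6.47, 54.33, 0.26),
    "R" = c(3.71, 77.24, 0.76, 9.07, 10.38, 0.45))
  lapply(rows, function(r) {
    adj <- stats::uniroot(function(c) sum(pmax(r - c, 0)) - 100,
                          c(-100, max(r)), tol = 1e-12)$root
    p <- pmax(r - adj, 0) / 100
    stats::setNames(p / sum(p), c("miRNA", "tRNA_rRNA", "TE_piRNA",
                                  "mRNA_derived", "unannotated",
                                  "unmappable"))
  })
}

# default TE catalogue: per class, a few multi-copy families (identical
# copies -> multi-mapping reads) and single-copy families (unique-mapping)
default_te_catalogue <- function() {
  fam <- function(class, n_multi, n_single) {
    rbind(
      if (n_multi > 0)
        data.frame(family = paste0("TE_", class, "_m", seq_len(n_multi)),
                   class = class, copies = 4L, stringsAsFactors = FALSE),
      if (n_single > 0)
        data.frame(family = paste0("TE_", class, "_s", seq_len(n_single)),
                   class = class, copies = 1L, stringsAsFactors = FALSE))
  }
  cat <- rbind(fam("LTR", 2, 4), fam("nonLTR", 2, 3), fam("DNA", 1, 2))
  cat$length <- NA_integer_   # drawn at build time
  cat$cluster <- NA_character_
  cat$bin_chrom <- NA_character_
  cat$bin <- NA_integer_
  rownames(cat) <- NULL
  cat
}

#' Configuration preset for piRNA genome-mapping studies
#'
#' A TE-piRNA-only mixture over a larger genome (~45 distinct 1-Mb bins)
#' with two planted piRNA clusters holding 17.7% and 3.3% of
#' unique-mapping reads and a 40-bin background, plus multi-copy TE
#' families sized so that 82.8% of reads are multi-mapping.
#'
#' @inheritParams sim_config
#' @return a `sim_config`.
#' @export
sim_config_pirna <- function(seed = 1L, ...) {
  chroms <- c("2R" = 12e6, "2L" = 8e6, "3R" = 8e6, "3L" = 7e6,
              "X" = 6e6, "UNKN" = 4e6)
  # enumerate 1-Mb bins; reserve two for the planted clusters
  bins <- do.call(rbind, lapply(names(chroms), function(ch) {
    data.frame(chrom = ch, bin = seq_len(chroms[[ch]] / 1e6) - 1L,
               stringsAsFactors = FALSE)
  }))
  cluster_bins <- data.frame(chrom = c("2R", "3L"), bin = c(7L, 2L),
                             cluster = c("clA", "clB"),
                             stringsAsFactors = FALSE)
  free <- bins[!(paste(bins$chrom, bins$bin) %in%
                   paste(cluster_bins$chrom, cluster_bins$bin)), ]
  bg <- free[seq_len(40L), ]
  classes <- rep(c("LTR", "nonLTR", "DNA"), length.out = 40L)
  cat <- rbind(
    data.frame(family = paste0("TE_", cluster_bins$cluster), class = "LTR",
               copies = 1L, length = NA_integer_,
               cluster = cluster_bins$cluster,
               bin_chrom = cluster_bins$chrom, bin = cluster_bins$bin,
               stringsAsFactors = FALSE),
    data.frame(family = sprintf("TE_bg%02d_%s", seq_len(40L), classes),
               class = classes, copies = 1L, length = NA_integer_,
               cluster = NA_character_, bin_chrom = bg$chrom, bin = bg$bin,
               stringsAsFactors = FALSE),
    data.frame(family = paste0("TE_", rep(c("LTR", "nonLTR", "DNA"),
                                          each = 2), "_m", 1:2),
               class = rep(c("LTR", "nonLTR", "DNA"), each = 2),
               copies = 4L, length = NA_integer_, cluster = NA_character_,
               bin_chrom = NA_character_, bin = NA_integer_,
               stringsAsFactors = FALSE))
  sim_config(
    seed = seed,
    chromosomes = chroms,
    n_reads = 50000L,
    class_mixture = c(miRNA = 0, tRNA_rRNA = 0, TE_piRNA = 1,
                      mRNA_derived = 0, unannotated = 0, unmappable = 0),
    te = list(catalogue = cat, copy_divergence = 0L),
    pirna = list(cluster_shares = c(clA = 0.177, clB = 0.033)),
    ...)
}

random_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# place features of given lengths on one chromosome without overlap;
# constraints: optional [lo, hi) windows per feature.  Rejection sampling.
place_features <- function(chrom_len, lengths, lo = NULL, hi = NULL) {
  n <- length(lengths)
  lo <- lo %||% rep(0, n)
  hi <- hi %||% rep(chrom_len, n)
  placed <- matrix(numeric(0), ncol = 2)
  starts <- numeric(n)
  ord <- order(hi - lo)     # most constrained first
  for (i in ord) {
    L <- lengths[i]
    if (hi[i] - lo[i] < L) stop("placement window smaller than feature")
    ok <- FALSE
    for (try in 1:2000) {
      s <- floor(stats::runif(1, lo[i], hi[i] - L))
      if (!nrow(placed) ||
          all(s + L <= placed[, 1] | s >= placed[, 2])) {
        placed <- rbind(placed, c(s, s + L))
        starts[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("could not place a %d nt feature on a %d nt chromosome (%d features placed)",
                   L, chrom_len, nrow(placed)))
    }
  }
  starts
}

#' Build a synthetic genome bundle
#'
#' Deterministically (for a given config seed) generates chromosome
#' sequences with planted miRNA hairpins, tRNA/rRNA genes, coding gene
#' models with 5'UTR/CDS/3'UTR geometry, and transposable-element copies
#' (identical within a family, so family copy number controls
#' multi-mapping), and returns the genome together with all reference sets
#' and feature coordinates.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_genome`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  chroms <- config$chromosomes

  # --- feature sequences -------------------------------------------------
  # miRNA hairpins: mature 5p arm + loop + reverse complement of the arm
  nh <- config$mirna$n_hairpins
  mat_lens <- as.integer(sample(names(config$size_profile$miRNA), nh,
                                replace = TRUE,
                                prob = config$size_profile$miRNA))
  matures <- vapply(mat_lens, random_dna, character(1))
  names(matures) <- sprintf("sim-miR-%02d", seq_len(nh))
  hairpins <- paste0(matures,
                     vapply(rep(config$mirna$loop_len, nh), random_dna,
                            character(1)),
                     revcomp(matures))
  names(hairpins) <- sprintf("sim-mir-%02d", seq_len(nh))

  # ncRNA genes
  nc <- config$ncrna
  nc_len <- c(sample(nc$trna_len[1]:nc$trna_len[2], nc$n_trna, TRUE),
              sample(nc$rrna_len[1]:nc$rrna_len[2], nc$n_rrna, TRUE))
  nc_type <- rep(c("tRNA", "rRNA"), c(nc$n_trna, nc$n_rrna))
  nc_id <- sprintf("%s-%02d", nc_type,
                   c(seq_len(nc$n_trna), seq_len(nc$n_rrna)))
  nc_seq <- vapply(nc_len, random_dna, character(1))
  nc_weight <- stats::rlnorm(length(nc_id), sdlog = nc$weight_sdlog)

  # coding genes
  mg <- config$mrna
  gene_len <- mg$utr5_len + mg$cds_len + mg$utr3_len
  gene_id <- sprintf("GENE%04d", seq_len(mg$n_genes))
  gene_strand <- sample(c("+", "-"), mg$n_genes, TRUE)
  gene_seq <- vapply(rep(gene_len, mg$n_genes), random_dna, character(1))

  # TE catalogue and copies
  cat <- config$te$catalogue %||% default_te_catalogue()
  cat$length[is.na(cat$length)] <-
    sample(800:1500, sum(is.na(cat$length)), TRUE)
  consensus <- stats::setNames(
    vapply(cat$length, random_dna, character(1)), cat$family)
  copies <- do.call(rbind, lapply(seq_len(nrow(cat)), function(i) {
    data.frame(family = cat$family[i], class = cat$class[i],
               copy = seq_len(cat$copies[i]),
               id = sprintf("%s_c%d", cat$family[i],
                            seq_len(cat$copies[i])),
               cluster = cat$cluster[i],
               bin_chrom = cat$bin_chrom[i], bin = cat$bin[i],
               stringsAsFactors = FALSE)
  }))
  copy_seq <- consensus[copies$family]
  div <- config$te$copy_divergence
  if (div > 0) {
    copy_seq <- vapply(copy_seq, function(s) {
      pos <- sample(nchar(s), div)
      ch <- strsplit(s, "")[[1]]
      ch[pos] <- sample(c("A", "C", "G", "T"), div, TRUE)
      paste(ch, collapse = "")
    }, character(1))
  }
  copies$seq <- unname(copy_seq)
  copies$strand <- sample(c("+", "-"), nrow(copies), TRUE)

  # --- placement ---------------------------------------------------------
  feats <- rbind(
    data.frame(id = names(hairpins), type = "hairpin",
               length = nchar(hairpins), strand = "+",
               bin_chrom = NA_character_, bin = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(id = nc_id, type = nc_type, length = nc_len, strand = "+",
               bin_chrom = NA_character_, bin = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(id = gene_id, type = "gene", length = gene_len,
               strand = gene_strand, bin_chrom = NA_character_,
               bin = NA_integer_, stringsAsFactors = FALSE),
    data.frame(id = copies$id, type = "te_copy", length = nchar(copies$seq),
               strand = copies$strand, bin_chrom = copies$bin_chrom,
               bin = copies$bin, stringsAsFactors = FALSE))
  seqs <- c(hairpins, stats::setNames(nc_seq, nc_id),
            stats::setNames(gene_seq, gene_id),
            stats::setNames(copies$seq, copies$id))
  # minus-strand features are planted as the reverse complement of their
  # feature-orientation sequence
  planted <- ifelse(feats$strand == "-", revcomp(seqs[feats$id]),
                    seqs[feats$id])
  feats$chrom <- ifelse(!is.na(feats$bin_chrom), feats$bin_chrom,
                        sample(names(chroms), nrow(feats), TRUE,
                               prob = chroms / sum(chroms)))
  feats$start <- NA_real_
  for (ch in names(chroms)) {
    sel <- feats$chrom == ch
    if (!any(sel)) next
    lo <- ifelse(is.na(feats$bin[sel]), 0, feats$bin[sel] * 1e6)
    hi <- ifelse(is.na(feats$bin[sel]), chroms[[ch]],
                 pmin((feats$bin[sel] + 1) * 1e6, chroms[[ch]]))
    feats$start[sel] <- place_features(chroms[[ch]], feats$length[sel],
                                       lo, hi)
  }
  feats$end <- feats$start + feats$length

  # --- assemble chromosome sequences and intergenic gaps -----------------
  genome <- character(0)
  intergenic <- list()
  for (ch in names(chroms)) {
    f <- feats[feats$chrom == ch, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(f$start, f$end)), chroms[[ch]])
    gap_start <- bounds[seq(1, length(bounds), by = 2)]
    gap_end <- bounds[seq(2, length(bounds), by = 2)]
    gaps <- vapply(gap_end - gap_start, random_dna, character(1))
    pieces <- character(2 * nrow(f) + 1)
    pieces[seq(1, length(pieces), by = 2)] <- gaps
    if (nrow(f)) {
      pieces[seq(2, length(pieces), by = 2)] <- planted[
        match(f$id, feats$id)]
    }
    genome[ch] <- paste(pieces, collapse = "")
    keep <- gap_end - gap_start >= 60
    intergenic[[ch]] <- data.frame(chrom = ch, start = gap_start[keep],
                                   end = gap_end[keep],
                                   stringsAsFactors = FALSE)
  }
  intergenic <- do.call(rbind, intergenic)
  rownames(intergenic) <- NULL

  # --- gene models data.frame (GFF-compatible) ---------------------------
  gidx <- match(gene_id, feats$id)
  gs <- feats$start[gidx]; gchrom <- feats$chrom[gidx]
  u5 <- mg$utr5_len; cd <- mg$cds_len; u3 <- mg$utr3_len
  plus <- gene_strand == "+"
  seg <- function(off1, off2) {
    # transcript segment [off1, off2) in gene-orientation coordinates
    start <- ifelse(plus, gs + off1, gs + gene_len - off2)
    data.frame(chrom = gchrom, start = start, end = start + (off2 - off1),
               strand = gene_strand, stringsAsFactors = FALSE)
  }
  m5 <- seg(0, u5); mc <- seg(u5, u5 + cd); m3 <- seg(u5 + cd, gene_len)
  models <- rbind(
    data.frame(chrom = gchrom, start = gs, end = gs + gene_len,
               strand = gene_strand, type = "mRNA", id = gene_id,
               parent = NA_character_, stringsAsFactors = FALSE),
    data.frame(m5, type = "five_prime_UTR",
               id = paste0(gene_id, ".utr5"), parent = gene_id),
    data.frame(mc, type = "CDS", id = paste0(gene_id, ".cds"),
               parent = gene_id),
    data.frame(m3, type = "three_prime_UTR",
               id = paste0(gene_id, ".utr3"), parent = gene_id),
    data.frame(chrom = feats$chrom[match(nc_id, feats$id)],
               start = feats$start[match(nc_id, feats$id)],
               end = feats$end[match(nc_id, feats$id)],
               strand = "+", type = nc_type, id = nc_id,
               parent = NA_character_, stringsAsFactors = FALSE))
  class(models) <- c("gene_models", "data.frame")

  copies$chrom <- feats$chrom[match(copies$id, feats$id)]
  copies$start <- feats$start[match(copies$id, feats$id)]
  copies$end <- feats$end[match(copies$id, feats$id)]
  copies$strand <- feats$strand[match(copies$id, feats$id)]

  true_genes <- if (mg$n_true_candidates > 0) {
    gene_id[seq_len(min(mg$n_true_candidates, length(gene_id)))]
  } else character(0)

  structure(list(
    config = config, genome = genome, features = feats,
    matures = matures, hairpins = hairpins,
    mirna_loci = data.frame(id = names(hairpins),
                            chrom = feats$chrom[match(names(hairpins),
                                                      feats$id)],
                            start = feats$start[match(names(hairpins),
                                                      feats$id)],
                            stringsAsFactors = FALSE),
    ncrna = data.frame(id = nc_id, type = nc_type, length = nc_len,
                       weight = nc_weight, seq = nc_seq,
                       stringsAsFactors = FALSE),
    genes = data.frame(id = gene_id, chrom = gchrom, start = gs,
                       end = gs + gene_len, strand = gene_strand,
                       seq = gene_seq, stringsAsFactors = FALSE),
    true_genes = true_genes,
    te_catalogue = cat, te_consensus = consensus, te_copies = copies,
    models = models, intergenic = intergenic), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosome(s), %.1f Mb; %d hairpins, %d ncRNA genes, %d coding genes, %d TE copies (%d families)\n",
              length(x$genome), sum(nchar(x$genome)) / 1e6,
              length(x$hairpins), nrow(x$ncrna), nrow(x$genes),
              nrow(x$te_copies), nrow(x$te_catalogue)))
  invisible(x)
}

#' Reference sets of a genome bundle, as the cascade expects them
#'
#' @param bundle a `sim_genome`.
#' @return list with components `genome`, `mirna`, `te` (reference sets)
#'   and `models` (gene models).
#' @export
sim_references <- function(bundle) {
  list(genome = reference_set(bundle$genome, "genome"),
       mirna = reference_set(bundle$hairpins, "miRNA"),
       te = reference_set(bundle$te_consensus, "TE",
                          meta = data.frame(id = bundle$te_catalogue$family,
                                            class = bundle$te_catalogue$class,
                                            stringsAsFactors = FALSE)),
       models = bundle$models)
}

# sample read lengths from a named-profile pmf, truncated to max_len
sample_lengths <- function(profile, n, max_len = Inf) {
  lens <- as.integer(names(profile))
  ok <- lens <= max_len
  sample(lens[ok], n, replace = TRUE, prob = profile[ok])
}

#' Simulate one small RNA-Seq library with ground truth
#'
#' Draws reads from the genome bundle according to the configured class
#' mixture and per-class structure.  Every read of the mapped classes is an
#' exact substring (or reverse-complement substring) of the genome; piRNA
#' 1U/10A biases are imposed by offset selection, not base substitution,
#' so the cascade can recover the configured mixture without mismatches.
#'
#' @param bundle a `sim_genome` from [build_genome()].
#' @param tissue tissue label; when it names a [tissue_mixtures()] preset
#'   and `mixture` is NULL, that preset is used.
#' @param replicate replicate number (enters the derived seed).
#' @param seed optional override of the config master seed for this
#'   library.
#' @param n_reads optional override of the configured read count.
#' @param mixture optional class-mixture override.
#' @return object of class `sim_library`: list with `records` (id, insert,
#'   sequence with adapter appended), `truth` (per-read class, source,
#'   genomic strand, chrom, offset, orientation), `tissue`, `replicate`.
#' @export
simulate_library <- function(bundle, tissue = "OV", replicate = 1L,
                             seed = NULL, n_reads = NULL, mixture = NULL) {
  stopifnot(inherits(bundle, "sim_genome"))
  config <- bundle$config
  seed <- seed %||% config$seed
  set.seed(derive_seed(seed, "library", tissue, replicate))
  n <- as.integer(n_reads %||% config$n_reads)
  presets <- tissue_mixtures()
  mixture <- mixture %||% config$class_mixture %||%
    (if (tissue %in% names(presets)) presets[[tissue]] else
       stop("no class mixture: configure one or use a preset tissue"))
  stopifnot(abs(sum(mixture) - 1) < 1e-6)

  classes <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  out <- vector("list", length(unique(classes)))
  names(out) <- unique(classes)
  for (cl in unique(classes)) {
    m <- sum(classes == cl)
    out[[cl]] <- switch(
      cl,
      miRNA = sim_reads_mirna(bundle, m),
      tRNA_rRNA = sim_reads_ncrna(bundle, m),
      TE_piRNA = sim_reads_te(bundle, m),
      mRNA_derived = sim_reads_mrna(bundle, m),
      unannotated = sim_reads_unannotated(bundle, m),
      unmappable = sim_reads_unmappable(bundle, m),
      stop("unknown class in mixture: ", cl))
    out[[cl]]$class <- cl
    if (is.null(out[[cl]]$feature)) out[[cl]]$feature <- NA_character_
  }
  truth <- do.call(rbind, out)
  truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
  truth$tissue <- tissue
  truth$replicate <- as.integer(replicate)
  truth$read_id <- sprintf("read_%07d", seq_len(nrow(truth)))
  rownames(truth) <- NULL
  records <- data.frame(
    id = truth$read_id, insert = truth$sequence,
    sequence = paste0(truth$sequence, config$adapter),
    stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, tissue = tissue,
                 replicate = as.integer(replicate),
                 library_id = sprintf("%s_rep%d", tissue, replicate)),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %s: %d reads\n", x$library_id, nrow(x$truth)))
  print(round(100 * table(x$truth$class) / nrow(x$truth), 2))
  invisible(x)
}

#' Collapse a simulated library into an `srna_library`
#'
#' Bypasses the FASTQ round trip (which [write_fastq()] + [ingest_fastq()]
#' perform identically) for in-memory pipelines.
#'
#' @param sim a `sim_library`.
#' @return an [srna_library()].
#' @export
as_srna_library <- function(sim) {
  srna_library(sim$library_id, collapse_reads(sim$truth$sequence),
               tissue = sim$tissue, replicate = sim$replicate,
               total_raw = nrow(sim$truth))
}

empty_truth <- function() {
  data.frame(sequence = character(), source = character(),
             strand = character(), chrom = character(), offset = integer(),
             orientation = character(), stringsAsFactors = FALSE)
}

sim_reads_mirna <- function(bundle, n) {
  w <- bundle$config$mirna$hairpin_weights %||%
    rep(1, length(bundle$matures))
  idx <- sample(length(bundle$matures), n, replace = TRUE, prob = w)
  loci <- bundle$mirna_loci
  data.frame(sequence = unname(bundle$matures[idx]),
             source = names(bundle$matures)[idx], strand = "+",
             chrom = loci$chrom[idx], offset = as.integer(loci$start[idx]),
             orientation = "sense", stringsAsFactors = FALSE)
}

sim_reads_ncrna <- function(bundle, n) {
  ncr <- bundle$ncrna
  gi <- sample(nrow(ncr), n, replace = TRUE, prob = ncr$weight)
  lens <- sample_lengths(bundle$config$size_profile$tRNA_rRNA, n)
  lens <- pmin(lens, ncr$length[gi])
  off <- floor(stats::runif(n) * (ncr$length[gi] - lens + 1))
  seqs <- substring(ncr$seq[gi], off + 1, off + lens)
  f <- bundle$features
  fs <- f$start[match(ncr$id[gi], f$id)]
  data.frame(sequence = seqs, source = ncr$id[gi], strand = "+",
             chrom = f$chrom[match(ncr$id[gi], f$id)],
             offset = as.integer(fs + off), orientation = "sense",
             stringsAsFactors = FALSE)
}

# choose TE source copy for each read honouring multi-mapping probability,
# cluster shares and TE-class mixture
pick_te_copies <- function(bundle, n) {
  cfg <- bundle$config$pirna
  cat <- bundle$te_catalogue
  multi_fams <- cat$family[cat$copies > 1]
  single_fams <- cat$family[cat$copies == 1]
  if (!length(multi_fams)) multi_fams <- single_fams
  if (!length(single_fams)) single_fams <- multi_fams
  is_multi <- stats::runif(n) < cfg$multi_prob

  pick_by_class <- function(fams, m) {
    if (m == 0) return(character(0))
    cls <- cat$class[match(fams, cat$family)]
    avail <- intersect(names(cfg$te_class_mixture), cls)
    p <- cfg$te_class_mixture[avail] / sum(cfg$te_class_mixture[avail])
    want <- sample(avail, m, replace = TRUE, prob = p)
    vapply(want, function(w) {
      f <- fams[cls == w]
      f[sample.int(length(f), 1)]
    }, character(1), USE.NAMES = FALSE)
  }

  fam <- character(n)
  fam[is_multi] <- pick_by_class(multi_fams, sum(is_multi))
  shares <- cfg$cluster_shares
  if (is.null(shares) || !any(!is.na(cat$cluster))) {
    fam[!is_multi] <- pick_by_class(single_fams, sum(!is_multi))
  } else {
    # planted-cluster path: unique-mapping reads choose a cluster (or the
    # background) first, then a family within it
    nu <- sum(!is_multi)
    groups <- c(names(shares), "background")
    gp <- c(shares, background = 1 - sum(shares))
    g <- sample(groups, nu, replace = TRUE, prob = gp)
    fam_u <- character(nu)
    for (grp in unique(g)) {
      fams <- if (grp == "background") {
        single_fams[is.na(cat$cluster[match(single_fams, cat$family)])]
      } else {
        cat$family[!is.na(cat$cluster) & cat$cluster == grp]
      }
      sel <- g == grp
      fam_u[sel] <- if (length(fams) == 1) fams else
        fams[sample.int(length(fams), sum(sel), replace = TRUE)]
    }
    fam[!is_multi] <- fam_u
  }
  # uniform copy within family, vectorized per family
  copies <- bundle$te_copies
  out <- character(n)
  for (f in unique(fam)) {
    ids <- copies$id[copies$family == f]
    sel <- fam == f
    out[sel] <- ids[sample.int(length(ids), sum(sel), replace = TRUE)]
  }
  out
}

sim_reads_te <- function(bundle, n) {
  cfg <- bundle$config$pirna
  copies <- bundle$te_copies
  copy_id <- pick_te_copies(bundle, n)
  antisense <- stats::runif(n) < cfg$antisense_prob
  lens <- sample_lengths(bundle$config$size_profile$TE_piRNA, n)
  want1 <- stats::runif(n) < cfg$u1_prob
  want10 <- stats::runif(n) < cfg$a10_prob   # applied to sense reads only

  ci <- match(copy_id, copies$id)
  seqs <- character(n)
  offs <- integer(n)
  key <- paste(ci, antisense, lens, want1, ifelse(antisense, NA, want10))
  for (k in unique(key)) {
    sel <- which(key == k)
    i <- ci[sel[1]]; anti <- antisense[sel[1]]; L <- lens[sel[1]]
    w1 <- want1[sel[1]]; w10 <- want10[sel[1]]
    s <- copies$seq[i]
    nc <- nchar(s)
    if (L > nc) { L <- nc; lens[sel] <- L }
    ch <- strsplit(s, "")[[1]]
    smax <- nc - L            # offsets 0..smax
    if (anti) {
      # read position 1 is the complement of the copy base at s + L
      ok <- (ch[(1:(smax + 1)) + L - 1] == "A") == w1
    } else {
      ok <- (ch[1:(smax + 1)] == "T") == w1
      if (L >= 10) ok <- ok & ((ch[(1:(smax + 1)) + 9] == "A") == w10)
    }
    cand <- which(ok) - 1L
    if (!length(cand)) cand <- 0:smax   # relax when the stratum is empty
    o <- cand[sample.int(length(cand), length(sel), replace = TRUE)]
    r <- substring(s, o + 1, o + L)
    if (anti) r <- revcomp(r)
    seqs[sel] <- r
    offs[sel] <- o
  }
  # genomic coordinates: copies are planted at (chrom, start) with a
  # genomic strand; consensus offset maps accordingly
  cstrand <- copies$strand[ci]
  clen <- nchar(copies$seq)[ci]
  gstart <- ifelse(cstrand == "+", copies$start[ci] + offs,
                   copies$start[ci] + clen - offs - lens)
  read_gstrand <- ifelse((cstrand == "+") != antisense, "+", "-")
  data.frame(sequence = seqs, source = copy_id, strand = read_gstrand,
             chrom = copies$chrom[ci], offset = as.integer(gstart),
             orientation = ifelse(antisense, "antisense", "sense"),
             stringsAsFactors = FALSE)
}

sim_reads_mrna <- function(bundle, n) {
  cfg <- bundle$config$mrna_derived
  mg <- bundle$config$mrna
  genes <- bundle$genes
  w <- ifelse(genes$id %in% bundle$true_genes, mg$true_weight, 1)
  gi <- sample(nrow(genes), n, replace = TRUE, prob = w)

  feature <- sample(names(cfg$feature_share), n, replace = TRUE,
                    prob = cfg$feature_share)
  sense <- stats::runif(n) < cfg$sense_prob
  lens <- sample_lengths(bundle$config$size_profile$mRNA_derived, n)
  # dominant planted fragment: drawn from within the 3'UTR-sense stratum
  # of the true candidate genes, so the configured feature and orientation
  # distributions are preserved
  dominant <- genes$id[gi] %in% bundle$true_genes &
    feature == "three_prime_UTR" & sense &
    stats::runif(n) < mg$dominant_frac
  # transcript-coordinate feature windows
  f_off <- c(five_prime_UTR = 0, CDS = mg$utr5_len,
             three_prime_UTR = mg$utr5_len + mg$cds_len)
  f_len <- c(five_prime_UTR = mg$utr5_len, CDS = mg$cds_len,
             three_prime_UTR = mg$utr3_len)
  lens <- pmin(lens, f_len[feature])
  toff <- f_off[feature] +
    floor(stats::runif(n) * (f_len[feature] - lens + 1))
  # the planted dominant fragment: fixed 3'UTR offset and length
  toff[dominant] <- mg$utr5_len + mg$cds_len + 11L
  lens[dominant] <- mg$dominant_len

  tseq <- substring(genes$seq[gi], toff + 1, toff + lens)
  seqs <- ifelse(sense, tseq, revcomp(tseq))
  gene_len <- mg$utr5_len + mg$cds_len + mg$utr3_len
  plus <- genes$strand[gi] == "+"
  gstart <- ifelse(plus, genes$start[gi] + toff,
                   genes$start[gi] + gene_len - toff - lens)
  read_gstrand <- ifelse(plus == sense, "+", "-")
  data.frame(sequence = seqs, source = genes$id[gi],
             strand = read_gstrand, chrom = genes$chrom[gi],
             offset = as.integer(gstart),
             orientation = ifelse(sense, "sense", "antisense"),
             feature = unname(feature), stringsAsFactors = FALSE)
}

sim_reads_unannotated <- function(bundle, n) {
  ig <- bundle$intergenic
  lens <- sample_lengths(bundle$config$size_profile$unannotated, n)
  w <- ig$end - ig$start
  ii <- sample(nrow(ig), n, replace = TRUE, prob = w)
  lens <- pmin(lens, w[ii])
  off <- ig$start[ii] + floor(stats::runif(n) * (w[ii] - lens + 1))
  gseq <- substring(bundle$genome[ig$chrom[ii]], off + 1, off + lens)
  minus <- stats::runif(n) < 0.5
  data.frame(sequence = ifelse(minus, revcomp(gseq), gseq),
             source = "intergenic", strand = ifelse(minus, "-", "+"),
             chrom = ig$chrom[ii], offset = as.integer(off),
             orientation = NA_character_, stringsAsFactors = FALSE)
}

sim_reads_unmappable <- function(bundle, n) {
  lens <- sample_lengths(bundle$config$size_profile$unmappable, n)
  seqs <- vapply(lens, random_dna, character(1))
  # verify absence from the genome; resample any collision
  for (round in 1:3) {
    mp <- map_reads(seqs, reference_set(bundle$genome, "genome"), 0L)
    bad <- which(mp$n_hits > 0)
    if (!length(bad)) break
    seqs[bad] <- vapply(lens[bad], random_dna, character(1))
  }
  data.frame(sequence = seqs, source = "random", strand = NA_character_,
             chrom = NA_character_, offset = NA_integer_,
             orientation = NA_character_, stringsAsFactors = FALSE)
}

#' Write a genome bundle to standard-format files
#'
#' @param bundle a `sim_genome`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly; writes genome.fa, te.fa (headers carry
#'   `class=` tags), mirna_mature.fa, mirna_hairpin.fa and models.gff3.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_fasta(bundle$genome, file.path(dir, "genome.fa"))
  te <- bundle$te_consensus
  names(te) <- sprintf("%s class=%s", bundle$te_catalogue$family,
                       bundle$te_catalogue$class)
  write_reference_fasta(te, file.path(dir, "te.fa"))
  write_reference_fasta(bundle$matures, file.path(dir, "mirna_mature.fa"))
  write_reference_fasta(bundle$hairpins, file.path(dir, "mirna_hairpin.fa"))
  m <- bundle$models
  gr <- GenomicRanges::GRanges(
    m$chrom, IRanges::IRanges(m$start + 1L, m$end), strand = m$strand,
    type = m$type, ID = m$id,
    Parent = ifelse(is.na(m$parent), NA, m$parent),
    phase = ifelse(m$type == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, file.path(dir, "models.gff3"), format = "gff3")
  invisible(dir)
}
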