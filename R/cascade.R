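#' Extract genomic feature sequences
#'
#' @param genome named character vector (or genome `reference_set`).
#' @param models a `gene_models` data.frame.
#' @param types feature types to extract (rows of `models`).
#' @return named character vector of strand-aware feature sequences (minus
#'   strand features are reverse-complemented into feature orientation).
#' @export
feature_sequences <- function(genome, models, types) {
  if (inherits(genome, "reference_set")) genome <- genome$seqs
  m <- models[models$type %in% types, , drop = FALSE]
  if (nrow(m) == 0) return(stats::setNames(character(0), character(0)))
  seqs <- substring(genome[m$chrom], m$start + 1, m$end)
  seqs <- ifelse(m$strand == "-", revcomp(seqs), seqs)
  stats::setNames(seqs, m$id)
}

#' Sequential-depletion classification of a small RNA library
#'
#' Implements the ordered annotation cascade: (1) reads failing to map to
#' the genome are labeled unmapped; (2) reads matching the miRNA reference
#' are labeled miRNA and depleted; (3) remaining reads matching tRNA/rRNA
#' gene models are labeled tRNA_rRNA; (4) remaining reads matching the TE
#' consensus library within the TE mismatch budget (default 2) are labeled
#' TE_piRNA; (5) remaining reads matching coding gene models are labeled
#' mRNA_derived; (6) the rest are unannotated.  Earlier stages always win.
#'
#' @param library an [srna_library()].
#' @param references list with components `genome` (reference_set),
#'   `mirna` (reference_set of mature/hairpin sequences), `te`
#'   (reference_set with class metadata) and `models` (gene_models with
#'   tRNA/rRNA and coding features), as produced by [sim_references()].
#' @param params list of per-stage mismatch budgets:
#'   `genome_mm`, `mirna_mm`, `ncrna_mm`, `mrna_mm` (default 0) and
#'   `te_mm` (default 2); `stage_order` reorders the annotation stages
#'   2-5 (default `c("miRNA", "tRNA_rRNA", "TE_piRNA", "mRNA_derived")`,
#'   the shipped cascade order — classification is order-sensitive for
#'   reads matching several references).
#' @return object of class `srna_classification`; see Details.
#' @details The result carries per-collapsed-read labels (`reads$label`),
#'   count-weighted composition percentages over the six labels
#'   (`composition`), per-class size histograms (`size_histograms`), the
#'   stage-by-stage depletion log (`depletion_log`), and per-stage hit
#'   tables used by the piRNA and mRNA-derived analyses: `genome_hits`
#'   (all genome placements), `te_hits` (best TE hit per TE_piRNA read
#'   with class and strand), `mrna_hits` (best coding-gene hit per
#'   mRNA_derived read with genomic coordinates, orientation and feature
#'   assignment) and `ncrna_hits` (tRNA/rRNA biotype attribution).
#' @export
classify <- function(library, references, params = list()) {
  stopifnot(inherits(library, "srna_library"))
  for (need in c("genome", "mirna", "te", "models")) {
    if (is.null(references[[need]])) {
      stop("missing reference set for stage: ", need)
    }
  }
  p <- utils::modifyList(list(genome_mm = 0L, mirna_mm = 0L, ncrna_mm = 0L,
                              te_mm = 2L, mrna_mm = 0L,
                              stage_order = c("miRNA", "tRNA_rRNA",
                                              "TE_piRNA", "mRNA_derived")),
                         params)
  stopifnot(setequal(p$stage_order, c("miRNA", "tRNA_rRNA", "TE_piRNA",
                                      "mRNA_derived")))
  reads <- library$reads
  n <- nrow(reads)
  label <- rep(NA_character_, n)
  log_rows <- list()
  note <- function(stage, assigned_idx, remaining_idx) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      stage = stage,
      reads_in = sum(reads$count[c(assigned_idx, remaining_idx)]),
      assigned = sum(reads$count[assigned_idx]),
      remaining = sum(reads$count[remaining_idx]),
      stringsAsFactors = FALSE)
  }

  # stage 1: genome
  gmap <- map_reads(reads$sequence, references$genome, p$genome_mm, "all")
  mapped <- which(gmap$n_hits > 0)
  label[gmap$n_hits == 0] <- "unmapped"
  note("genome", which(gmap$n_hits == 0), mapped)
  remaining <- mapped
  mirna_hits <- nc_hits <- te_hits <- mrna_hits <- NULL

  stage_mirna <- function(remaining) {
    mi <- map_reads(reads$sequence[remaining], references$mirna,
                    p$mirna_mm, "best")
    mh <- best_hit(mi)
    if (nrow(mh)) mh$read <- remaining[mh$read]
    mirna_hits <<- mh
    mi$n_hits > 0
  }

  stage_ncrna <- function(remaining) {
    nc_seqs <- feature_sequences(references$genome, references$models,
                                 c("tRNA", "rRNA"))
    if (!length(nc_seqs)) return(rep(FALSE, length(remaining)))
    ncm <- map_reads(reads$sequence[remaining], nc_seqs, p$ncrna_mm, "all")
    if (nrow(ncm$hits)) {
      # biotype attribution: a read hitting both biotypes counts as tRNA
      types <- references$models$type[match(ncm$hits$ref,
                                            references$models$id)]
      is_t <- tapply(types == "tRNA", ncm$hits$read, any)
      h <- data.frame(
        read = remaining[as.integer(names(is_t))],
        biotype = ifelse(is_t, "tRNA", "rRNA"), stringsAsFactors = FALSE)
      gene <- best_hit(ncm)
      h$gene <- gene$ref[match(h$read, remaining[gene$read])]
      nc_hits <<- h
    }
    ncm$n_hits > 0
  }

  stage_te <- function(remaining) {
    tem <- map_reads(reads$sequence[remaining], references$te, p$te_mm,
                     "best")
    h <- best_hit(tem)
    if (nrow(h)) {
      h$read <- remaining[h$read]
      h$class <- references$te$meta$class[
        match(h$ref, references$te$meta$id)]
      h$count <- reads$count[h$read]
      h$sequence <- reads$sequence[h$read]
      h$length <- reads$length[h$read]
      te_hits <<- h
    }
    tem$n_hits > 0
  }

  stage_mrna <- function(remaining) {
    gene_models <- references$models[references$models$type == "mRNA", ,
                                     drop = FALSE]
    gene_seqs <- feature_sequences(references$genome, references$models,
                                   "mRNA")
    if (!length(gene_seqs)) return(rep(FALSE, length(remaining)))
    mrm <- map_reads(reads$sequence[remaining], gene_seqs, p$mrna_mm,
                     "best")
    mh <- best_hit(mrm)
    if (nrow(mh)) {
      mh$read <- remaining[mh$read]
      gi <- match(mh$ref, gene_models$id)
      L <- reads$length[mh$read]
      plus <- gene_models$strand[gi] == "+"
      # transcript-space hit -> genomic interval and strand
      gstart <- ifelse(plus, gene_models$start[gi] + mh$start,
                       gene_models$end[gi] - mh$start - L)
      h <- data.frame(
        read = mh$read, gene = mh$ref, chrom = gene_models$chrom[gi],
        gstart = gstart, gend = gstart + L,
        strand = ifelse(plus == (mh$strand == "+"), "+", "-"),
        orientation = ifelse(mh$strand == "+", "sense", "antisense"),
        count = reads$count[mh$read], sequence = reads$sequence[mh$read],
        length = L, stringsAsFactors = FALSE)
      h$feature <- assign_feature(h$gstart, h$gend, h$strand, h$gene,
                                  references$models)$counted_as
      mrna_hits <<- h
    }
    mrm$n_hits > 0
  }

  stages <- list(miRNA = stage_mirna, tRNA_rRNA = stage_ncrna,
                 TE_piRNA = stage_te, mRNA_derived = stage_mrna)
  for (st in p$stage_order) {
    hit <- stages[[st]](remaining)
    label[remaining[hit]] <- st
    note(st, remaining[hit], remaining[!hit])
    remaining <- remaining[!hit]
  }

  label[remaining] <- "unannotated"
  note("unannotated", remaining, integer(0))

  reads$label <- label
  lv <- c("miRNA", "tRNA_rRNA", "TE_piRNA", "mRNA_derived", "unannotated",
          "unmapped")
  comp <- vapply(lv, function(l) sum(reads$count[label == l]), numeric(1))
  composition <- 100 * comp / sum(reads$count)
  hist <- table(factor(label, lv)[rep(seq_len(n), reads$count)],
                factor(rep(reads$length, reads$count), levels = 15:50))
  structure(list(
    library_id = library$library_id, tissue = library$tissue,
    replicate = library$replicate, reads = reads,
    composition = composition, size_histograms = unclass(hist),
    depletion_log = do.call(rbind, log_rows),
    genome_hits = gmap, mirna_hits = mirna_hits, ncrna_hits = nc_hits,
    te_hits = te_hits, mrna_hits = mrna_hits,
    genome_mapped = sum(reads$count[label != "unmapped"]),
    params = p), class = "srna_classification")
}

#' @export
print.srna_classification <- function(x, ...) {
  cat(sprintf("<srna_classification> %s (%s rep %d), %d reads\n",
              x$library_id, x$tissue, x$replicate, sum(x$reads$count)))
  print(round(x$composition, 2))
  invisible(x)
}

#' @export
summary.srna_classification <- function(object, ...) {
  cat("Depletion cascade:\n")
  print(object$depletion_log, row.names = FALSE)
  cat("\nComposition (% of trimmed reads):\n")
  print(round(object$composition, 2))
  invisible(object)
}

#' Discover miRNA homolog candidates among unannotated reads
#'
#' Filters reads to the size window (default 20-25 nt) and the read-count
#' floor (default strictly more than 200 reads per unique sequence), then
#' scores each survivor against a database of mature miRNA sequences by
#' the best ungapped offset alignment (the shorter sequence fully
#' contained in the longer, same strand): homology score = 100 * (1 -
#' mismatches / alignment length).  Candidates require score at or above
#' `min_score` and at most `max_mismatches` mismatches.
#'
#' @param reads collapsed-read data.frame (`sequence`, `count`); typically
#'   the unannotated reads pooled across libraries.
#' @param mirna_db named character vector of mature miRNA sequences.
#' @param min_reads count floor; candidates must exceed it (strict).
#' @param size_range inclusive length window.
#' @param max_mismatches maximum mismatches in the best alignment.
#' @param min_score minimum homology score (percent identity).
#' @return data.frame `sequence`, `length`, `total_reads`, `best_match`,
#'   `mismatches`, `homology_score`, ordered by decreasing total reads.
#' @export
discover_mirna_homologs <- function(reads, mirna_db, min_reads = 200L,
                                    size_range = c(20L, 25L),
                                    max_mismatches = 3L, min_score = 80) {
  if (length(mirna_db) == 0) stop("empty miRNA database")
  mirna_db <- toupper(rna_to_dna(mirna_db))
  cand <- reads[reads$length >= size_range[1] &
                  reads$length <= size_range[2] &
                  reads$count > min_reads, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(sequence = character(), length = integer(),
                      total_reads = integer(), best_match = character(),
                      mismatches = integer(), homology_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  score_one <- function(seq) {
    best_mm <- NA_integer_; best_db <- NA_character_; best_len <- NA_integer_
    for (j in seq_along(mirna_db)) {
      db <- mirna_db[j]
      if (nchar(seq) <= nchar(db)) {
        m <- map_reads(seq, stats::setNames(db, "db"), max_mismatches,
                       "best")
      } else {
        m <- map_reads(db, stats::setNames(seq, "q"), max_mismatches,
                       "best")
      }
      h <- m$hits[m$hits$strand == "+", , drop = FALSE]
      if (nrow(h) && (is.na(best_mm) || h$mismatches[1] < best_mm)) {
        best_mm <- h$mismatches[1]
        best_db <- names(mirna_db)[j]
        best_len <- min(nchar(seq), nchar(db))
      }
    }
    list(mm = best_mm, db = best_db,
         score = if (is.na(best_mm)) NA_real_ else
           100 * (1 - best_mm / best_len))
  }
  sc <- lapply(cand$sequence, score_one)
  cand$best_match <- vapply(sc, `[[`, character(1), "db")
  cand$mismatches <- vapply(sc, `[[`, integer(1), "mm")
  cand$homology_score <- vapply(sc, `[[`, numeric(1), "score")
  out <- cand[!is.na(cand$homology_score) &
                cand$homology_score >= min_score, , drop = FALSE]
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  data.frame(sequence = out$sequence, length = out$length,
             total_reads = out$count, best_match = out$best_match,
             mismatches = out$mismatches,
             homology_score = out$homology_score,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantify reads mapping within a genomic window
#'
#' Counts (count-weighted, both strands, exact match) the reads of each
#' library that map fully inside the window, and converts to RPM.
#'
#' @param libraries list of [srna_library()] objects.
#' @param genome genome `reference_set` or named character vector.
#' @param chrom,start,end window coordinates (0-based half-open).
#' @param denominators named numeric vector of per-library RPM
#'   denominators (genome-mapped totals); computed by mapping each
#'   library to the genome when omitted.
#' @return data.frame `library_id`, `count`, `rpm`.
#' @export
quantify_locus <- function(libraries, genome, chrom, start, end,
                           denominators = NULL) {
  if (inherits(genome, "reference_set")) genome <- genome$seqs
  if (!chrom %in% names(genome)) stop("window chromosome absent: ", chrom)
  stopifnot(start >= 0, end <= nchar(genome[[chrom]]), end > start)
  window <- stats::setNames(substring(genome[[chrom]], start + 1, end),
                            "window")
  rows <- lapply(libraries, function(lib) {
    m <- map_reads(lib$reads$sequence, window, 0L, "all")
    cnt <- sum(lib$reads$count[m$n_hits > 0])
    denom <- if (!is.null(denominators)) {
      denominators[[lib$library_id]]
    } else {
      g <- map_reads(lib$reads$sequence, genome, 0L, "all")
      sum(lib$reads$count[g$n_hits > 0])
    }
    data.frame(library_id = lib$library_id, count = cnt,
               rpm = rpm(cnt, denom), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tissue-enrichment test for one feature
#'
#' One-way ANOVA across tissues followed by Tukey's honest significant
#' difference test.  A tissue is called enriched only when it holds the
#' unique maximum mean and every pairwise Tukey comparison against it is
#' significant at `alpha`.
#'
#' @param values numeric vector of per-replicate RPM values.
#' @param tissues factor/character vector of the same length.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `enrichment_call`: list with `means`, `sem`,
#'   `F`, `p`, `tukey` (pairwise adjusted p), `enriched` (tissue name or
#'   NA).
#' @export
tissue_enrichment <- function(values, tissues, alpha = 0.05) {
  tissues <- factor(tissues)
  stopifnot(length(values) == length(tissues), nlevels(tissues) >= 2)
  means <- tapply(values, tissues, mean)
  sems <- tapply(values, tissues, function(v) sd(v) / sqrt(length(v)))
  if (stats::var(values) == 0) {
    return(structure(list(means = means, sem = sems, F = 0, p = 1,
                          tukey = NULL, enriched = NA_character_),
                     class = "enrichment_call"))
  }
  fit <- aov(values ~ tissues)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$tissues
  top <- names(means)[which.max(means)]
  tied <- sum(means == max(means)) > 1
  involves <- grepl(paste0("(^|-)", top, "(-|$)"), rownames(tk))
  enriched <- if (!tied && all(tk[involves, "p adj"] < alpha)) top else
    NA_character_
  structure(list(means = means, sem = sems, F = an$`F value`[1],
                 p = an$`Pr(>F)`[1], tukey = tk[, "p adj"],
                 enriched = enriched), class = "enrichment_call")
}

#' @export
print.enrichment_call <- function(x, ...) {
  cat(sprintf("<enrichment_call> F = %.3g, p = %.3g, enriched: %s\n",
              x$F, x$p, ifelse(is.na(x$enriched), "none", x$enriched)))
  invisible(x)
}

#' Cross-reference candidates against an AGO-IP library
#'
#' For each candidate sequence, counts the AGO library reads mapping to it
#' (exact, both strands, count-weighted, best-hit attribution so a read
#' counts once), reports the share of the library's annotated miRNA-class
#' total, and ranks candidates by count.
#'
#' @param classification an `srna_classification` of the AGO library.
#' @param candidates named character vector of candidate sequences
#'   (e.g. mature miRNAs).
#' @return data.frame `candidate`, `count`, `share_percent`, `rank`
#'   (NA for candidates with zero mapped reads).
#' @export
cross_reference_ago <- function(classification, candidates) {
  stopifnot(inherits(classification, "srna_classification"))
  reads <- classification$reads
  m <- map_reads(reads$sequence, toupper(rna_to_dna(candidates)), 0L,
                 "best")
  bh <- best_hit(m)
  counts <- stats::setNames(rep(0, length(candidates)), names(candidates))
  if (nrow(bh)) {
    agg <- tapply(reads$count[bh$read], bh$ref, sum)
    counts[names(agg)] <- agg
  }
  class_total <- sum(reads$count[reads$label == "miRNA"])
  share <- if (class_total > 0) 100 * counts / class_total else
    rep(NA_real_, length(counts))
  rk <- rank(-counts, ties.method = "min")
  rk[counts == 0] <- NA_integer_
  data.frame(candidate = names(candidates), count = as.numeric(counts),
             share_percent = as.numeric(share), rank = as.integer(rk),
             stringsAsFactors = FALSE, row.names = NULL)
}
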