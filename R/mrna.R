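#' Assign reads to 5'UTR/CDS/3'UTR features
#'
#' A read is assigned the feature that contains its full genomic interval;
#' reads overlapping a feature boundary (or falling outside all features)
#' are labeled junction and, for summary distributions, counted to the
#' feature containing the read's 5' end (the left end for "+" reads, the
#' right end for "-" reads).  Feature intervals are strand-aware: for a
#' minus-strand gene the 3'UTR is the leftmost genomic interval.
#'
#' @param gstart,gend read genomic interval (0-based half-open),
#'   vectorized.
#' @param strand read genomic strand ("+"/"-").
#' @param gene parent gene id per read.
#' @param models `gene_models` data.frame carrying the genes'
#'   five_prime_UTR/CDS/three_prime_UTR intervals.
#' @return data.frame `feature` (five_prime_UTR/CDS/three_prime_UTR or
#'   "junction") and `counted_as` (the feature the read contributes to in
#'   summaries; NA only when the 5' end lies outside all features).
#' @export
assign_feature <- function(gstart, gend, strand, gene, models) {
  feats <- models[models$type %in% c("five_prime_UTR", "CDS",
                                     "three_prime_UTR"), , drop = FALSE]
  n <- length(gstart)
  feature <- rep("junction", n)
  counted <- rep(NA_character_, n)
  for (g in unique(gene)) {
    f <- feats[!is.na(feats$parent) & feats$parent == g, , drop = FALSE]
    idx <- which(gene == g)
    if (nrow(f) == 0) next
    for (i in idx) {
      contains <- f$start <= gstart[i] & f$end >= gend[i]
      if (any(contains)) {
        feature[i] <- f$type[which(contains)[1]]
        counted[i] <- feature[i]
      } else {
        five_end <- if (strand[i] == "+") gstart[i] else gend[i] - 1
        at5 <- f$start <= five_end & f$end > five_end
        if (any(at5)) counted[i] <- f$type[which(at5)[1]]
      }
    }
  }
  data.frame(feature = feature, counted_as = counted,
             stringsAsFactors = FALSE)
}

#' Orientation class of a gene's mapped reads
#'
#' @param gene_hits data.frame with `orientation` ("sense"/"antisense")
#'   and `count` columns for one gene.
#' @param threshold sense-fraction cutoff: at or above it the gene is
#'   "sense", at or below 1 - threshold "antisense", otherwise
#'   "sense/antisense".
#' @return one of "sense", "antisense", "sense/antisense".
#' @export
orientation_class <- function(gene_hits, threshold = 0.95) {
  tot <- sum(gene_hits$count)
  if (tot == 0) stop("orientation_class: gene has no mapped reads")
  fr <- sum(gene_hits$count[gene_hits$orientation == "sense"]) / tot
  if (fr >= threshold) "sense"
  else if (fr <= 1 - threshold) "antisense"
  else "sense/antisense"
}

#' Call mRNA-derived small ncRNA candidate genes
#'
#' Two-rule filter over per-gene pooled read tables: a candidate gene must
#' (i) have one unique sequence accounting for at least `min_top_frac`
#' (default 10%) of the reads mapping to the gene, and (ii) carry strictly
#' more than `min_reads` (default 1000) reads summed across the tissue's
#' replicates.
#'
#' @param mrna_hits data.frame of coding-gene hits pooled over a tissue's
#'   replicates: columns `gene`, `sequence`, `count`, `orientation`,
#'   `feature` (as in the `mrna_hits` component of an
#'   `srna_classification`), `length`.
#' @param min_reads strict read-count floor.
#' @param min_top_frac inclusive top-sequence fraction floor.
#' @param orientation_threshold passed to [orientation_class()].
#' @return data.frame of candidates ordered by decreasing total reads then
#'   gene id: `gene`, `total_reads`, `top_sequence`, `top_count`,
#'   `top_fraction`, `orientation`, `n_5UTR`, `n_CDS`, `n_3UTR`,
#'   `size_min`, `size_max`.
#' @export
call_candidates <- function(mrna_hits, min_reads = 1000L,
                            min_top_frac = 0.10,
                            orientation_threshold = 0.95) {
  empty <- data.frame(gene = character(), total_reads = numeric(),
                      top_sequence = character(), top_count = numeric(),
                      top_fraction = numeric(), orientation = character(),
                      n_5UTR = numeric(), n_CDS = numeric(),
                      n_3UTR = numeric(), size_min = integer(),
                      size_max = integer(), stringsAsFactors = FALSE)
  if (is.null(mrna_hits) || nrow(mrna_hits) == 0) return(empty)
  rows <- lapply(split(mrna_hits, mrna_hits$gene), function(h) {
    total <- sum(h$count)
    per_seq <- tapply(h$count, h$sequence, sum)
    top <- which.max(per_seq)
    frac <- per_seq[[top]] / total
    if (!(total > min_reads && frac >= min_top_frac)) return(NULL)
    fcount <- function(f) sum(h$count[!is.na(h$feature) & h$feature == f])
    data.frame(gene = h$gene[1], total_reads = total,
               top_sequence = names(per_seq)[top],
               top_count = per_seq[[top]], top_fraction = frac,
               orientation = orientation_class(h, orientation_threshold),
               n_5UTR = fcount("five_prime_UTR"), n_CDS = fcount("CDS"),
               n_3UTR = fcount("three_prime_UTR"),
               size_min = min(h$length), size_max = max(h$length),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_reads, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
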