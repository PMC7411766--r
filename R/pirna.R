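#' TE-class breakdown of TE-piRNA reads
#'
#' Count-weighted percentages of TE-piRNA reads attributed (best hit) to
#' LTR, non-LTR and DNA transposons.
#'
#' @param te_hits data.frame with `class` and `count` columns (the
#'   `te_hits` component of an `srna_classification`).
#' @return named numeric vector of percentages over
#'   LTR/nonLTR/DNA, summing to 100.
#' @export
te_class_breakdown <- function(te_hits) {
  if (any(is.na(te_hits$class))) {
    stop("TE hit without class tag; TE references must carry classes")
  }
  lv <- c("LTR", "nonLTR", "DNA")
  cnt <- vapply(lv, function(cl) sum(te_hits$count[te_hits$class == cl]),
                numeric(1))
  100 * cnt / sum(cnt)
}

#' Sense/antisense fractions of TE-piRNA reads
#'
#' Strand is relative to the TE consensus: "+" hits are sense, "-"
#' antisense.  Count-weighted; the two fractions sum to 1.
#'
#' @param te_hits data.frame with `strand` and `count` columns.
#' @return named numeric vector `c(sense = , antisense = )`.
#' @export
strand_fractions <- function(te_hits) {
  tot <- sum(te_hits$count)
  s <- sum(te_hits$count[te_hits$strand == "+"])
  c(sense = s / tot, antisense = (tot - s) / tot)
}

#' Positional nucleotide bias matrix
#'
#' Per-position base frequencies (RNA alphabet, 5' to 3' in the read's own
#' orientation, 1-based positions) for reads of one exact length, as used
#' for piRNA 1U/10A signature logos.
#'
#' @param reads data.frame with `sequence` and `count` columns, already
#'   filtered to one orientation and the target length.
#' @param length the read length; reads of any other length are dropped.
#' @param orientation label recorded on the result ("sense" or
#'   "antisense").
#' @return object of class `positional_bias`: list with `matrix` (4 x
#'   length, rows A/C/G/U, columns positions; each column sums to 1),
#'   `n_reads`, `length`, `orientation`.  With no qualifying reads the
#'   matrix is empty and `n_reads` is 0.
#' @export
positional_bias <- function(reads, length, orientation = "sense") {
  sel <- nchar(reads$sequence) == length
  reads <- reads[sel, , drop = FALSE]
  bases <- c("A", "C", "G", "U")
  if (nrow(reads) == 0) {
    return(structure(list(matrix = matrix(numeric(0), nrow = 4, ncol = 0,
                                          dimnames = list(bases, NULL)),
                          n_reads = 0L, length = length,
                          orientation = orientation),
                     class = "positional_bias"))
  }
  ch <- matrix(unlist(strsplit(dna_to_rna(reads$sequence), "")),
               nrow = nrow(reads), byrow = TRUE)
  mat <- vapply(seq_len(length), function(pos) {
    vapply(bases, function(b) {
      sum(reads$count[ch[, pos] == b])
    }, numeric(1))
  }, numeric(4))
  mat <- sweep(mat, 2, colSums(mat), "/")
  dimnames(mat) <- list(bases, seq_len(length))
  structure(list(matrix = mat, n_reads = sum(reads$count),
                 length = length, orientation = orientation),
            class = "positional_bias")
}

#' @export
print.positional_bias <- function(x, ...) {
  cat(sprintf("<positional_bias> %s %d nt, %d reads\n", x$orientation,
              x$length, x$n_reads))
  if (ncol(x$matrix)) print(round(x$matrix[, seq_len(min(12, ncol(x$matrix)))], 2))
  invisible(x)
}

#' Sense/antisense coverage profile along a TE consensus
#'
#' Signed per-position read-start and coverage tracks (sense up, antisense
#' down) over the consensus sequence.
#'
#' @param te_hits data.frame with `ref`, `start`, `strand`, `length`,
#'   `count` columns.
#' @param te_id the consensus to profile.
#' @param te_ref the TE `reference_set` (or a named character/length
#'   vector) supplying the consensus length; an unknown `te_id` is an
#'   error.
#' @return data.frame `position` (1-based), `sense_starts`,
#'   `antisense_starts`, `sense_cov`, `antisense_cov` (antisense values
#'   negative).
#' @export
te_coverage_profile <- function(te_hits, te_id, te_ref) {
  if (inherits(te_ref, "reference_set")) te_ref <- te_ref$seqs
  if (!te_id %in% names(te_ref)) stop("unknown TE id: ", te_id)
  te_length <- if (is.numeric(te_ref)) te_ref[[te_id]] else
    nchar(te_ref[[te_id]])
  h <- te_hits[te_hits$ref == te_id, , drop = FALSE]
  starts_s <- starts_a <- cov_s <- cov_a <- numeric(te_length)
  for (i in seq_len(nrow(h))) {
    s <- h$start[i] + 1L
    e <- min(h$start[i] + h$length[i], te_length)
    if (h$strand[i] == "+") {
      starts_s[s] <- starts_s[s] + h$count[i]
      cov_s[s:e] <- cov_s[s:e] + h$count[i]
    } else {
      starts_a[s] <- starts_a[s] + h$count[i]
      cov_a[s:e] <- cov_a[s:e] + h$count[i]
    }
  }
  data.frame(position = seq_len(te_length), sense_starts = starts_s,
             antisense_starts = -starts_a, sense_cov = cov_s,
             antisense_cov = -cov_a)
}

#' Per-chromosome contribution of unique-mapping reads
#'
#' @param unique_hits data.frame with `chrom` (or `ref`) and `count`
#'   columns, one row per unique-mapping read.
#' @return data.frame `chrom`, `count`, `percent` (percentages sum to
#'   100); empty input gives an empty table.
#' @export
chromosome_contribution <- function(unique_hits) {
  if (nrow(unique_hits) == 0) {
    return(data.frame(chrom = character(), count = numeric(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  ch <- unique_hits$chrom %||% unique_hits$ref
  agg <- tapply(unique_hits$count, ch, sum)
  data.frame(chrom = names(agg), count = as.numeric(agg),
             percent = 100 * as.numeric(agg) / sum(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bin unique-mapping reads into a genomic cluster map
#'
#' Non-overlapping bins (default 1 Mb) aligned to position 0 on each
#' chromosome, counting unique-mapping piRNA reads (count-weighted).
#'
#' @param unique_hits data.frame with `chrom`, `start`, `count` columns
#'   (one genomic placement per unique-mapping read).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param bin_size bin width in nt (default 1e6).
#' @return object of class `pi_cluster_map`: data.frame `chrom`,
#'   `bin_start`, `count`, `share` (percent of all unique mappers), with
#'   `bin_size` and `total` attributes.
#' @export
pi_cluster_map <- function(unique_hits, chrom_lengths, bin_size = 1e6) {
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    data.frame(chrom = ch,
               bin_start = seq(0, chrom_lengths[[ch]] - 1, by = bin_size),
               stringsAsFactors = FALSE)
  }))
  bins$count <- 0
  if (nrow(unique_hits)) {
    b <- floor(unique_hits$start / bin_size) * bin_size
    agg <- tapply(unique_hits$count, paste(unique_hits$chrom, b), sum)
    idx <- match(names(agg), paste(bins$chrom, bins$bin_start))
    bins$count[idx] <- as.numeric(agg)
  }
  total <- sum(bins$count)
  bins$share <- if (total > 0) 100 * bins$count / total else 0
  structure(bins, class = c("pi_cluster_map", "data.frame"),
            bin_size = bin_size, total = total)
}

#' Call piRNA clusters from a binned map
#'
#' @param map a [pi_cluster_map()].
#' @param min_share minimum percent of unique-mapping reads a bin must
#'   hold, in (0, 100].
#' @return data.frame `chrom`, `bin_start`, `bin_mb` (start offset in Mb),
#'   `count`, `share`, sorted by decreasing share (ties by chrom then
#'   bin start; deterministic and invariant to input chromosome order).
#' @export
call_clusters <- function(map, min_share = 1) {
  stopifnot(min_share > 0, min_share <= 100)
  cl <- map[map$share >= min_share, , drop = FALSE]
  cl <- cl[order(-cl$share, cl$chrom, cl$bin_start), , drop = FALSE]
  cl$bin_mb <- cl$bin_start / 1e6
  rownames(cl) <- NULL
  as.data.frame(cl)[, c("chrom", "bin_start", "bin_mb", "count", "share")]
}

#' Unique-mapping genome placements of TE-piRNA reads
#'
#' Convenience extractor: partitions the classification's genome mapping
#' restricted to TE_piRNA-labeled reads and returns one placement per
#' unique-mapping read.
#'
#' @param classification an `srna_classification`.
#' @return list with `hits` (data.frame `chrom`, `start`, `strand`,
#'   `count` for unique mappers), `n_unique`, `n_multi` (count-weighted
#'   totals).
#' @export
unique_pirna_hits <- function(classification) {
  reads <- classification$reads
  te_idx <- which(reads$label == "TE_piRNA")
  part <- partition_unique_multi(classification$genome_hits)
  uni <- intersect(part$unique, te_idx)
  mult <- intersect(part$multi, te_idx)
  hits <- classification$genome_hits$hits
  best <- classification$genome_hits$best_mismatch[hits$read]
  h <- hits[hits$read %in% uni & hits$mismatches == best, , drop = FALSE]
  list(hits = data.frame(chrom = h$ref, start = h$start,
                         strand = h$strand, count = reads$count[h$read],
                         stringsAsFactors = FALSE),
       n_unique = sum(reads$count[uni]), n_multi = sum(reads$count[mult]))
}

#' Export clusters as BED6
#'
#' @param clusters output of [call_clusters()].
#' @param path output path.
#' @param bin_size bin width used to build the map.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path, bin_size = 1e6) {
  bed <- data.frame(clusters$chrom, clusters$bin_start,
                    clusters$bin_start + bin_size,
                    sprintf("cluster_%s_%gMb", clusters$chrom,
                            clusters$bin_mb),
                    round(clusters$share, 3), ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
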