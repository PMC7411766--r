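#' Mismatch-tolerant all-hits read mapping
#'
#' Maps each read (and its reverse complement) against every reference
#' sequence, reporting every placement whose Hamming distance is at most
#' `max_mismatches` (`report = "all"`) or only the minimum-distance
#' placements per read (`report = "best"`).  N never matches any base,
#' including another N.  Hits are ordered deterministically by
#' (reference id, start, strand).
#'
#' @param reads character vector of read sequences, or a collapsed-read
#'   data.frame with a `sequence` column.
#' @param refs a `reference_set` or named character vector of reference
#'   sequences.
#' @param max_mismatches maximum Hamming distance, 0-3.
#' @param report `"all"` or `"best"`.
#' @return object of class `srna_mapping`: list with
#'   \describe{
#'     \item{hits}{data.frame `read` (index into `reads`), `ref`
#'       (reference id), `start` (0-based), `strand` ("+"/"-"),
#'       `mismatches`}
#'     \item{n_hits}{integer vector, hits per read}
#'     \item{best_mismatch}{integer vector, minimum distance per read (NA
#'       when unmapped)}
#'     \item{sequences}{the read sequences mapped}
#'   }
#' @export
map_reads <- function(reads, refs, max_mismatches = 0L,
                      report = c("all", "best")) {
  report <- match.arg(report)
  stopifnot(max_mismatches %in% 0:3)
  if (is.data.frame(reads)) reads <- reads$sequence
  if (inherits(refs, "reference_set")) refs <- refs$seqs
  stopifnot(!is.null(names(refs)))
  hits <- .map_reads_cpp(as.character(reads), as.character(refs),
                         as.integer(max_mismatches), report == "all")
  hits$ref <- names(refs)[hits$ref]
  hits$strand <- c("+", "-")[hits$strand + 1L]
  # deterministic ordering by reference id (C++ orders by input index)
  hits <- hits[order(hits$read, hits$ref, hits$start,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  rownames(hits) <- NULL
  n_hits <- tabulate(hits$read, nbins = length(reads))
  best <- rep(NA_integer_, length(reads))
  if (nrow(hits)) {
    agg <- tapply(hits$mismatches, hits$read, min)
    best[as.integer(names(agg))] <- as.integer(agg)
  }
  structure(list(hits = hits, n_hits = n_hits, best_mismatch = best,
                 sequences = as.character(reads),
                 max_mismatches = as.integer(max_mismatches),
                 report = report),
            class = "srna_mapping")
}

#' @export
print.srna_mapping <- function(x, ...) {
  cat(sprintf("<srna_mapping> %d reads, %d hits (%d reads mapped, max mm %d, report=%s)\n",
              length(x$n_hits), nrow(x$hits), sum(x$n_hits > 0),
              x$max_mismatches, x$report))
  invisible(x)
}

#' Partition mapped reads into unique- and multi-mapping
#'
#' A read is unique-mapping when it has exactly one (position, strand)
#' placement at its minimum observed mismatch count; multi-mapping when it
#' has two or more; unmapped reads are excluded from both bins.
#'
#' @param mapping an `srna_mapping` from [map_reads()] with
#'   `report = "all"` against the genome.
#' @return list with integer read-index vectors `unique`, `multi`,
#'   `unmapped`.
#' @export
partition_unique_multi <- function(mapping) {
  stopifnot(inherits(mapping, "srna_mapping"))
  if (mapping$report != "all") {
    stop("partition requires report = 'all' mapping")
  }
  hits <- mapping$hits
  n <- length(mapping$n_hits)
  unmapped <- which(mapping$n_hits == 0L)
  if (nrow(hits) == 0) {
    return(list(unique = integer(), multi = integer(), unmapped = unmapped))
  }
  best <- mapping$best_mismatch[hits$read]
  at_best <- hits[hits$mismatches == best, , drop = FALSE]
  cnt <- tapply(rep(1L, nrow(at_best)), at_best$read, sum)
  ids <- as.integer(names(cnt))
  list(unique = ids[cnt == 1L], multi = ids[cnt >= 2L], unmapped = unmapped)
}

#' Best-hit attribution of reads to references
#'
#' Assigns each mapped read to a single reference: its minimum-distance
#' hit, ties broken by lexicographically smallest reference id, then
#' smallest start, then "+" strand first.
#'
#' @inheritParams partition_unique_multi
#' @return data.frame `read`, `ref`, `start`, `strand`, `mismatches` with
#'   one row per mapped read.
#' @export
best_hit <- function(mapping) {
  hits <- mapping$hits
  if (nrow(hits) == 0) return(hits)
  best <- mapping$best_mismatch[hits$read]
  hits <- hits[hits$mismatches == best, , drop = FALSE]
  # hits are already ordered (read, ref, start, strand); take first per read
  hits <- hits[!duplicated(hits$read), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Dump hits as a SAM-like TSV
#'
#' @inheritParams partition_unique_multi
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(mapping, path) {
  hits <- mapping$hits
  out <- data.frame(read = mapping$sequences[hits$read], ref = hits$ref,
                    start = hits$start, strand = hits$strand,
                    NM = hits$mismatches, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
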