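#' Read a FASTQ file
#'
#' Plain 4-line-record FASTQ; gzip is handled transparently by file
#' extension (.gz).  Malformed records raise an error naming the offending
#' line.
#'
#' @param path path to a FASTQ file, optionally gzipped.
#' @return data.frame with columns `id`, `sequence`, `quality`, in file
#'   order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n == 0) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4 != 0) {
    stop("truncated FASTQ record starting at line ", 4L * (n %/% 4L) + 1L)
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("malformed FASTQ header at line ", idx[bad[1L]])
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("malformed FASTQ separator at line ", idx[bad[1L]] + 2L)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch in record at line ", idx[bad[1L]])
  }
  data.frame(id = sub("^@", "", hdr), sequence = toupper(rna_to_dna(seq)),
             quality = qual, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param records data.frame with `id`, `sequence` and optionally `quality`
#'   columns (constant "I" quality is filled in when absent).
#' @param path output path; a `.gz` extension triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- records$quality
  if (is.null(qual)) {
    qual <- vapply(nchar(records$sequence),
                   function(n) strrep("I", n), character(1))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$sequence, "\n+\n", qual),
             con)
  invisible(path)
}

#' Trim a 3' adapter from read sequences
#'
#' Removes the leftmost exact occurrence of a prefix (at least
#' `min_overlap` nt long) of the adapter and everything 3' of it.  Reads in
#' which no adapter prefix is found are dropped (`policy = "drop"`) or kept
#' untrimmed (`policy = "keep"`).  The 15-50 nt length gate is applied
#' separately by [gate_length()].
#'
#' @param sequences character vector of read sequences.
#' @param adapter adapter sequence, non-empty.
#' @param min_overlap minimum adapter prefix length to accept, >= 1.
#' @param policy what to do with reads lacking an adapter match.
#' @return character vector of trimmed sequences with dropped reads set to
#'   `NA`.
#' @export
trim_adapter <- function(sequences, adapter, min_overlap = 8L,
                         policy = c("drop", "keep")) {
  policy <- match.arg(policy)
  stopifnot(nchar(adapter) >= 1, min_overlap >= 1)
  adapter <- toupper(rna_to_dna(adapter))
  probe <- substr(adapter, 1L, min(min_overlap, nchar(adapter)))
  pos <- regexpr(probe, sequences, fixed = TRUE)
  out <- ifelse(pos > 0L, substr(sequences, 1L, pos - 1L),
                if (policy == "keep") sequences else NA_character_)
  out
}

#' Apply the small ncRNA length and alphabet gate
#'
#' Keeps reads of 15-50 nt containing only A/C/G/T; reads with any N (or
#' other character) and reads outside the length window are dropped and
#' tallied.
#'
#' @param sequences character vector (NA entries count as already dropped
#'   upstream and are removed silently from the tallies' denominator).
#' @param min_len,max_len inclusive length bounds.
#' @return list with `kept` (character vector) and `tally` (named integer
#'   vector: n_in, n_kept, n_short, n_long, n_ambiguous).
#' @export
gate_length <- function(sequences, min_len = 15L, max_len = 50L) {
  x <- sequences[!is.na(sequences)]
  len <- nchar(x)
  clean <- !grepl("[^ACGT]", x)
  short <- len < min_len
  long <- len > max_len
  keep <- clean & !short & !long
  list(kept = x[keep],
       tally = c(n_in = length(x), n_kept = sum(keep),
                 n_short = sum(short), n_long = sum(long & !short),
                 n_ambiguous = sum(!clean & !short & !long)))
}

#' Collapse reads to unique sequences with counts
#'
#' @param sequences character vector of (trimmed, gated) read sequences.
#' @return data.frame with columns `sequence`, `length`, `count`, ordered
#'   by decreasing count then sequence; `sum(count)` equals
#'   `length(sequences)`.
#' @export
collapse_reads <- function(sequences) {
  if (length(sequences) == 0) {
    return(data.frame(sequence = character(), length = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(sequences)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$length <- nchar(df$sequence)
  df <- df[order(-df$count, df$sequence), c("sequence", "length", "count")]
  rownames(df) <- NULL
  df
}

#' Construct a small RNA library object
#'
#' A library holds the collapsed reads of one sequencing library together
#' with its identity and read-accounting totals.
#'
#' @param library_id identifier string.
#' @param reads collapsed-read data.frame from [collapse_reads()].
#' @param tissue tissue label (e.g. "FB-Ab", "MG", "OV", "R", "AGO1",
#'   "AGO2").
#' @param replicate replicate number.
#' @param total_raw raw read count before trimming (defaults to trimmed
#'   total).
#' @return object of class `srna_library`.
#' @export
srna_library <- function(library_id, reads, tissue = "other",
                         replicate = 1L, total_raw = NULL) {
  total_trimmed <- sum(reads$count)
  total_raw <- total_raw %||% total_trimmed
  stopifnot(total_trimmed <= total_raw)
  structure(list(library_id = library_id, tissue = tissue,
                 replicate = as.integer(replicate), reads = reads,
                 total_raw = as.integer(total_raw),
                 total_trimmed = as.integer(total_trimmed)),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("<srna_library> %s (%s, rep %d): %d unique sequences, %d reads\n",
              x$library_id, x$tissue, x$replicate, nrow(x$reads),
              x$total_trimmed))
  invisible(x)
}

#' Reads-per-million normalization
#'
#' @param count read count (vectorized).
#' @param denominator library-size denominator, by default the library's
#'   genome-mapped read total; must be > 0.
#' @return `count * 1e6 / denominator`.
#' @export
rpm <- function(count, denominator) {
  if (any(denominator <= 0)) stop("rpm denominator must be > 0")
  count * 1e6 / denominator
}

#' Read gene models from a GFF3 file
#'
#' Features among gene/mRNA/five_prime_UTR/CDS/three_prime_UTR/tRNA/rRNA
#' are parsed; unknown types are skipped with a warning giving their count.
#' GFF3 1-based inclusive coordinates are converted to the package's
#' internal 0-based half-open convention.
#'
#' @param gff_path path to a GFF3 file.
#' @return a `gene_models` object: data.frame with columns `chrom`,
#'   `start` (0-based), `end` (half-open), `strand`, `type`, `id`,
#'   `parent`.
#' @export
read_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  known <- c("gene", "mRNA", "five_prime_UTR", "CDS", "three_prime_UTR",
             "tRNA", "rRNA")
  type <- as.character(gr$type)
  unknown <- !(type %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " feature(s) of unknown type skipped")
    gr <- gr[!unknown]
    type <- type[!unknown]
  }
  ids <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else
    as.character(gr$ID)
  if (all(is.na(ids)) && length(gr)) ids <- paste0("feature_", seq_along(gr))
  parent <- if (is.null(gr$Parent)) rep(NA_character_, length(gr)) else
    vapply(as.list(gr$Parent), function(p) {
      if (length(p)) as.character(p[1]) else NA_character_
    }, character(1))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type, id = ids, parent = parent, stringsAsFactors = FALSE)
  if (any(df$end < df$start)) stop("feature with end < start in ", gff_path)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Feature intervals of one mRNA, ordered 5' to 3'
#'
#' @param models a `gene_models` data.frame.
#' @param mrna_id the mRNA (or gene) identifier whose child features are
#'   wanted.
#' @return data.frame of five_prime_UTR/CDS/three_prime_UTR intervals
#'   ordered along the transcript (for minus-strand models the 3'UTR is the
#'   leftmost genomic interval and sorts last).
#' @export
mrna_features <- function(models, mrna_id) {
  feats <- models[!is.na(models$parent) & models$parent == mrna_id &
                    models$type %in% c("five_prime_UTR", "CDS",
                                       "three_prime_UTR"), , drop = FALSE]
  if (nrow(feats) == 0) return(feats)
  minus <- feats$strand[1] == "-"
  feats[order(if (minus) -feats$start else feats$start), , drop = FALSE]
}

#' Build a reference set
#'
#' A named collection of reference sequences with a category and optional
#' per-feature metadata (TE class, gene models).
#'
#' @param seqs named character vector (or DNAStringSet) of sequences.
#' @param category one of genome, miRNA, ncRNA-gene, TE, mRNA.
#' @param meta optional data.frame of per-sequence metadata keyed by `id`.
#' @param models optional `gene_models` data.frame (for genome-anchored
#'   categories).
#' @return object of class `reference_set`.
#' @export
reference_set <- function(seqs, category = c("genome", "miRNA", "ncRNA-gene",
                                             "TE", "mRNA"),
                          meta = NULL, models = NULL) {
  category <- match.arg(category)
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("reference sequences must be named")
  }
  seqs <- toupper(rna_to_dna(seqs))
  if (category == "TE") {
    if (is.null(meta) || !all(c("id", "class") %in% names(meta))) {
      stop("TE reference set requires meta with id and class columns")
    }
    missing_cls <- setdiff(names(seqs), meta$id[!is.na(meta$class)])
    if (length(missing_cls)) {
      stop("TE reference(s) without class tag: ",
           paste(head(missing_cls, 3), collapse = ", "))
    }
  }
  structure(list(seqs = seqs, category = category, meta = meta,
                 models = models),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %s: %d sequence(s), %0.1f kb\n", x$category,
              length(x$seqs), sum(nchar(x$seqs)) / 1000))
  invisible(x)
}

#' Read a FASTA reference set
#'
#' @param path FASTA file.
#' @inheritParams reference_set
#' @param class_from_header for TE libraries, parse a trailing
#'   `class=LTR|nonLTR|DNA` tag from each header into the metadata.
#' @return a `reference_set`.
#' @export
read_reference_fasta <- function(path, category, class_from_header = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  meta <- NULL
  if (class_from_header) {
    cls <- ifelse(grepl("class=", headers),
                  sub(".*class=([A-Za-z]+).*", "\\1", headers), NA_character_)
    meta <- data.frame(id = ids, class = cls, stringsAsFactors = FALSE)
  }
  reference_set(setNames(as.character(ss), ids), category, meta = meta)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Ingest a FASTQ file into a library
#'
#' Convenience wrapper: read, trim the adapter, apply the length/alphabet
#' gate, collapse.
#'
#' @inheritParams read_fastq
#' @inheritParams trim_adapter
#' @inheritParams srna_library
#' @return an `srna_library`.
#' @export
ingest_fastq <- function(path, adapter, library_id = basename(path),
                         tissue = "other", replicate = 1L,
                         min_overlap = 8L, policy = "drop") {
  rec <- read_fastq(path)
  trimmed <- trim_adapter(rec$sequence, adapter, min_overlap, policy)
  gated <- gate_length(trimmed)
  srna_library(library_id, collapse_reads(gated$kept), tissue = tissue,
               replicate = replicate, total_raw = nrow(rec))
}
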