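# shared fixtures and independent oracles, built in code

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent brute-force Hamming scan: every offset, both strands,
# N never matches.  The reference implementation the mapper must equal.
brute_map_oracle <- function(read, refs, max_mm) {
  out <- list()
  for (orient in c("+", "-")) {
    q <- strsplit(if (orient == "+") read else revcomp(read), "")[[1]]
    L <- length(q)
    for (rn in names(refs)) {
      r <- strsplit(refs[[rn]], "")[[1]]
      R <- length(r)
      if (L > R || L == 0) next
      nS <- R - L + 1
      mm <- integer(nS)
      for (i in seq_len(L)) {
        seg <- r[i:(i + nS - 1)]
        mm <- mm + as.integer(seg != q[i] | seg == "N" | q[i] == "N")
      }
      keep <- which(mm <= max_mm)
      if (length(keep)) {
        out[[length(out) + 1]] <- data.frame(
          ref = rn, start = keep - 1L, strand = orient,
          mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

hit_key <- function(d) {
  if (is.null(d) || nrow(d) == 0) return(character(0))
  sort(paste(d$ref, d$start, d$strand, d$mismatches))
}

# collapsed-read data.frame from explicit sequences/counts
reads_df <- function(sequences, counts = rep(1L, length(sequences))) {
  data.frame(sequence = sequences, length = nchar(sequences),
             count = as.integer(counts), stringsAsFactors = FALSE)
}

make_library <- function(sequences, counts = rep(1L, length(sequences)),
                         id = "test", tissue = "other", replicate = 1L) {
  srna_library(id, reads_df(sequences, counts), tissue = tissue,
               replicate = replicate)
}

empty_models <- function() {
  df <- data.frame(chrom = character(), start = numeric(),
                   end = numeric(), strand = character(),
                   type = character(), id = character(),
                   parent = character(), stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

# a tiny hand-built reference bundle with a read that matches both the
# miRNA hairpin and a TE consensus (cascade order-sensitivity fixture)
ambiguous_fixture <- function(seed = 11) {
  set.seed(seed)
  mature <- rand_dna(22)
  hairpin <- paste0(mature, rand_dna(40), revcomp(mature))
  te <- paste0(rand_dna(80), mature, rand_dna(80))
  genome <- c(chr1 = paste0(rand_dna(50), hairpin, rand_dna(50), te,
                            rand_dna(50)))
  refs <- list(
    genome = reference_set(genome, "genome"),
    mirna = reference_set(c(hp1 = hairpin), "miRNA"),
    te = reference_set(c(TE1 = te), "TE",
                       meta = data.frame(id = "TE1", class = "LTR",
                                         stringsAsFactors = FALSE)),
    models = empty_models())
  list(mature = mature, refs = refs, genome = genome)
}

# small fast genome bundle for cascade tests
small_bundle <- function(seed = 5) {
  cfg <- sim_config(
    seed = seed,
    chromosomes = c("2R" = 3e5, "3L" = 3e5, "X" = 2e5),
    n_reads = 5000L,
    mirna = list(n_hairpins = 6L),
    ncrna = list(n_trna = 5L, n_rrna = 6L, rrna_len = c(300L, 800L)),
    mrna = list(n_genes = 10L))
  build_genome(cfg)
}
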