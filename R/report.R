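#' Per-tissue composition table
#'
#' Mean and SEM (sd/sqrt(n) over replicates) of the per-library class
#' percentages, one row per tissue.
#'
#' @param classifications list of `srna_classification` objects.
#' @return data.frame with `tissue`, `n_replicates`, then `<class>_mean`
#'   and `<class>_sem` for each of the six labels.
#' @export
composition_table <- function(classifications) {
  lv <- c("miRNA", "tRNA_rRNA", "TE_piRNA", "mRNA_derived", "unannotated",
          "unmapped")
  comp <- t(vapply(classifications, function(x) x$composition[lv],
                   numeric(length(lv))))
  tissue <- vapply(classifications, function(x) x$tissue, character(1))
  rows <- lapply(unique(tissue), function(ts) {
    m <- comp[tissue == ts, , drop = FALSE]
    means <- colMeans(m)
    sems <- apply(m, 2, function(v) {
      if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    })
    out <- data.frame(tissue = ts, n_replicates = nrow(m))
    for (l in lv) {
      out[[paste0(l, "_mean")]] <- means[[l]]
      out[[paste0(l, "_sem")]] <- sems[[l]]
    }
    out
  })
  do.call(rbind, rows)
}

#' Abundance filter for heatmap rows
#'
#' Keeps rows whose maximum RPM across libraries exceeds
#' `10^threshold_log10` (default threshold 1, i.e. RPM > 10).
#'
#' @param rpm_table numeric matrix, features x libraries.
#' @param threshold_log10 log10 RPM threshold.
#' @return the filtered matrix.
#' @export
filter_abundance <- function(rpm_table, threshold_log10 = 1) {
  keep <- apply(rpm_table, 1, max) > 10^threshold_log10
  rpm_table[keep, , drop = FALSE]
}

#' Agglomerative clustering with deterministic leaf order
#'
#' Euclidean distance, average linkage (the defaults), as used to order
#' the tRNA/rRNA heatmap rows and columns.
#'
#' @param mat numeric matrix; rows are clustered.
#' @param metric distance metric for [stats::dist()].
#' @param linkage linkage method for [stats::hclust()].
#' @return for >= 2 rows, the `hclust` object with an added `leaf_order`
#'   component (row indices in dendrogram order); for a single row, a
#'   trivial list with `leaf_order = 1`.
#' @export
hierarchical_cluster <- function(mat, metric = "euclidean",
                                 linkage = "average") {
  if (nrow(mat) < 2) {
    return(list(trivial = TRUE, leaf_order = seq_len(nrow(mat))))
  }
  hc <- hclust(dist(mat, method = metric), method = linkage)
  hc$leaf_order <- hc$order
  hc
}

#' Per-gene tRNA/rRNA fragment RPM table
#'
#' @param classifications list of `srna_classification` objects.
#' @return numeric matrix gene x library of RPM values (denominator:
#'   genome-mapped reads per library).
#' @export
trna_rrna_rpm_table <- function(classifications) {
  per_lib <- lapply(classifications, function(x) {
    h <- x$ncrna_hits
    if (is.null(h) || nrow(h) == 0) return(stats::setNames(numeric(0), character(0)))
    cnt <- tapply(x$reads$count[h$read], h$gene, sum)
    rpm(as.numeric(cnt), x$genome_mapped) |> stats::setNames(names(cnt))
  })
  genes <- sort(unique(unlist(lapply(per_lib, names))))
  mat <- matrix(0, length(genes), length(classifications),
                dimnames = list(genes, vapply(classifications,
                                              function(x) x$library_id,
                                              character(1))))
  for (j in seq_along(per_lib)) {
    mat[names(per_lib[[j]]), j] <- per_lib[[j]]
  }
  mat
}

#' Run the full simulate-classify-report pipeline
#'
#' Simulates (or ingests) libraries, runs the annotation cascade, the
#' piRNA statistics and the mRNA-derived candidate calling, and writes all
#' report tables plus a manifest to the output directory.
#'
#' @param config a [sim_config()] (simulation mode), or a list with
#'   `fastq` (named vector of FASTQ paths), `adapter` and reference paths
#'   `genome_fa`, `mirna_fa`, `te_fa`, `models_gff` (file mode).
#' @param out_dir output directory.
#' @param tissues tissues to simulate (simulation mode).
#' @param replicates replicates per tissue.
#' @return invisibly, a list with the classifications and the output
#'   paths.  Fails with the stage name on any missing input.
#' @export
run_pipeline <- function(config, out_dir, tissues = c("OV", "MG"),
                         replicates = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(config, "sim_config")) {
    bundle <- build_genome(config)
    refs <- sim_references(bundle)
    libs <- list()
    for (ts in tissues) {
      for (r in seq_len(replicates)) {
        sim <- simulate_library(bundle, tissue = ts, replicate = r)
        libs[[sim$library_id]] <- as_srna_library(sim)
      }
    }
    chrom_lengths <- config$chromosomes
    seed <- config$seed
  } else {
    for (need in c("genome_fa", "mirna_fa", "te_fa", "models_gff")) {
      if (is.null(config[[need]]) || !file.exists(config[[need]])) {
        stop("cascade/genome: missing input ", need)
      }
    }
    refs <- list(genome = read_reference_fasta(config$genome_fa, "genome"),
                 mirna = read_reference_fasta(config$mirna_fa, "miRNA"),
                 te = read_reference_fasta(config$te_fa, "TE",
                                           class_from_header = TRUE),
                 models = read_gene_models(config$models_gff))
    libs <- lapply(names(config$fastq), function(id) {
      ingest_fastq(config$fastq[[id]], config$adapter, library_id = id)
    })
    names(libs) <- names(config$fastq)
    chrom_lengths <- nchar(refs$genome$seqs)
    seed <- NA
  }

  cls <- lapply(libs, classify, references = refs)

  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(tsv(composition_table(cls), "composition.tsv"))
  for (x in cls) {
    hist <- as.data.frame.matrix(x$size_histograms)
    hist <- cbind(class = rownames(x$size_histograms), hist)
    paths <- c(paths,
               tsv(hist, paste0("sizes_", x$library_id, ".tsv")),
               tsv(x$depletion_log, paste0("depletion_", x$library_id,
                                           ".tsv")))
    if (!is.null(x$te_hits) && nrow(x$te_hits)) {
      tb <- te_class_breakdown(x$te_hits)
      sf <- strand_fractions(x$te_hits)
      paths <- c(paths, tsv(
        data.frame(metric = c(paste0("class_", names(tb)),
                              paste0("strand_", names(sf))),
                   value = c(tb, sf)),
        paste0("pirna_", x$library_id, ".tsv")))
      up <- unique_pirna_hits(x)
      if (nrow(up$hits)) {
        cm <- pi_cluster_map(up$hits, chrom_lengths)
        paths <- c(paths, tsv(call_clusters(cm),
                              paste0("clusters_", x$library_id, ".tsv")))
      }
    }
    if (!is.null(x$mrna_hits) && nrow(x$mrna_hits)) {
      paths <- c(paths, tsv(call_candidates(x$mrna_hits),
                            paste0("candidates_", x$library_id, ".tsv")))
    }
  }
  rpm_tab <- trna_rrna_rpm_table(cls)
  if (nrow(rpm_tab)) {
    filt <- filter_abundance(rpm_tab)
    paths <- c(paths, tsv(cbind(gene = rownames(filt),
                                as.data.frame(filt)),
                          "trna_rrna_rpm.tsv"))
  }
  manifest <- list(
    package = "srnacensus",
    version = as.character(utils::packageVersion("srnacensus")),
    seed = seed, libraries = names(libs), outputs = basename(paths))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(classifications = cls, paths = paths,
                 manifest = manifest))
}
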