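te_hits_fixture <- function() {
  data.frame(
    ref = c("TE_L1", "TE_L1", "TE_N1"),
    class = c("LTR", "LTR", "nonLTR"),
    strand = c("+", "+", "-"),
    start = c(0L, 5L, 2L),
    length = c(27L, 27L, 28L),
    sequence = c(rand_dna(27), rand_dna(27), rand_dna(28)),
    count = c(1L, 1L, 1L), stringsAsFactors = FALSE)
}

test_that("TE class breakdown matches hand counts and conserves totals", {
  h <- te_hits_fixture()
  # 3 reads -> L,N,D counts 2,1,0
  br <- te_class_breakdown(h)
  expect_equal(unname(br), c(200 / 3, 100 / 3, 0))
  expect_equal(sum(br), 100)

  one <- h[1, , drop = FALSE]
  expect_equal(unname(te_class_breakdown(one)), c(100, 0, 0))
  h2 <- h; h2$class[2] <- NA
  expect_error(te_class_breakdown(h2), "class")
})

test_that("strand fractions are count-weighted and sum to one", {
  h <- data.frame(strand = c("+", "+", "+", "-"), count = c(1, 1, 1, 1))
  expect_equal(strand_fractions(h), c(sense = 0.75, antisense = 0.25))
  all_minus <- data.frame(strand = "-", count = 5)
  expect_equal(strand_fractions(all_minus)[["antisense"]], 1.0)
  # conservation against the class breakdown on a shared fixture
  fx <- te_hits_fixture()
  sf <- strand_fractions(fx)
  expect_equal(sum(fx$count) * sum(sf), sum(fx$count))
})

test_that("positional bias equals hand tabulation and columns sum to one", {
  reads <- reads_df(c("ACGT", "AGGT", "TCGA", "ACGA"))
  pb <- positional_bias(reads, 4, "sense")
  # hand counts: pos1 A=3 T=1; pos2 C=3 G=1; pos3 G=4; pos4 U=2 A=2
  expect_equal(pb$matrix["A", 1], 0.75)
  expect_equal(pb$matrix["U", 1], 0.25)
  expect_equal(pb$matrix["C", 2], 0.75)
  expect_equal(pb$matrix["G", 3], 1.0)
  expect_equal(pb$matrix["U", 4], 0.5)
  expect_true(all(abs(colSums(pb$matrix) - 1) < 1e-9))
  expect_equal(pb$n_reads, 4L)

  same <- reads_df(rep("ACGTACGTACGTACGTACGTACGTACG", 3), c(5, 2, 1))
  pb2 <- positional_bias(same, 27)
  expect_true(all(apply(pb2$matrix, 2, max) == 1))

  none <- positional_bias(reads, 10)
  expect_equal(none$n_reads, 0L)
  expect_equal(ncol(none$matrix), 0)
})

test_that("reverse-complementing the read set mirrors the bias matrix", {
  set.seed(41)
  reads <- reads_df(replicate(50, rand_dna(27)),
                    sample(1:5, 50, replace = TRUE))
  pb <- positional_bias(reads, 27)
  rc <- reads
  rc$sequence <- revcomp(rc$sequence)
  pb_rc <- positional_bias(rc, 27)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (b in names(comp)) {
    for (p in c(1, 10, 27)) {
      expect_equal(pb_rc$matrix[b, p], pb$matrix[comp[[b]], 27 + 1 - p])
    }
  }
})

test_that("simulated piRNA reads carry the configured 1U bias", {
  cfg <- sim_config(
    seed = 42,
    chromosomes = c("2R" = 4e5, "3L" = 4e5),
    class_mixture = c(miRNA = 0, tRNA_rRNA = 0, TE_piRNA = 1,
                      mRNA_derived = 0, unannotated = 0, unmappable = 0))
  b <- build_genome(cfg)
  sim <- simulate_library(b, tissue = "OV", n_reads = 10000)
  tr <- sim$truth[sim$truth$orientation == "sense", ]
  tr27 <- tr[nchar(tr$sequence) == 27, ]
  pb <- positional_bias(reads_df(tr27$sequence), 27, "sense")
  expect_equal(pb$matrix["U", 1], 0.9, tolerance = 0.03)
  expect_equal(pb$matrix["A", 10], 0.9, tolerance = 0.03)
  anti <- sim$truth[sim$truth$orientation == "antisense", ]
  anti27 <- anti[nchar(anti$sequence) == 27, ]
  pba <- positional_bias(reads_df(anti27$sequence), 27, "antisense")
  expect_equal(pba$matrix["U", 1], 0.9, tolerance = 0.03)
})

test_that("TE coverage profiles overlay reads by hand", {
  te_ref <- c(TE1 = rand_dna(100))
  h <- data.frame(ref = "TE1", strand = c("+", "-", "-"),
                  start = c(0L, 10L, 20L), length = c(27L, 27L, 27L),
                  count = c(1L, 1L, 1L), stringsAsFactors = FALSE)
  prof <- te_coverage_profile(h, "TE1", te_ref)
  expect_equal(prof$sense_cov[1:27], rep(1, 27))
  expect_equal(prof$sense_cov[28], 0)
  # antisense reads overlap on [21,37]: coverage -2 there
  expect_equal(prof$antisense_cov[25], -2)
  expect_equal(prof$antisense_cov[15], -1)
  expect_equal(prof$antisense_starts[11], -1)
  expect_error(te_coverage_profile(h, "nope", te_ref), "unknown")
})

test_that("uniformly planted starts give a flat coverage profile", {
  te_ref <- c(TE1 = rand_dna(200))
  # one sense read starting at every admissible offset
  h <- data.frame(ref = "TE1", strand = "+", start = 0:(200 - 27),
                  length = 27L, count = 1L, stringsAsFactors = FALSE)
  prof <- te_coverage_profile(h, "TE1", te_ref)
  interior <- prof$sense_cov[27:(200 - 26)]
  expect_true(all(interior == 27))   # exactly flat away from the edges
  expect_lt(max(prof$sense_cov), 2 * mean(prof$sense_cov))
})

test_that("chromosome contribution percentages are exact", {
  h <- data.frame(chrom = c(rep("c1", 3), rep("c2", 7)), count = rep(1, 10))
  cc <- chromosome_contribution(h)
  expect_equal(cc$percent[cc$chrom == "c1"], 30)
  expect_equal(cc$percent[cc$chrom == "c2"], 70)
  expect_equal(sum(cc$percent), 100)
  one <- chromosome_contribution(data.frame(chrom = "c1", count = 5))
  expect_equal(one$percent, 100)
  expect_equal(nrow(chromosome_contribution(
    data.frame(chrom = character(), count = numeric()))), 0)
})

test_that("cluster calling filters, sorts and conserves shares", {
  lens <- c(c1 = 3e6, c2 = 2e6)
  hits <- data.frame(
    chrom = c(rep("c1", 40), rep("c1", 35), rep("c2", 25)),
    start = c(runif(40, 0, 1e6), runif(35, 1e6, 2e6), runif(25, 0, 1e6)),
    count = rep(1, 100))
  cm <- pi_cluster_map(hits, lens)
  expect_equal(sum(cm$count), 100)
  expect_equal(sum(cm$share), 100)
  cl <- call_clusters(cm, min_share = 30)
  expect_equal(nrow(cl), 2)          # shares 40 and 35 pass, 25 does not
  expect_equal(cl$share, c(40, 35))
  # single-bin degenerate case
  cm1 <- pi_cluster_map(data.frame(chrom = "c1", start = 10, count = 7),
                        lens)
  expect_equal(call_clusters(cm1, 1)$share, 100)
  # invariant to chromosome ordering of the input
  hits2 <- hits[order(hits$chrom, decreasing = TRUE), ]
  cl2 <- call_clusters(pi_cluster_map(hits2, lens), min_share = 30)
  expect_identical(cl, cl2)
})

test_that("unique piRNA extraction feeds a consistent cluster map", {
  cfg <- sim_config_pirna(seed = 3, n_reads = 4000L)
  b <- build_genome(cfg)
  sim <- simulate_library(b, tissue = "OV", n_reads = 4000,
                          mixture = cfg$class_mixture)
  cl <- classify(as_srna_library(sim), sim_references(b))
  up <- unique_pirna_hits(cl)
  te_total <- sum(cl$reads$count[cl$reads$label == "TE_piRNA"])
  expect_equal(up$n_unique + up$n_multi, te_total)
  cm <- pi_cluster_map(up$hits, cfg$chromosomes)
  expect_equal(sum(cm$count), up$n_unique)
})
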