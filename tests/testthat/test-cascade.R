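test_that("a read matching both miRNA and TE references is labeled miRNA, and stage order matters", {
  fx <- ambiguous_fixture()
  lib <- make_library(fx$mature)
  cl <- classify(lib, fx$refs)
  expect_equal(cl$reads$label, "miRNA")
  # the same read is genuinely ambiguous: it also matches the TE consensus
  expect_gt(nrow(map_reads(fx$mature, fx$refs$te, 2)$hits), 0)
  # permuting stages 2-5 changes the label
  cl2 <- classify(lib, fx$refs,
                  params = list(stage_order = c("TE_piRNA", "miRNA",
                                                "tRNA_rRNA",
                                                "mRNA_derived")))
  expect_equal(cl2$reads$label, "TE_piRNA")
})

test_that("reads matching nothing in the genome are unmapped; missing references error", {
  fx <- ambiguous_fixture()
  lib <- make_library(c(fx$mature, rand_dna(30)))
  cl <- classify(lib, fx$refs)
  expect_setequal(cl$reads$label, c("miRNA", "unmapped"))
  expect_error(classify(lib, fx$refs[c("genome", "mirna", "te")]),
               "models")
})

test_that("composition sums to 100, histograms and depletion log are consistent", {
  b <- small_bundle()
  sim <- simulate_library(b, tissue = "OV", n_reads = 5000)
  cl <- classify(as_srna_library(sim), sim_references(b))
  expect_equal(sum(cl$composition), 100, tolerance = 1e-9)
  # per class, size histogram row sums equal class totals
  for (l in rownames(cl$size_histograms)) {
    expect_equal(sum(cl$size_histograms[l, ]),
                 sum(cl$reads$count[cl$reads$label == l]))
  }
  # depletion log: remaining is non-increasing, totals conserved
  expect_true(all(diff(cl$depletion_log$remaining) <= 0))
  expect_equal(cl$depletion_log$reads_in[1], sum(cl$reads$count))
  expect_equal(cl$depletion_log$assigned + cl$depletion_log$remaining,
               cl$depletion_log$reads_in)
})

test_that("classification recovers simulator ground truth on mismatch-free reads", {
  b <- small_bundle()
  sim <- simulate_library(b, tissue = "MG", n_reads = 10000)
  cl <- classify(as_srna_library(sim), sim_references(b))
  truth <- sim$truth
  truth$class[truth$class == "unmappable"] <- "unmapped"
  lab <- cl$reads$label[match(truth$sequence, cl$reads$sequence)]
  expect_gte(mean(lab == truth$class), 0.99)
})

test_that("miRNA homolog discovery applies size, count and score filters exactly", {
  set.seed(21)
  db_mature <- rand_dna(22)
  db <- c("dme-miR-x" = db_mature)
  ch <- strsplit(db_mature, "")[[1]]
  pos <- c(4, 11, 18)
  ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A","C","G","T"), b)[1],
                    character(1))
  homolog3 <- paste(ch, collapse = "")         # 3 mismatches, 22 nt

  bg22 <- rand_dna(22)
  reads <- reads_df(
    c(homolog3, db_mature, rand_dna(27), bg22),
    c(5000L, 150L, 10000L, 4000L))
  out <- discover_mirna_homologs(reads, db)
  # 3-mismatch 22-nt candidate retained: score 100*(1 - 3/22) ~ 86.4 >= 80
  expect_true(homolog3 %in% out$sequence)
  expect_equal(out$homology_score[out$sequence == homolog3],
               100 * (1 - 3 / 22), tolerance = 1e-9)
  # 150-count perfect match rejected by the strict >200 count rule
  expect_false(db_mature %in% out$sequence)
  # 27-nt read rejected by size regardless of depth
  expect_false(any(out$length > 25))
  # unrelated 22-mer rejected by score
  expect_false(bg22 %in% out$sequence)
  expect_error(discover_mirna_homologs(reads, character(0)), "empty")
})

test_that("count threshold is strict: 201 passes, 200 does not", {
  set.seed(22)
  db <- c(m = rand_dna(22))
  reads <- reads_df(c(db[["m"]]), 200L)
  expect_equal(nrow(discover_mirna_homologs(reads, db)), 0)
  reads <- reads_df(c(db[["m"]]), 201L)
  expect_equal(nrow(discover_mirna_homologs(reads, db)), 1)
})

test_that("quantify_locus counts only reads inside the window", {
  set.seed(23)
  genome <- c(chr = rand_dna(2000))
  win <- c(500, 800)
  inside <- vapply(1:3, function(i) {
    s <- sample(win[1]:(win[2] - 25), 1)
    substr(genome[["chr"]], s + 1, s + 25)
  }, character(1))
  outside <- vapply(1:7, function(i) {
    s <- sample(c(0:(win[1] - 30), win[2]:(2000 - 30)), 1)
    substr(genome[["chr"]], s + 1, s + 25)
  }, character(1))
  lib <- make_library(c(inside, outside), id = "L1")
  q <- quantify_locus(list(lib), genome, "chr", win[1], win[2],
                      denominators = c(L1 = 10))
  expect_equal(q$count, 3)
  expect_equal(q$rpm, rpm(3, 10))
  expect_error(quantify_locus(list(lib), genome, "nope", 0, 10),
               "absent")
})

test_that("tissue enrichment matches hand-computed one-way ANOVA", {
  vals <- c(10, 11, 12, 10, 12, 14, 50, 52, 54)
  tis <- rep(c("FB", "MG", "OV"), each = 3)
  # textbook sums of squares on the fixture
  gm <- mean(vals)
  means <- tapply(vals, tis, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((vals - rep(means, each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  call <- tissue_enrichment(vals, tis)
  expect_equal(call$F, f_hand, tolerance = 1e-9)
  expect_equal(call$enriched, "OV")
  expect_lt(call$p, 1e-4)

  # identical values everywhere: F = 0, no enrichment
  flat <- tissue_enrichment(rep(7, 9), tis)
  expect_equal(flat$F, 0)
  expect_true(is.na(flat$enriched))

  # two tissues tied at the maximum mean: no enrichment
  tie <- tissue_enrichment(c(5, 6, 7, 7, 6, 5, 1, 1, 1), tis)
  expect_true(is.na(tie$enriched))
})

test_that("AGO cross-reference recovers a planted loading share", {
  cfg <- sim_config(
    seed = 31,
    chromosomes = c("2R" = 3e5, "3L" = 3e5),
    mirna = list(n_hairpins = 8L,
                 hairpin_weights = c(0.16, rep(0.84 / 7, 7))),
    class_mixture = c(miRNA = 1, tRNA_rRNA = 0, TE_piRNA = 0,
                      mRNA_derived = 0, unannotated = 0, unmappable = 0))
  b <- build_genome(cfg)
  sim <- simulate_library(b, tissue = "AGO1", n_reads = 20000)
  cl <- classify(as_srna_library(sim), sim_references(b))
  cands <- c(b$matures[1], b$matures[2], absent = rand_dna(22))
  tab <- cross_reference_ago(cl, cands)
  target <- tab[tab$candidate == names(b$matures)[1], ]
  expect_equal(target$share_percent, 16, tolerance = 0.1 * 16)
  absent <- tab[tab$candidate == "absent", ]
  expect_equal(absent$count, 0)
  expect_true(is.na(absent$rank))

  # a single candidate holding every miRNA-stage read: share 100, rank 1
  lib1 <- make_library(b$matures[1], 500L)
  cl1 <- classify(lib1, sim_references(b))
  one <- cross_reference_ago(cl1, b$matures[1])
  expect_equal(one$share_percent, 100)
  expect_equal(one$rank, 1L)
})
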