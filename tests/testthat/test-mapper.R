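test_that("exact and reverse-complement placements are reported with coordinates", {
  set.seed(2)
  ref <- c(r = rand_dna(120))
  read <- substr(ref[["r"]], 11, 32)        # offset 10, 22 nt
  m <- map_reads(read, ref, 0)
  expect_equal(m$hits$start, 10)
  expect_equal(m$hits$strand, "+")
  expect_equal(m$hits$mismatches, 0)

  rc <- revcomp(substr(ref[["r"]], 21, 42)) # ref[20:42) on the minus strand
  m2 <- map_reads(rc, ref, 0)
  expect_equal(m2$hits$start, 20)
  expect_equal(m2$hits$strand, "-")
})

test_that("mismatch budget gates hits exactly", {
  set.seed(3)
  ref <- c(r = rand_dna(300))
  read <- substr(ref[["r"]], 101, 128)
  ch <- strsplit(read, "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  ch[5] <- flip(ch[5]); ch[17] <- flip(ch[17])
  mut <- paste(ch, collapse = "")
  expect_equal(nrow(map_reads(mut, ref, 2)$hits), 1)
  expect_equal(map_reads(mut, ref, 2)$hits$mismatches, 2)
  expect_equal(nrow(map_reads(mut, ref, 1)$hits), 0)
  # brute-force oracle agrees
  expect_identical(hit_key(map_reads(mut, ref, 2)$hits),
                   hit_key(brute_map_oracle(mut, ref, 2)))
})

test_that("mapper equals the brute-force oracle on random instances", {
  set.seed(4)
  for (i in 1:40) {
    refs <- c(a = rand_dna(sample(100:600, 1)),
              b = rand_dna(sample(50:300, 1)))
    L <- sample(15:40, 1)
    read <- if (runif(1) < 0.6) {
      s <- sample(0:(nchar(refs[["a"]]) - L), 1)
      x <- substr(refs[["a"]], s + 1, s + L)
      ch <- strsplit(x, "")[[1]]
      nm <- sample(0:3, 1)
      if (nm > 0) {
        ch[sample(L, nm)] <- sample(c("A", "C", "G", "T", "N"), nm, TRUE)
      }
      x <- paste(ch, collapse = "")
      if (runif(1) < 0.5) revcomp(x) else x
    } else {
      rand_dna(L)
    }
    mm <- sample(0:3, 1)
    expect_identical(hit_key(map_reads(read, refs, mm, "all")$hits),
                     hit_key(brute_map_oracle(read, refs, mm)))
  }
})

test_that("the seed-indexed path equals the oracle on a large reference", {
  set.seed(5)
  big <- c(g = rand_dna(30000))   # large enough to trigger the index
  for (i in 1:12) {
    L <- sample(24:45, 1)
    s <- sample(0:(30000 - L), 1)
    x <- substr(big[["g"]], s + 1, s + L)
    ch <- strsplit(x, "")[[1]]
    nm <- sample(0:2, 1)
    if (nm > 0) ch[sample(L, nm)] <- sample(c("A", "C", "G", "T"), nm, TRUE)
    x <- paste(ch, collapse = "")
    if (runif(1) < 0.5) x <- revcomp(x)
    for (mm in 0:2) {
      expect_identical(hit_key(map_reads(x, big, mm, "all")$hits),
                       hit_key(brute_map_oracle(x, big, mm)))
    }
  }
})

test_that("strand symmetry: mapping revcomp flips strands", {
  set.seed(6)
  refs <- c(a = rand_dna(400))
  for (i in 1:10) {
    read <- if (i %% 2) substr(refs[["a"]], 20 + i, 45 + i) else rand_dna(25)
    h1 <- map_reads(read, refs, 1)$hits
    h2 <- map_reads(revcomp(read), refs, 1)$hits
    h2$strand <- ifelse(h2$strand == "+", "-", "+")
    expect_identical(hit_key(h1), hit_key(h2))
  }
})

test_that("N never matches, including N against N", {
  ref <- c(r = "AAAANAAAAAAAAAAAAAAA")
  expect_equal(nrow(map_reads("AAAANAAAAAAAAAAA", ref, 0)$hits), 0)
  m <- map_reads("AAAANAAAAAAAAAAA", ref, 2)$hits
  expect_true(all(m$mismatches >= 1))
  expect_identical(hit_key(m),
                   hit_key(brute_map_oracle("AAAANAAAAAAAAAAA", ref, 2)))
})

test_that("report=best keeps only minimum-distance hits", {
  set.seed(7)
  core <- rand_dna(30)
  ch <- strsplit(core, "")[[1]]
  ch[8] <- setdiff(c("A", "C", "G", "T"), ch[8])[1]
  near <- paste(ch, collapse = "")
  refs <- c(x = paste0(rand_dna(40), core, rand_dna(40), near, rand_dna(40)))
  all_hits <- map_reads(core, refs, 2, "all")$hits
  best <- map_reads(core, refs, 2, "best")$hits
  expect_equal(nrow(all_hits), 2)
  expect_equal(nrow(best), 1)
  expect_equal(best$mismatches, 0)
})

test_that("unique/multi partition follows the minimum-distance rule", {
  set.seed(8)
  core <- rand_dna(25)
  ch <- strsplit(core, "")[[1]]
  mut <- function(x, pos) {
    y <- strsplit(x, "")[[1]]
    y[pos] <- vapply(y[pos], function(b) setdiff(c("A","C","G","T"), b)[1],
                     character(1))
    paste(y, collapse = "")
  }
  # one perfect locus + three 2-mismatch loci for read `core`
  genome <- c(g = paste0(rand_dna(30), core, rand_dna(30), mut(core, c(3, 9)),
                         rand_dna(30), mut(core, c(5, 14)), rand_dna(30),
                         mut(core, c(7, 21)), rand_dna(30)))
  dup <- rand_dna(20)
  genome2 <- c(g = paste0(genome[["g"]], dup, rand_dna(25), dup,
                          rand_dna(25)))
  reads <- c(core, dup, rand_dna(22))
  m <- map_reads(reads, genome2, 2, "all")
  part <- partition_unique_multi(m)
  expect_equal(part$unique, 1L)     # min-distance stratum has one hit
  expect_equal(part$multi, 2L)      # exact duplicate at two loci
  expect_equal(part$unmapped, 3L)
  # the three bins partition the reads
  expect_setequal(c(part$unique, part$multi, part$unmapped), 1:3)
  # independent recount at minimum distance from the oracle
  o <- brute_map_oracle(core, genome2, 2)
  expect_equal(sum(o$mismatches == min(o$mismatches)), 1)
})

test_that("best-hit attribution breaks ties lexicographically", {
  set.seed(9)
  core <- rand_dna(26)
  refs <- c(TEb = paste0(rand_dna(10), core, rand_dna(10)),
            TEa = paste0(rand_dna(25), core, rand_dna(5)))
  m <- map_reads(core, refs, 0, "all")
  bh <- best_hit(m)
  expect_equal(nrow(bh), 1)
  expect_equal(bh$ref, "TEa")
})

test_that("the SAM-like TSV dump carries read, reference, position, strand and NM", {
  set.seed(10)
  ref <- c(r1 = rand_dna(100))
  reads <- c(substr(ref[["r1"]], 11, 35), rand_dna(20))
  m <- map_reads(reads, ref, 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(m, path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$read, reads[1])
  expect_equal(tab$start, 10)
  expect_equal(tab$NM, 0)
})

test_that("reads longer than every reference yield zero hits", {
  m <- map_reads(rand_dna(40), c(short = rand_dna(20)), 2)
  expect_equal(nrow(m$hits), 0)
  expect_equal(m$n_hits, 0L)
  expect_true(is.na(m$best_mismatch))
})
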