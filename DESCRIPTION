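Package: srnacensus
Title: Hierarchical Classification of Insect Small Non-Coding RNA Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A sequential-depletion annotation cascade for insect small
    RNA-Seq libraries (15-50 nt): reads are partitioned into miRNA,
    tRNA/rRNA-fragment, transposon-derived piRNA, mRNA-derived, unannotated
    and unmapped classes by ordered queries against a genome, a mature-miRNA
    set, non-coding gene models, a transposable-element consensus library and
    coding gene models. Includes an all-hits mismatch-tolerant read mapper,
    miRNA homolog discovery, tissue-enrichment testing (one-way ANOVA with
    Tukey contrasts), piRNA signature statistics (strand bias, 1U/10A
    positional nucleotide frequencies, TE coverage, genomic cluster calling
    on unique-mapping reads), mRNA-derived small RNA candidate calling with
    UTR/CDS feature assignment, reporting utilities, and a synthetic-data
    generator that plants all of these structures in a desk-scale genome with
    per-read ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
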