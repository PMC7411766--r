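# srnacensus

Hierarchical classification of small non-coding RNA populations in insect
small RNA-Seq libraries.

## The problem

A small RNA-Seq library from a mosquito tissue (15-50 nt after adapter
trimming) mixes several biologically distinct populations: microRNAs,
tRNA/rRNA fragments, transposon-targeting piRNAs, small RNAs derived from
protein-coding transcripts, and genome-mapping reads matching no
annotation. Surveys of these populations separate them with a
**sequential depletion cascade**: reads are mapped to the genome, then
queried in a fixed order against a mature-miRNA set, tRNA/rRNA gene
models, a transposable-element consensus library (allowing ≤ 2
mismatches), and coding gene models; a read annotated at one stage is
depleted before the next. srnacensus implements that cascade for
bioinformaticians working on insect small RNA biology, together with the
class-specific statistics such a survey reports:

* **piRNA statistics** — sense/antisense fractions relative to the TE
  consensus; positional nucleotide frequency matrices for the 1U/10A
  signature (the hallmark enrichment of U at read position 1 and, for
  sense piRNAs, A at position 10); TE-class breakdown
  (LTR / non-LTR / DNA); coverage profiles along a consensus; the
  unique/multi-mapping partition (a read is unique iff it has exactly one
  genomic placement at its minimum mismatch count); and piRNA-cluster
  calling by 1-Mb genomic binning of unique-mapping reads.
* **miRNA homolog discovery** — 20-25 nt sequences with > 200 reads are
  scored against a mature-miRNA database by the best ungapped offset
  alignment, score = 100 (1 − mismatches/length), retained at score ≥ 80;
  per-locus RPM quantitation; tissue enrichment by one-way ANOVA with
  Tukey contrasts; AGO1/AGO2-loading cross-reference.
* **mRNA-derived small RNA calling** — a gene is a candidate iff one
  unique sequence holds ≥ 10% of its mapped reads *and* the gene carries
  > 1000 reads across a tissue's replicates; reads are assigned to
  5'UTR/CDS/3'UTR strand-awarely and genes classified as sense /
  antisense / sense-antisense.

At its core is an all-hits, both-strand, mismatch-tolerant Hamming mapper
(Rcpp; exact-equality contract against a brute-force oracle) and a
synthetic-data generator that plants all of the structure above in a
desk-scale genome with per-read ground-truth labels, so the entire
pipeline is validated end to end by parameter recovery.

## Worked example

Simulate an ovary-like library (class mixture from the package's
published-tissue presets), classify it, and compute piRNA statistics:

```r
library(srnacensus)

cfg <- sim_config(seed = 1, chromosomes = c("2R" = 3e5, "3L" = 3e5, "X" = 2e5),
                  n_reads = 20000L)
g   <- build_genome(cfg)
sim <- simulate_library(g, tissue = "OV", replicate = 1)
lib <- as_srna_library(sim)
cl  <- classify(lib, sim_references(g))
print(cl)
#> <srna_classification> OV_rep1 (OV rep 1), 20000 reads
#>        miRNA    tRNA_rRNA     TE_piRNA mRNA_derived  unannotated     unmapped
#>         1.27         5.64        34.45         6.01        52.63         0.00

sf <- strand_fractions(cl$te_hits)
up <- unique_pirna_hits(cl)
sprintf("TE-piRNA strand: %.1f%% antisense; %d unique / %d multi mappers",
        100 * sf[["antisense"]], up$n_unique, up$n_multi)
#> "TE-piRNA strand: 76.5% antisense; 1144 unique / 5746 multi mappers"
round(te_class_breakdown(cl$te_hits), 1)
#>    LTR nonLTR    DNA
#>   55.2   35.7    9.1
```

The composition row is the percentage of trimmed reads per class — an
ovary library is dominated by TE-piRNAs and unannotated reads. The strand
fraction recovers the generator's 77% antisense probability and the class
breakdown its 56/35/9 TE-class mixture, within sampling error at this
library size.

`run_pipeline(cfg, "out/")` runs simulate → classify → piRNA → mRNA →
report end to end and writes the composition, size-histogram, depletion,
piRNA, cluster and candidate tables plus a manifest;
`inst/scripts/census.R` wraps it for shell use.

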