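---
title: "The small ncRNA annotation cascade: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The small ncRNA annotation cascade: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnacensus)
```

## The problem

A small RNA-Seq library from an insect tissue is a mixture of several
biologically distinct populations in the 15-50 nt range: microRNAs
(20-25 nt), fragments of tRNA and rRNA (broad, with a 32 nt mode),
PIWI-interacting RNAs targeting transposable elements (25-30 nt), small
RNAs derived from protein-coding transcripts (mode 29 nt), and reads that
map to the genome without matching any annotation. srnacensus implements
the standard way these populations are separated: a *sequential depletion
cascade*. Reads are queried against reference sets in a fixed order, and a
read annotated at one stage is removed before the next stage runs:

1. genome (reads that fail to map are set aside as **unmapped**);
2. mature-miRNA/hairpin reference → **miRNA**;
3. tRNA and rRNA gene models → **tRNA_rRNA**;
4. transposable-element consensus library, allowing up to 2 mismatches →
   **TE_piRNA**;
5. coding gene models → **mRNA_derived**;
6. everything left → **unannotated**.

The order matters: a read matching both a miRNA hairpin and a TE consensus
is a miRNA under this cascade. `classify()` exposes the order as a
parameter (`stage_order`) precisely so that this sensitivity can be
demonstrated and tested, but the shipped default is the order above.

Every statistic in the package is *count-weighted*: reads are collapsed to
unique sequences with occurrence counts, and fractions, histograms and
cluster shares weight each sequence by its count. This matches how small
RNA surveys report read totals.

## Mapping model

The mapper (`map_reads()`) is an all-hits, both-strand Hamming matcher: a
hit is every (reference, offset, strand) whose mismatch count is at most
the stage budget, with N matching nothing (not even another N). Gapped
alignment is deliberately out of scope — small RNA annotation pipelines
match short reads ungapped. Internally, exact stages use a sorted 12-mer
seed index; mismatch-tolerant stages partition the read into
`max_mismatches + 1` segments and seed on each (pigeonhole: a qualifying
alignment has at least one clean segment), falling back to a direct scan
for reads too short to segment or reference sets too small to repay an
index. The implementation strategy is free; its contract is exact
equality with a brute-force scan, which the test suite enforces on
thousands of randomized instances against an independent R oracle.

A read is **unique-mapping** when it has exactly one genomic placement at
its minimum observed mismatch count, **multi-mapping** with two or more;
this minimum-distance convention matches common read-mapper semantics.
Attribution of a read to a single reference (for per-TE tables and AGO
loading counts) takes the best hit, breaking ties by lexicographic
reference id — deterministic if arbitrary, and documented as such.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| adapter, `min_overlap` | — / 8 nt | 3' adapter; minimum exact prefix match; untrimmed reads dropped (configurable) |
| length gate | 15-50 nt | applied after trimming; N-containing reads dropped |
| `genome_mm`, `mirna_mm`, `ncrna_mm`, `mrna_mm` | 0 | per-stage mismatch budgets |
| `te_mm` | 2 | the TE stage allows 2 mismatches |
| homolog filter | >200 reads, 20-25 nt, score ≥ 80, ≤3 mismatches | score = 100 (1 − mm/length) over the best ungapped offset alignment |
| candidate rules | ≥10% top sequence, >1000 reads | both strict as worded: the read floor is exclusive, the fraction inclusive |
| orientation threshold | 0.95 | sense if sense fraction ≥ 0.95; antisense if ≤ 0.05; else sense/antisense |
| cluster bins | 1 Mb, `min_share` 1% | non-overlapping, aligned to 0 |
| heatmap filter | log10(RPM) > 1 on the per-row maximum | rows are tRNA/rRNA genes |
| enrichment α | 0.05 | ANOVA + Tukey; a tissue is enriched only if it is the unique maximum and every pairwise contrast is significant |

The homolog score is a declared proxy for the miRBase SSEARCH cutoff
(">80"); exact SSEARCH parity is out of scope. RPM denominators default to
each library's genome-mapped read total (the defensible reading of
"converted to reads per million"); raw-trimmed totals can be passed
instead. Coordinates are 0-based half-open internally, converted at the
GFF3 (1-based inclusive) and BED boundaries by the I/O layer.

Decisions taken where the method description was silent: untrimmed reads
are dropped by default (keep is a policy option); a read hitting both a
tRNA and an rRNA gene is attributed to tRNA; the miRNA stage matches the
mature/hairpin reference at 0 mismatches rather than re-running a de novo
annotation pipeline; the "unannotated" bin contains only genome-mapped
reads (unmapped is a disjoint column); the hairpin loop length defaults
to 150 nt (hairpin arms in this clade can sit ~150 nt apart).

## The synthetic-data generator

`build_genome()` and `simulate_library()` exist so the whole cascade can
be validated against known truth. The generator plants, in a random
genome: miRNA hairpins (mature arm + loop + reverse-complement arm),
tRNA/rRNA genes with log-normal abundance weights, coding genes with
5'UTR/CDS/3'UTR geometry on both strands, and TE families. Reads are then
drawn per a class mixture with per-class length profiles (miRNA 20-25,
tRNA/rRNA peaking at 32, TE-piRNA 25-30, mRNA-derived peaking at 29,
unannotated peaking at 41 nt), and ground truth (class, source, strand,
offset) is recorded per read.

Three design points deserve emphasis:

* **Reads are exact genomic substrings.** The piRNA 1U/10A biases
  (P(U at position 1) = 0.9 for both orientations, P(A at position 10) =
  0.9 for sense reads) are imposed by *conditional offset sampling* —
  choosing source offsets whose genomic base already yields the desired
  read base — never by substituting bases. Substitution would create
  mismatches against the genome and corrupt the 0-mismatch cascade; offset
  conditioning leaves every mapped-class read a perfect substring, so
  classification errors measure the pipeline, not the generator.
* **Multi-mapping is controlled by copy number.** A TE family with
  `copies = k > 1` is planted as k identical copies, making its exact
  reads multi-mapping by construction; single-copy families produce
  unique mappers. The simulator draws each TE read from the multi-copy
  pool with probability 0.828 (the published ovary multi-mapping
  fraction). Optional per-copy divergence exists but defaults to 0.
* **Cluster shares are planted on single-copy loci.** Unique-mapping reads
  choose a planted cluster (17.7% and 3.3% by default in the piRNA
  preset) or a 40-locus background, each locus confined to its own 1-Mb
  bin. Because shares are measured against 1-Mb bins, the piRNA preset
  uses a ~45 Mb genome (45 distinct bins) so the 79% background spreads
  thinly enough (<2% per bin) that the planted 3.3% cluster remains the
  second-ranked bin; the default preset used for composition studies is a
  lighter ~5.5 Mb. Cluster bins are placed at desk-scale coordinates, not
  at the source survey's literal 58/21 Mb offsets — the recovered
  quantity is the share, not the coordinate.

One printed-data wrinkle: the published per-tissue composition rows are
averages of per-replicate percentages and do not sum exactly to 100
(the ovary row sums to 104.09). A simulation mixture must be a
probability vector, so `tissue_mixtures()` reconciles each row by the
Chebyshev projection onto the simplex — subtracting one common constant
(clipped at zero) from all classes. This keeps every class within ~0.8
points of its printed value, whereas proportional rescaling would move
the largest ovary classes more than 2 points. The choice is recorded here
because it bounds how closely any simulation can reproduce the printed
table.

What the generator does **not** emulate: sequencing error and quality
scores, PCR duplication, the secondary 25-30 nt shoulder the source data
show in ovary unannotated reads, TE nesting/fragmentation, and isomiR
end-heterogeneity. Passing recovery tests therefore demonstrates that the
pipeline's statistics are correct on clean, structurally faithful data —
not that the cascade is robust to base-call noise, which real libraries
would add on top.

## Numerical and degenerate-input choices

Ties in best-hit attribution break lexicographically; a read hitting both
ncRNA biotypes counts as tRNA; two tissues tied at the maximum mean yield
no enrichment call; zero variance everywhere yields F = 0 and no call.
`positional_bias()` columns are renormalized per position and must sum to
1 within 1e-9; empty read sets return an empty matrix with `n_reads = 0`.
Cluster calling sorts by share, then chromosome, then bin start, making
output invariant to input ordering. All simulation randomness derives
from one master seed through a deterministic hash, so genome building and
library simulation are bit-reproducible; seeds stay below 2^31.

## Problem sizes used in validation

The shipped validation suite simulates 100,000-read libraries for the
four tissue presets (10 seeds each) for composition recovery; 20,000
TE-piRNA reads for strand-fraction recovery; 50,000 for TE-class,
multi-mapping, cluster-share, 3'UTR-share and orientation recovery (10
seeds each); and checks the mapper against a brute-force oracle on 1,000
randomized instances. These sizes put binomial sampling error well inside
the recovery tolerances (for example, sd ≈ 0.15 points for a 35% class at
n = 100,000) while keeping a full validation run at desk scale.

## Known limitations

The mapper is ungapped by design and its seed index addresses references
up to 2^28 nt with at most 4096 sequences per set (larger sets fall back
to scanning). The cascade assigns exactly one label per read; reads that
are biologically plural (e.g. a tRNA fragment inside a TE) take the
earliest matching stage. Homolog scoring requires full containment of the
shorter sequence in the longer at some offset; 5'/3' overhanging
alignments are not scored. AGO-loading analysis cross-references
candidate sequences by exact match and does not model IP efficiency.
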