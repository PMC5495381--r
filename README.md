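# syntseg

Conserved-segment detection from pairwise gene-order comparisons, with a
genome-evolution simulator and a recall/precision benchmark.

A **conserved segment** is a maximal run of ancestral genes whose order and
transcriptional orientations were never internally disrupted on any lineage
from the most recent common ancestor (MRCA) down to the two genomes being
compared. Most synteny software reports *synteny blocks* of at least two
markers whose gaps may hide micro-rearranged material; a block with *n*
non-empty gaps actually contains *n + 1* conserved segments, and blocks
miss mono-genic segments entirely. `syntseg` refines gapped synteny
diagonals into accurate, non-overlapping conserved segments — down to
single genes — and quantifies how well they match a simulated truth.

## Method

Two genomes (ordered lists of oriented genes) and a gene-family map (flat
table, or NHX gene trees pruned at the MRCA) define a sparse **homology
matrix**: one cell per same-family gene pair, signed `+` when the homologs
have the same orientation and `-` when opposite. After removing genes with
no homolog in the other genome and collapsing clusters of tandem
duplicates (members separated by at most `tandemGapMax` genes, collapsed
at the first member's position), conserved segments appear as **consistent
diagonals**: chains of same-sign cells, ascending/ascending for `+`,
ascending/descending for `-`, with Chebyshev gaps
`max(|di|, |dj|) - 1 <= gapMax`.

Diagonals are then refined in four steps: micro-rearranged blocks nested
in the gaps of other blocks split their host (`imr`); isolated
opposite-sign cells nested in gaps or adjacent to block edges become
mono-genic conserved segments (`imcs`); small bounding-box overlaps
(`<= truncationMax`) are truncated from the homology-poorer side and
spuriously broken diagonals are re-merged; remaining overlaps are resolved
by a greedy conflict graph that repeatedly keeps the homology-richest
diagonal. Detections are scored against truth as recall
`r = |Tp|/|T|`, precision `p = |Tp|/|D|` and `F1 = 2rp/(r+p)` over three
item kinds: segment extremities (`sX`/`eX`, the 5'/3' ends of gene `X`),
gene adjacencies, and gene names, with or without orientations.

## Worked example

The classic ambiguity: in one lineage gene B was tandemly duplicated in
reverse orientation and the ancestral copy was then deleted — no
rearrangement happened, the true conserved segment spans A..C. The extant
genomes are indistinguishable from a mono-genic inversion of B, so the
detector reports three segments:

```r
library(syntseg)
g1 <- genome("chr", c("a", "b", "c"), c(1, -1, 1), species = "S1")
g2 <- genome("chr", c("x", "y", "z"), c(1,  1, 1), species = "S2")
fams <- family_set(c("A", "B", "C", "A", "B", "C"),
                   c("a", "b", "c", "x", "y", "z"))
fit <- conserved_segments(g1, g2, fams, gapMax = 1)
fit
#> Conserved segments: S1 vs S2
#> gapMax=1 tandemGapMax=5 imr=1 imcs=1 truncationMax=4
#> 3 segments (3 mono-genic) covering 3 homologies
fit$segments
#>   segment_id chrom1 start1 end1 chrom2 start2 end2 sign n_homologies families
#> 1    seg0001    chr      0    1    chr      0    1    1            1      A:+
#> 2    seg0002    chr      1    2    chr      1    2   -1            1      B:+
#> 3    seg0003    chr      2    3    chr      2    3    1            1      C:+
```

Spans are half-open 0-based gene-rank intervals in the input coordinates
of each genome. Scoring those three segments against the true single
segment (oriented extremities `{sA, eC}`) gives recall 100% and precision
33% — the deliberate trade-off of always favouring the mono-genic
inversion reading:

```r
truth <- fit$segments[0, ]                    # same table layout
truth[1, ] <- list("t1", "anc", 0L, 3L, "anc", 0L, 3L, 1L, 2L, "A:+,C:+")
score_items(extract_items(fit, "extremity", TRUE),
            extract_items(truth, "extremity", TRUE))
#> extremity items (oriented): |T|=2 |D|=6 |Tp|=2 |Fp|=4 |Fn|=0
#> recall=1.0000 precision=0.3333 F1=0.5000
```

Simulation and benchmarking:

```r
cfg <- sim_config(n_chrom = 3, genes_per_chrom = 100, seed = 1)
sim <- simulate_evolution(cfg)                 # genomes + exact truth
res <- benchmark_run(cfg, list(conseg_params(gapMax = 1),
                               conseg_params(gapMax = 2)))
```

A thin command-line front end (`inst/scripts/syntseg`) exposes `detect`,
`simulate` and `evaluate` over the same TSV formats.

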