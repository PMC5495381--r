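---
title: "Detecting conserved segments from pairwise gene-order comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved segments from pairwise gene-order comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntseg)
```

## The problem

A *conserved segment* is a run of ancestral genes whose order and
transcriptional orientations were never internally disrupted on any lineage
from an ancestral genome down to the two genomes being compared.  Conserved
segments are the natural unit for rearrangement studies, but most software
reports *synteny blocks*: clusters of at least two markers whose members may
be separated by small gaps hiding micro-rearranged material.  A synteny
block with `n` non-empty gaps actually contains `n + 1` conserved segments,
and blocks of at least two markers systematically miss the mono-genic
conserved segments created by single-gene inversions.

`syntseg` implements a detection pipeline that starts from the classical
gapped-diagonal representation of synteny and refines it into
non-overlapping conserved segments, down to mono-genic ones.  It also ships
a two-lineage genome-evolution simulator that maintains the true conserved
segments event by event, and a recall/precision/F1 benchmark that scores a
detection against that truth.

## Model and representation

Genomes are ordered lists of oriented genes on linear chromosomes; gene
positions are 0-based ranks, and orientation is `+1` when transcription
points toward the end of the chromosome.  Two genes are homologs when they
belong to the same *family*, a family being all descendants of one gene of
the most recent common ancestor (MRCA) of the compared species.  Families
can be supplied as a flat table or derived from NHX gene trees pruned at
the MRCA (`families_from_pruned_trees()`): duplications that predate the
MRCA split a family, duplications after it do not, and trees born after the
MRCA are dropped.

The *homology matrix* of two genomes has one cell per same-family gene
pair, signed `+` when the homologs have equal known orientations and `-`
when opposite; a collapsed tandem cluster with mixed member orientations
yields an unknown representative orientation and hence wildcard cells.  A
*consistent diagonal* is a chain of cells with strictly increasing row
index, strictly monotone column index, uniform sign matching its direction,
and consecutive Chebyshev gaps (`max(|di|, |dj|) - 1`) bounded by `gapMax`.
On perfectly filtered genomes a conserved segment is exactly a gap-free
consistent diagonal; on real genomes, dispersed duplicates scatter
artificial unit gaps through the matrix, which is why `gapMax >= 1` is
needed in practice.

## Pipeline

`conserved_segments(g1, g2, fams, params)` applies, in order:

1. **Filtering** – genes whose family has no member in the other genome are
   removed (`filter_unshared_genes()`).
2. **Tandem collapsing** – same-family genes separated by at most
   `tandemGapMax` genes are clustered by single-linkage chaining and
   rewritten as one representative at the first member's position
   (`cluster_tandem_duplicates()`, `collapse_clusters()`).  The collapsed
   content depends on the reading direction of the chromosome, but the
   segment extremities do not; orientations are taken as read and never
   canonicalised.
3. **Chaining** – `detect_diagonals()` merges cells into maximal consistent
   diagonals, agglomeratively and smallest-junction-gap first, so gap-0
   (strict) diagonals form before any gapped merge.  Ties are broken by
   bounding-box starts, making the output invariant to input order.
4. **Refinements** –
   `identify_micro_rearrangements()` splits a host diagonal where another
   block (two or more homologies) is completely nested in one of its gaps
   on both axes, or nested on exactly one axis with disjoint projections on
   the other; each extremity of the nested block must be within `imrGap` of
   the nearest host homology (measured on the nested axis alone for partial
   nesting, where the orthogonal distance is meaningless).
   `identify_monogenic_segments()` promotes isolated cells to mono-genic
   segments when they are nested in a gap with opposite sign (splitting the
   host), when they lie within `imcsWidth` of a diagonal with opposite
   sign, or when they sit within `imcsWidth` of their sub-matrix edge; a
   same-sign cell near a diagonal is ambient signal and is never promoted.
   `truncate_overlaps()` removes, for bounding-box overlaps of at most
   `truncationMax` gene indices, the overlap-region homologies of the
   poorer diagonal; `merge_truncated_extremities()` re-joins truncated ends
   that chain consistently, repairing spurious ruptures of collinearity;
   `solve_conflict_graph()` resolves all remaining overlaps by greedily
   keeping the homology-richest diagonal and discarding its neighbours
   until the conflict graph is empty.

The final segments are reported with half-open index spans in the input
coordinates of both genomes (the pre-processing keeps a monotone map back
to input positions), an orientation sign, and the oriented family list in
the reference (genome 2) frame.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `gapMax` | 2 | maximum Chebyshev gap inside a diagonal (genes) |
| `tandemGapMax` | 5 | maximum intervening genes inside a tandem cluster |
| `imrGap` | 1 | nested-block extremity gap for micro-rearrangement splits |
| `imcsWidth` | 1 | neighbourhood width for mono-genic identification |
| `truncationMax` | 4 | largest overlap resolved by truncation |

`imrGap`, `imcsWidth` and `truncationMax` can each be disabled (`NA`); an
integer value, even 0, means the option is active.  Disabling
`truncationMax` disables the whole overlap-resolution stage (truncation,
rupture repair and the conflict graph), so the detected diagonals are
returned verbatim.  `tandemGapMax = 5` is the value used throughout the
benchmark; `gapMax` of 1–2 suffices when dispersed duplicates are the only
source of artificial gaps, while real annotations usually require more.

### Determinism and degenerate inputs

Every stage breaks ties by the lexicographic key (chromosome pair,
bounding-box start on axis 1, then axis 2, homology count), so repeated
runs are bit-identical.  Empty genomes, empty matrices, and chromosomes
left empty by filtering are legal everywhere and propagate to empty segment
tables.  In overlap truncation, when both diagonals project a gap onto the
overlap region there is nothing to truncate and the conflict is left to the
graph stage; when only one side has homologies there, that side is
truncated.  Equal in-region counts are resolved toward the diagonal with
fewer homologies overall, then by the deterministic order.

## The simulator and its ground truth

`simulate_evolution()` evolves an ancestral genome along two branches with
inversions, reciprocal translocations, fissions, fusions, duplications
(tandem or dispersed), deletions and de novo births, in a shuffled event
order.  Inversion lengths follow a discretised gamma law (shape 0.1, scale
800 genes) truncated at 1330 genes and renormalised; with these defaults
53.9% of inversions are mono-genic and 63.2% span at most 5 genes under
the untruncated law the discretisation is built from.  Each duplication
copy and each born gene is non-ancestral; the designated ancestral instance
of every gene is tracked explicitly, so the truth remains exact even when
the extant arrangement is ambiguous (a reverse tandem duplication followed
by deletion of the ancestral copy is indistinguishable from a mono-genic
inversion in the data, but not in the registry).

The truth registry holds the ancestral gene order and an intact flag per
adjacency.  Every rearrangement breakpoint cuts the ancestral adjacency it
disrupts — found by scanning to the nearest designated ancestral instances
on each side — and cuts are irreversible; fusions, duplications and births
cut nothing; a deletion removes the gene from the truth in both lineages
and fuses its flanking adjacencies only if both were intact.  Final true
segments are the maximal runs between cuts, written in ancestral
coordinates.

**Breakpoint reuse is not modelled.**  By default (`avoid_bp_reuse`,
`bp_min_sep = 2`) breakpoints are placed uniformly among *eligible* sites
only: chromosome ends and positions whose carried ancestral adjacency is
still intact and at least one adjacency away from any previously used
site, across both lineages; the two breakpoints of a single event are
exempt, so mono-genic inversions remain possible.  Breakpoint reuse in the
empirical literature is a region-level notion, and near-coincident
breakpoints produce extant arrangements that are provably indistinguishable
from conserved ones (two lineages cutting the two adjacencies flanking one
gene strand a mono-genic segment that retains a different ancestral
neighbour in each genome).  Excluding region reuse makes the simulator's
truth fully recoverable in the sparse regime, which is what the recovery
tests exercise; setting `avoid_bp_reuse = FALSE` restores fully uniform
placement.

What the simulator does *not* emulate: assembly and annotation errors,
gene-tree errors, transpositions (available nowhere in the event set),
breakpoint-reuse hotspots, and realistic clustering of event rates along
chromosomes.  Passing the simulation benchmark therefore shows the
pipeline is correct under the generative model, not that real-genome
accuracy will match it.

## What the tests do and do not show

The test suite checks the worked ambiguity scenarios exactly (reverse
tandem duplication plus deletion: oriented-extremity recall 100% and
precision 33%, gene-name precision 66%; breakpoint between tandem
duplicates: extremity recall and precision 66%), the nested-block
refinements (a completely nested block plus nested and adjacent
opposite-sign cells refine to four segments of which one is mono-genic,
plus two promoted cells; a partially nested block yields three diagonals),
and the structural guarantees on simulations: final segments never overlap
on either genome axis (100 seeded evolutions with the full event mix, 3
chromosomes of 60 genes, scaled down from the defaults to keep the suite
fast); perfect recovery of all item kinds on duplication-, deletion- and
birth-free evolutions (3 chromosomes of 200 genes, 6 inversions per
branch, seeds 1–10) — the sparse regime in which rearranged segments do
not interact, which is the hypothesis under which perfect recovery is
attainable at all; chaining equivalence with a subset-enumeration oracle on
1000 random matrices of at most 12 homologies; greedy conflict resolution
maximal and bounded by the exact maximum-weight independent set on 1000
random graphs of at most 10 vertices; and lower extremity recall at
`gapMax = 0` than at `gapMax = 1` in the presence of dispersed duplicates,
asserted on the mean over ten seeded simulations because a dispersed copy
landing on a true cut junction can trade recall the other way on an
individual run.

At higher rearrangement densities perfect recovery is impossible in
principle, not just for this implementation: successive inversions can
restore a previously cut adjacency (a done-and-undone rearrangement), and
scrambled micro-regions admit several event histories with different true
segmentations.  Precision likewise cannot reach 100% in the presence of
duplications, because a reverse tandem duplication followed by deletion of
the ancestral copy reproduces the homology matrix of a mono-genic
inversion exactly; the pipeline deliberately favours the inversion reading,
which maximises recall at a known precision cost.

## Known limitations

The conflict graph is resolved greedily, which guarantees a maximal but
not maximum set of non-overlapping diagonals.  Collapsed tandem clusters
depend on the chromosome reading direction (content, not extremities).
Items are scored on family identifiers, so paralogous copies inherit their
family's identity — the source of the residual false positives discussed
above.  Only pairwise comparisons are supported; nucleotide-level
breakpoint refinement and error simulation are out of scope.
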