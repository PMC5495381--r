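Package: syntseg
Title: Conserved Segment Detection from Pairwise Gene-Order Comparisons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conserved segments (maximal runs of ancestral genes whose
    order and orientation were never internally disrupted) from the comparison
    of two extant genomes represented as ordered lists of oriented genes.
    Builds the sparse signed homology matrix of two genomes, collapses
    clusters of tandem duplicates, chains homologies into gapped consistent
    diagonals (synteny blocks), and refines diagonals into non-overlapping
    conserved segments by identifying micro-rearrangements and mono-genic
    segments, truncating small overlaps, resolving remaining conflicts with a
    greedy weighted conflict graph, and repairing incorrect ruptures of
    collinearity. Includes a two-lineage genome-evolution simulator with
    event-by-event ground-truth segment bookkeeping, gene-family construction
    from NHX gene trees pruned at the most recent common ancestor, and a
    recall/precision/F1 benchmark over segment extremities, gene adjacencies
    and gene names.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
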