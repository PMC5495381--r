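#' Remove genes without a homolog in the other genome
#'
#' First pre-processing step toward "perfectly filtered" genomes: a gene is
#' kept only if its family has at least one member in the other genome.
#' Genes with no family assignment are non-ancestral and always removed.
#' Order and orientations are preserved; chromosomes left empty disappear.
#'
#' @param g1,g2 [genome()] objects.
#' @param fams a [family_set()].
#' @return A list with elements `g1` and `g2`, the filtered genomes (each
#'   retains the `orig` column mapping back to input coordinates).
#' @export
filter_unshared_genes <- function(g1, g2, fams) {
  f1 <- gene_families(g1, fams)
  f2 <- gene_families(g2, fams)
  shared <- intersect(f1[!is.na(f1)], f2[!is.na(f2)])
  out1 <- g1[!is.na(f1) & f1 %in% shared, , drop = FALSE]
  out2 <- g2[!is.na(f2) & f2 %in% shared, , drop = FALSE]
  rownames(out1) <- NULL; rownames(out2) <- NULL
  list(g1 = out1, g2 = out2)
}

#' Cluster tandem duplicates of the same family
#'
#' Two same-family genes on one chromosome belong to the same cluster when at
#' most `tandemGapMax` genes separate them; clusters are closed under
#' single-linkage chaining of this relation, so arbitrarily long tandem
#' arrays collapse to one cluster.  Intervening genes of any family count
#' toward the gap.  Every gene belongs to exactly one cluster (singletons are
#' trivial clusters).  The representative of a cluster sits at the position
#' of its first member; its orientation is the common orientation of the
#' members if they all agree and unknown (`NA`) otherwise.
#'
#' @param g a [genome()] (normally already filtered).
#' @param fams a [family_set()].
#' @param tandemGapMax non-negative integer: maximum number of intervening
#'   genes between chained cluster members.
#' @return A data frame of class `tandem_clustering` with one row per gene:
#'   `chrom`, `index` (0-based position in `g`), `family`, `cluster`
#'   (cluster id), `rep_index` and `rep_orient`.
#' @export
cluster_tandem_duplicates <- function(g, fams, tandemGapMax) {
  stopifnot(tandemGapMax >= 0)
  fam <- gene_families(g, fams)
  idx <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along) - 1L
  # genes lacking a family never cluster; give them unique pseudo-families
  key <- ifelse(is.na(fam), paste0("\r.solo", seq_along(fam)), fam)
  grp <- paste0(g$chrom, "\r", key)
  cluster <- integer(nrow(g))
  rep_index <- integer(nrow(g))
  rep_orient <- integer(nrow(g))
  next_id <- 1L
  for (members in split(seq_len(nrow(g)), grp)) {
    pos <- idx[members]
    o <- order(pos)
    members <- members[o]; pos <- pos[o]
    # chain same-family neighbours separated by <= tandemGapMax genes
    newclust <- c(TRUE, diff(pos) - 1L > tandemGapMax)
    cid <- cumsum(newclust)
    for (k in unique(cid)) {
      mem <- members[cid == k]
      cluster[mem] <- next_id
      rep_index[mem] <- min(idx[mem])
      ors <- unique(g$orient[mem])
      rep_orient[mem] <- if (length(ors) == 1L && !anyNA(ors)) ors else NA_integer_
      next_id <- next_id + 1L
    }
  }
  out <- data.frame(chrom = g$chrom, index = idx, family = fam,
                    cluster = cluster, rep_index = rep_index,
                    rep_orient = rep_orient, stringsAsFactors = FALSE)
  class(out) <- c("tandem_clustering", "data.frame")
  out
}

#' Collapse tandem-duplicate clusters to single representative genes
#'
#' Rewrites the genome so that each cluster is represented by one gene at the
#' location of its first member, carrying the representative orientation;
#' other members are deleted and remaining genes re-indexed compactly.  The
#' `orig` column of the result maps each representative back to the input
#' coordinate of the cluster's first member, so segment spans can be reported
#' in input coordinates.  Collapsing depends on chromosome reading direction,
#' a documented property of the method; orientations as read are never
#' canonicalised.
#'
#' @param g a [genome()].
#' @param clustering result of [cluster_tandem_duplicates()] on `g`.
#' @return A [genome()] with at most one gene per cluster.
#' @export
collapse_clusters <- function(g, clustering) {
  stopifnot(nrow(clustering) == nrow(g))
  idx <- clustering$index
  keep <- idx == clustering$rep_index
  out <- g[keep, , drop = FALSE]
  out$orient <- clustering$rep_orient[keep]
  rownames(out) <- NULL
  out
}

#' Pre-process a pair of genomes for comparison
#'
#' Applies the two pre-processing steps in order: remove genes with no
#' homolog in the other genome, then collapse clusters of tandem duplicates
#' on the filtered genomes (gap counts taken on filtered coordinates).  The
#' alternative order (collapse before filtering, with gap counts on raw
#' coordinates) is available for sensitivity checks.
#'
#' @param g1,g2 [genome()] objects.
#' @param fams a [family_set()].
#' @param tandemGapMax maximum intervening genes within a tandem cluster.
#' @param collapse_first collapse tandem clusters before filtering instead of
#'   after (default `FALSE`).
#' @return list with processed `g1`, `g2`.
#' @export
preprocess_genomes <- function(g1, g2, fams, tandemGapMax = 5L,
                               collapse_first = FALSE) {
  step_collapse <- function(g) {
    collapse_clusters(g, cluster_tandem_duplicates(g, fams, tandemGapMax))
  }
  if (collapse_first) {
    g1 <- step_collapse(g1); g2 <- step_collapse(g2)
    filter_unshared_genes(g1, g2, fams)
  } else {
    flt <- filter_unshared_genes(g1, g2, fams)
    list(g1 = step_collapse(flt$g1), g2 = step_collapse(flt$g2))
  }
}
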