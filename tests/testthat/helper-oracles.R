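# Independent oracles and fixture builders.  Everything here is written
# against the definitions only (no package internals), so it can serve as a
# cross-check of the package's own code paths.

# build a genome pair plus family set from parallel vectors:
# fam1/or1 describe genome 1 gene-by-gene (single chromosome each unless
# chrom vectors given); genes of equal family label are homologs.
mk_pair <- function(fam1, or1, fam2, or2, chrom1 = "c1", chrom2 = "c1") {
  ids <- function(prefix, n) if (n == 0L) character() else paste0(prefix, seq_len(n))
  g1 <- genome(rep_len(chrom1, length(fam1)), ids("a", length(fam1)),
               or1, species = "s1")
  g2 <- genome(rep_len(chrom2, length(fam2)), ids("b", length(fam2)),
               or2, species = "s2")
  fams <- family_set(c(fam1, fam2), c(g1$gene, g2$gene))
  list(g1 = g1, g2 = g2, fams = fams)
}

# ---- brute-force chain oracle ---------------------------------------------
# a set of cells (rows of a data.frame with i, j, sign) forms a consistent
# chain iff, ordered by i: i strictly increasing, j strictly monotone, all
# known signs equal and matching the geometric direction, and consecutive
# Chebyshev gaps <= gapMax.  Written from the definitions, independently of
# the package's chaining code.
oracle_chain_valid <- function(cells, gapMax) {
  k <- nrow(cells)
  if (k == 1L) return(TRUE)
  cells <- cells[order(cells$i), , drop = FALSE]
  di <- diff(cells$i); dj <- diff(cells$j)
  if (any(di < 1L) || any(dj == 0L)) return(FALSE)
  s <- sign(dj[1L])
  if (any(sign(dj) != s)) return(FALSE)
  ks <- cells$sign[!is.na(cells$sign)]
  if (length(ks) > 0L && any(ks != s)) return(FALSE)
  all(pmax(di, abs(dj)) - 1L <= gapMax)
}

# all maximal valid chains (as sorted row-index sets) by subset enumeration;
# feasible for <= 12 cells
oracle_maximal_chains <- function(cells, gapMax) {
  k <- nrow(cells)
  valid <- list()
  for (code in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    if (oracle_chain_valid(cells[idx, , drop = FALSE], gapMax)) {
      valid[[length(valid) + 1L]] <- idx
    }
  }
  is_max <- vapply(seq_along(valid), function(u) {
    !any(vapply(valid, function(v) {
      length(v) > length(valid[[u]]) && all(valid[[u]] %in% v)
    }, FALSE))
  }, FALSE)
  valid[is_max]
}

# can two disjoint chains merge into one valid chain?
oracle_mergeable <- function(cells, idx1, idx2, gapMax) {
  oracle_chain_valid(cells[c(idx1, idx2), , drop = FALSE], gapMax)
}

# random sparse signed matrix as a genome pair whose homology matrix has the
# wanted cells: place k 1-1 families at random distinct (i, j) cells
random_cell_case <- function(k, n1 = 10L, n2 = 10L, wildcard = FALSE) {
  i <- sample.int(n1, k, replace = TRUE) - 1L
  j <- sample.int(n2, k, replace = TRUE) - 1L
  keep <- !duplicated(paste(i, j))
  i <- i[keep]; j <- j[keep]
  sgn <- sample(c(1L, -1L), length(i), replace = TRUE)
  if (wildcard && length(i) > 0L) {
    w <- sample.int(length(i), max(1L, length(i) %/% 6L))
    sgn[w] <- NA_integer_
  }
  data.frame(i = i, j = j, sign = sgn)
}

# ---- brute-force maximum-weight independent set ---------------------------
oracle_mwis <- function(adj, w) {
  k <- length(w)
  best <- 0
  for (code in 0:(2^k - 1L)) {
    idx <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    if (length(idx) >= 2L) {
      if (any(adj[idx, idx])) next
    }
    best <- max(best, sum(w[idx]))
  }
  best
}

# independent set check
oracle_is_independent <- function(adj, idx) {
  length(idx) < 2L || !any(adj[idx, idx])
}

# run detect_diagonals on a raw cell table by synthesising a genome pair:
# genome 1 gets one gene per matrix row index, genome 2 one per column; a
# family per cell is impossible when a gene appears in several cells, so the
# synthesis places one gene per cell occurrence is avoided -- instead we
# construct the homology_matrix object directly with the documented fields.
detect_on_cells <- function(cells, gapMax, n1 = 10L, n2 = 10L) {
  m <- data.frame(chrom1 = "c1", chrom2 = "c1",
                  i = as.integer(cells$i), j = as.integer(cells$j),
                  sign = as.integer(cells$sign),
                  family = paste0("f", seq_len(nrow(cells))),
                  stringsAsFactors = FALSE)
  m <- m[order(m$i, m$j), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "dims1") <- c(c1 = n1)
  attr(m, "dims2") <- c(c1 = n2)
  attr(m, "species") <- c("s1", "s2")
  class(m) <- c("homology_matrix", "data.frame")
  detect_diagonals(m, gapMax)
}

# cell sets (as canonical strings) of the diagonals of a diagonal_set
diag_cell_sets <- function(ds) {
  m <- ds$matrix
  lapply(ds$diagonals, function(d) sort(paste(m$i[d$rows], m$j[d$rows])))
}

# family label of each gene of a genome (NA when unassigned)
gene_families_vec <- function(g, fams) unname(unclass(fams)[g$gene])

# recursive branch-and-bound maximum-weight independent set (exact), fast
# enough for 1000 graphs of <= 10 vertices
oracle_mwis_rec <- function(adj, w) {
  k <- length(w)
  nb <- lapply(seq_len(k), function(v) which(adj[v, ]))
  rec <- function(avail) {
    if (length(avail) == 0L) return(0)
    v <- avail[1L]
    rest <- avail[-1L]
    max(rec(rest), w[v] + rec(setdiff(rest, nb[[v]])))
  }
  rec(seq_len(k))
}
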