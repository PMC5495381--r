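#' Build the sparse signed homology matrix of two genomes
#'
#' One cell per pair of same-family genes.  The matrix is composed of
#' `n1 x n2` chromosome-pair sub-matrices; cells carry a sign: `+1` when the
#' two homologs have the same known orientation, `-1` when opposite, and `NA`
#' (wildcard) when either orientation is unknown.
#'
#' @param g1,g2 [genome()] objects (normally pre-processed; not enforced).
#' @param fams a [family_set()].
#' @return An object of class `homology_matrix`: a data frame with columns
#'   `chrom1`, `chrom2`, `i`, `j` (0-based gene ranks within chromosome) and
#'   `sign`, with attributes `dims1`/`dims2` (chromosome lengths) and the
#'   two species labels.
#' @export
build_homology_matrix <- function(g1, g2, fams) {
  f1 <- gene_families(g1, fams)
  f2 <- gene_families(g2, fams)
  i1 <- stats::ave(seq_len(nrow(g1)), g1$chrom, FUN = seq_along) - 1L
  i2 <- stats::ave(seq_len(nrow(g2)), g2$chrom, FUN = seq_along) - 1L
  a <- which(!is.na(f1)); b <- which(!is.na(f2))
  hit <- merge(
    data.frame(fam = f1[a], r1 = a, stringsAsFactors = FALSE),
    data.frame(fam = f2[b], r2 = b, stringsAsFactors = FALSE),
    by = "fam"
  )
  out <- data.frame(
    chrom1 = g1$chrom[hit$r1], chrom2 = g2$chrom[hit$r2],
    i = i1[hit$r1], j = i2[hit$r2],
    sign = g1$orient[hit$r1] * g2$orient[hit$r2],
    family = hit$fam,
    stringsAsFactors = FALSE
  )
  ord <- order(match(out$chrom1, unique(g1$chrom)),
               match(out$chrom2, unique(g2$chrom)), out$i, out$j)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dims1") <- chrom_lengths(g1)
  attr(out, "dims2") <- chrom_lengths(g2)
  attr(out, "species") <- c(attr(g1, "species"), attr(g2, "species"))
  class(out) <- c("homology_matrix", "data.frame")
  out
}

#' @export
print.homology_matrix <- function(x, ...) {
  cat(sprintf("homology_matrix %s x %s: %d homologies (%d +, %d -, %d wildcard)\n",
              attr(x, "species")[1L], attr(x, "species")[2L], nrow(x),
              sum(x$sign == 1L, na.rm = TRUE), sum(x$sign == -1L, na.rm = TRUE),
              sum(is.na(x$sign))))
  invisible(x)
}

#' Chebyshev gap between two homologies
#'
#' The gap between two cells of the same chromosome-pair sub-matrix is the
#' larger of the two intervening-gene counts on the two genome axes,
#' `max(|di|, |dj|) - 1`.  Adjacent cells have gap 0.
#'
#' @param h1,h2 numeric vectors `c(i, j)` (cell coordinates).
#' @return Integer gap; identical cells are an error (no self-gap).
#' @export
chebyshev_gap <- function(h1, h2) {
  di <- abs(h2[[1L]] - h1[[1L]]); dj <- abs(h2[[2L]] - h1[[2L]])
  if (di == 0 && dj == 0) stop("no gap is defined between identical cells")
  as.integer(max(di, dj) - 1)
}

# candidate merges appending diagonal b after diagonal a, vectorised over b.
# state columns: fi fj li lj (first/last cell coords), ks (known sign),
# gm (geometric direction), both NA-able.
.merge_candidates <- function(st, a, bs, gapMax) {
  if (length(bs) == 0L) return(NULL)
  di <- st$fi[bs] - st$li[a]
  dj <- st$fj[bs] - st$lj[a]
  s <- sign(dj)
  ok <- di >= 1L & dj != 0L
  gap <- pmax(di, abs(dj)) - 1L
  ok <- ok & gap <= gapMax
  compat <- function(v, s) is.na(v) | v == s
  ok <- ok & compat(st$ks[a], s) & compat(st$gm[a], s) &
    compat(st$ks[bs], s) & compat(st$gm[bs], s)
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NULL)
  data.frame(a = a, b = bs[ok], gap = gap[ok], s = s[ok])
}

# greedy smallest-gap-first chaining within one chromosome-pair sub-matrix.
# cells: data.frame(i, j, sign, row) . returns list of list(rows, sign)
.chain_cells <- function(cells, gapMax) {
  k <- nrow(cells)
  st <- data.frame(fi = cells$i, fj = cells$j, li = cells$i, lj = cells$j,
                   ks = cells$sign, gm = NA_integer_, alive = TRUE)
  chains <- lapply(seq_len(k), function(t) cells$row[t])
  cand <- NULL
  for (a in seq_len(k)) {
    cc <- .merge_candidates(st, a, setdiff(seq_len(k), a), gapMax)
    if (!is.null(cc)) cand <- rbind(cand, cc)
  }
  while (!is.null(cand) && nrow(cand) > 0L) {
    # deterministic greedy: smallest junction gap, ties by bounding-box starts
    o <- order(cand$gap, st$fi[cand$a], st$fj[cand$a],
               st$fi[cand$b], st$fj[cand$b], cand$s)
    pick <- cand[o[1L], ]
    a <- pick$a; b <- pick$b; s <- pick$s
    chains[[a]] <- c(chains[[a]], chains[[b]])
    st$li[a] <- st$li[b]; st$lj[a] <- st$lj[b]
    ks <- c(st$ks[a], st$ks[b]); ks <- ks[!is.na(ks)]
    st$ks[a] <- if (length(ks)) ks[1L] else NA_integer_
    st$gm[a] <- s
    st$alive[b] <- FALSE
    chains[b] <- list(NULL)
    cand <- cand[cand$a != a & cand$b != a & cand$a != b & cand$b != b, ,
                 drop = FALSE]
    others <- which(st$alive & seq_len(k) != a)
    cand <- rbind(cand,
                  .merge_candidates(st, a, others, gapMax),
                  do.call(rbind, lapply(others, function(x) {
                    .merge_candidates(st, x, a, gapMax)
                  })))
  }
  alive <- which(st$alive)
  lapply(alive, function(a) {
    list(rows = chains[[a]],
         sign = if (!is.na(st$ks[a])) st$ks[a] else st$gm[a])
  })
}

#' Chain homologies into maximal consistent diagonals
#'
#' Detects candidate synteny blocks: chains of homologies with strictly
#' increasing `i`, strictly monotone `j` (increasing for `+` diagonals,
#' decreasing for `-`), uniform non-wildcard sign, and consecutive Chebyshev
#' gaps at most `gapMax`.  Chaining is agglomerative: starting from
#' single-cell diagonals, the sign-compatible, order-consistent pair of
#' diagonals with the smallest junction gap is merged, repeatedly, until no
#' merge applies; gap-0 merges (strict diagonals) therefore happen first.
#' Wildcard-sign homologies may join either sign of diagonal but never flip
#' an established sign; an all-wildcard diagonal takes its sign from its
#' geometric direction.  Homologies left in no multi-cell diagonal are
#' retained as isolated single-cell diagonals for later mono-genic calling.
#'
#' @param m a [build_homology_matrix()] result.
#' @param gapMax non-negative integer: maximum Chebyshev gap inside a
#'   diagonal.
#' @return An object of class `diagonal_set`: `list(matrix = m, diagonals)`
#'   where each diagonal is `list(rows, sign, chrom1, chrom2, n, promoted,
#'   trunc_start, trunc_end)` and `rows` indexes rows of `m` in chain order.
#' @export
detect_diagonals <- function(m, gapMax) {
  stopifnot(gapMax >= 0)
  diagonals <- list()
  if (nrow(m) > 0L) {
    pair <- paste0(m$chrom1, "\r", m$chrom2)
    for (p in unique(pair)) {
      rows <- which(pair == p)
      cells <- data.frame(i = m$i[rows], j = m$j[rows], sign = m$sign[rows],
                          row = rows)
      cells <- cells[order(cells$i, cells$j), , drop = FALSE]
      chains <- .chain_cells(cells, gapMax)
      for (ch in chains) {
        d <- list(rows = ch$rows, sign = ch$sign,
                  chrom1 = m$chrom1[ch$rows[1L]], chrom2 = m$chrom2[ch$rows[1L]],
                  n = length(ch$rows), promoted = FALSE, kept = FALSE,
                  trunc_start = FALSE, trunc_end = FALSE)
        diagonals[[length(diagonals) + 1L]] <- d
      }
    }
  }
  ds <- list(matrix = m, diagonals = diagonals)
  class(ds) <- "diagonal_set"
  .sort_diagonals(ds)
}

# deterministic ordering of diagonals by (chrom pair, bbox start axis1, axis2,
# homology count); used everywhere a scan order or tie-break is needed.
.sort_diagonals <- function(ds) {
  if (length(ds$diagonals) == 0L) return(ds)
  m <- ds$matrix
  key <- vapply(ds$diagonals, function(d) {
    sprintf("%s\r%s\r%06d\r%06d\r%06d", d$chrom1, d$chrom2,
            min(m$i[d$rows]), min(m$j[d$rows]), d$n)
  }, "")
  ds$diagonals <- ds$diagonals[order(key)]
  ds
}

#' @export
print.diagonal_set <- function(x, ...) {
  n <- vapply(x$diagonals, `[[`, 0L, "n")
  cat(sprintf("diagonal_set: %d diagonals (%d multi-cell, %d isolated cells)\n",
              length(n), sum(n >= 2L), sum(n == 1L)))
  invisible(x)
}

# bounding box of a diagonal: c(i0, i1, j0, j1)
.bbox <- function(m, d) {
  c(min(m$i[d$rows]), max(m$i[d$rows]), min(m$j[d$rows]), max(m$j[d$rows]))
}
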