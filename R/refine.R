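# Post-processing refinements that turn gapped diagonals (synteny blocks)
# into conserved segments: micro-rearrangement splitting, mono-genic segment
# identification, overlap truncation, rupture repair and greedy conflict
# resolution.  All operations take and return a `diagonal_set` and append
# human-readable records to its `trace` (a RefinementTrace).

.get_trace <- function(ds) if (is.null(ds$trace)) list() else ds$trace

.add_trace <- function(ds, record) {
  tr <- .get_trace(ds)
  tr[[length(tr) + 1L]] <- record
  ds$trace <- tr
  ds
}

# gaps of a diagonal: one row per junction between consecutive chain cells,
# with open intervals on both axes (coordinates strictly between the cells)
.diag_gaps <- function(m, d) {
  if (d$n < 2L) {
    return(data.frame(t = integer(), i_lo = integer(), i_hi = integer(),
                      j_lo = integer(), j_hi = integer()))
  }
  ii <- m$i[d$rows]; jj <- m$j[d$rows]
  t <- seq_len(d$n - 1L)
  data.frame(t = t,
             i_lo = ii[t], i_hi = ii[t + 1L],
             j_lo = pmin(jj[t], jj[t + 1L]), j_hi = pmax(jj[t], jj[t + 1L]))
}

# split a diagonal after the chain positions listed in `cuts`
.split_diag <- function(d, cuts) {
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts >= 1L & cuts < d$n]
  if (length(cuts) == 0L) return(list(d))
  bounds <- c(0L, cuts, d$n)
  np <- length(bounds) - 1L
  lapply(seq_len(np), function(k) {
    piece <- d
    piece$rows <- d$rows[(bounds[k] + 1L):bounds[k + 1L]]
    piece$n <- length(piece$rows)
    piece$trunc_start <- if (k == 1L) d$trunc_start else FALSE
    piece$trunc_end <- if (k == np) d$trunc_end else FALSE
    piece$kept <- TRUE                    # pieces of a split block stay segments
    piece
  })
}

# minimum Chebyshev gap from cell (i, j) to any cell of diagonal d
.min_gap_to_diag <- function(m, d, i, j) {
  as.integer(min(pmax(abs(m$i[d$rows] - i), abs(m$j[d$rows] - j))) - 1L)
}

#' Identify micro-rearrangements nested in gaps of other synteny blocks
#'
#' A diagonal A (at least two homologies) is completely nested in a diagonal
#' B when A's bounding box falls inside one gap of B on both axes, and
#' partially nested when it falls inside a gap of B on exactly one axis
#' while the projections on the other axis are disjoint.  Each extremity of
#' A must lie within a Chebyshev gap of at most `imrGap` of the nearest
#' homology of B (for partial nesting the gap is taken on the nested axis).
#' Every host B is split at the insertion location of its nested blocks, so
#' the number of blocks never decreases.
#'
#' @param ds a `diagonal_set` from [detect_diagonals()].
#' @param imrGap non-negative integer.
#' @return The refined `diagonal_set`.
#' @export
identify_micro_rearrangements <- function(ds, imrGap) {
  stopifnot(imrGap >= 0)
  m <- ds$matrix
  dl <- ds$diagonals
  multi <- which(vapply(dl, `[[`, 0L, "n") >= 2L)
  cuts <- vector("list", length(dl))
  for (bx in multi) {
    B <- dl[[bx]]
    gaps <- .diag_gaps(m, B)
    bb <- .bbox(m, B)
    for (ax in multi) {
      if (ax == bx) next
      A <- dl[[ax]]
      if (A$chrom1 != B$chrom1 || A$chrom2 != B$chrom2) next
      ab <- .bbox(m, A)
      in1 <- gaps$i_lo < ab[1L] & ab[2L] < gaps$i_hi
      in2 <- gaps$j_lo < ab[3L] & ab[4L] < gaps$j_hi
      both <- which(in1 & in2)
      a_ends <- A$rows[c(1L, A$n)]
      if (length(both) > 0L) {                    # completely nested
        t <- both[1L]
        egap <- vapply(a_ends, function(r) {
          .min_gap_to_diag(m, B, m$i[r], m$j[r])
        }, 0L)
        if (all(egap <= imrGap)) {
          cuts[[bx]] <- c(cuts[[bx]], t)
          ds <- .add_trace(ds, list(op = "split_micro_rearrangement",
                                    host = bx, nested = ax, gap = t))
        }
        next
      }
      # partially nested: inside a gap on one axis, disjoint on the other
      disj2 <- ab[4L] < bb[3L] || ab[3L] > bb[4L]
      disj1 <- ab[2L] < bb[1L] || ab[1L] > bb[2L]
      t <- NA_integer_; axis <- NA_integer_
      if (any(in1) && disj2) { t <- which(in1)[1L]; axis <- 1L }
      if (is.na(t) && any(in2) && disj1) { t <- which(in2)[1L]; axis <- 2L }
      if (!is.na(t)) {
        egap <- vapply(a_ends, function(r) {
          if (axis == 1L) min(abs(m$i[B$rows] - m$i[r])) - 1L
          else min(abs(m$j[B$rows] - m$j[r])) - 1L
        }, 0L)
        if (all(egap <= imrGap)) {
          cuts[[bx]] <- c(cuts[[bx]], t)
          ds <- .add_trace(ds, list(op = "split_micro_rearrangement",
                                    host = bx, nested = ax, gap = t,
                                    partial = TRUE))
        }
      }
    }
  }
  out <- list()
  for (k in seq_along(dl)) {
    out <- c(out, .split_diag(dl[[k]], cuts[[k]]))
  }
  ds$diagonals <- out
  .sort_diagonals(ds)
}

#' Identify mono-genic conserved segments
#'
#' Promotes isolated homologies (single-cell diagonals) to mono-genic
#' conserved segments when (a) the cell is completely nested in a gap of a
#' multi-cell diagonal whose sign is opposite to the cell's, in which case
#' the host is split around it; or (b) the cell lies within a Chebyshev gap
#' of at most `imcsWidth` of the nearest multi-cell diagonal and their signs
#' differ; or (c) the cell lies within `imcsWidth` of the edge of its
#' chromosome-pair sub-matrix.  An isolated cell whose sign matches the
#' surrounding or nearest diagonal is never promoted (it is ambient signal,
#' not a segment).
#'
#' @param ds a `diagonal_set`.
#' @param imcsWidth non-negative integer neighbourhood width.
#' @return The refined `diagonal_set`; promoted cells are flagged and later
#'   emitted as mono-genic segments.
#' @export
identify_monogenic_segments <- function(ds, imcsWidth) {
  stopifnot(imcsWidth >= 0)
  m <- ds$matrix
  dl <- ds$diagonals
  nn <- vapply(dl, `[[`, 0L, "n")
  multi <- which(nn >= 2L)
  iso <- which(nn == 1L & !vapply(dl, `[[`, FALSE, "promoted"))
  cuts <- vector("list", length(dl))
  dims1 <- attr(m, "dims1"); dims2 <- attr(m, "dims2")
  for (cx in iso) {
    cell <- dl[[cx]]
    r <- cell$rows[1L]
    ci <- m$i[r]; cj <- m$j[r]; cs <- m$sign[r]
    # (a) nested in a gap of a multi-cell diagonal
    nested_host <- NA_integer_; nested_t <- NA_integer_; nested_same <- FALSE
    for (bx in multi) {
      B <- dl[[bx]]
      if (B$chrom1 != cell$chrom1 || B$chrom2 != cell$chrom2) next
      gaps <- .diag_gaps(m, B)
      hit <- which(gaps$i_lo < ci & ci < gaps$i_hi &
                   gaps$j_lo < cj & cj < gaps$j_hi)
      if (length(hit) > 0L) {
        if (!is.na(cs) && !is.na(B$sign) && cs != B$sign) {
          nested_host <- bx; nested_t <- hit[1L]
        } else {
          nested_same <- TRUE
        }
        break
      }
    }
    if (!is.na(nested_host)) {
      dl[[cx]]$promoted <- TRUE
      cuts[[nested_host]] <- c(cuts[[nested_host]], nested_t)
      ds <- .add_trace(ds, list(op = "promote_monogenic", cell = cx,
                                host = nested_host, rule = "nested"))
      next
    }
    if (nested_same) next
    # (b) neighbourhood of the nearest multi-cell diagonal
    same_pair <- multi[vapply(multi, function(bx) {
      dl[[bx]]$chrom1 == cell$chrom1 && dl[[bx]]$chrom2 == cell$chrom2
    }, FALSE)]
    if (length(same_pair) > 0L) {
      gg <- vapply(same_pair, function(bx) {
        .min_gap_to_diag(m, dl[[bx]], ci, cj)
      }, 0L)
      nb <- same_pair[which.min(gg)]
      if (min(gg) <= imcsWidth) {
        if (!is.na(cs) && !is.na(dl[[nb]]$sign) && cs != dl[[nb]]$sign) {
          dl[[cx]]$promoted <- TRUE
          ds <- .add_trace(ds, list(op = "promote_monogenic", cell = cx,
                                    host = nb, rule = "adjacent"))
        }
        next
      }
    }
    # (c) neighbourhood of the sub-matrix edge
    n1 <- dims1[[cell$chrom1]]; n2 <- dims2[[cell$chrom2]]
    if (min(ci, n1 - 1L - ci, cj, n2 - 1L - cj) <= imcsWidth) {
      dl[[cx]]$promoted <- TRUE
      ds <- .add_trace(ds, list(op = "promote_monogenic", cell = cx,
                                rule = "matrix_edge"))
    }
  }
  out <- list()
  for (k in seq_along(dl)) {
    out <- c(out, .split_diag(dl[[k]], cuts[[k]]))
  }
  ds$diagonals <- out
  .sort_diagonals(ds)
}

# diagonals that count as candidate segments for the overlap stages
.active_idx <- function(dl) {
  which(vapply(dl, `[[`, 0L, "n") >= 2L |
          vapply(dl, `[[`, FALSE, "promoted") |
          vapply(dl, function(d) isTRUE(d$kept), FALSE))
}

# overlap of the bounding-box projections of two diagonals on either genome
# axis (including diagonals of different chromosome pairs sharing one
# chromosome).  Returns 0 when disjoint, else the largest per-axis overlap in
# gene indices; `small` additionally requires every positive overlap to be
# <= truncationMax.
.pair_overlap <- function(m, d1, d2) {
  ov <- 0L
  b1 <- .bbox(m, d1); b2 <- .bbox(m, d2)
  if (d1$chrom1 == d2$chrom1) {
    o <- min(b1[2L], b2[2L]) - max(b1[1L], b2[1L]) + 1L
    if (o > 0L) ov <- max(ov, o)
  }
  if (d1$chrom2 == d2$chrom2) {
    o <- min(b1[4L], b2[4L]) - max(b1[3L], b2[3L]) + 1L
    if (o > 0L) ov <- max(ov, o)
  }
  ov
}

#' Truncate small overlaps between diagonals
#'
#' For every pair of diagonals whose bounding-box projections overlap on a
#' genome axis by at most `truncationMax` gene indices, the homologies lying
#' in the overlap region are removed from the diagonal having the fewest
#' homologies inside that region (ties: the diagonal with fewer homologies
#' overall, then the one later in deterministic order).  Diagonals left
#' empty are dropped; a truncation that cuts the interior splits the
#' remainder into its contiguous pieces.  Truncated extremities are recorded
#' so that incorrect ruptures can be repaired later.
#'
#' @param ds a `diagonal_set`.
#' @param truncationMax non-negative integer.
#' @return The refined `diagonal_set`.
#' @export
truncate_overlaps <- function(ds, truncationMax) {
  stopifnot(truncationMax >= 0)
  m <- ds$matrix
  repeat {
    dl <- ds$diagonals
    act <- .active_idx(dl)
    done <- TRUE
    if (length(act) >= 2L) {
      for (u in seq_along(act)) {
        for (v in seq_len(u - 1L)) {
          a <- act[[u]]; b <- act[[v]]
          ov <- .pair_overlap(m, dl[[a]], dl[[b]])
          if (ov < 1L || ov > truncationMax) next
          # cells of each diagonal inside the overlap region
          inreg <- function(d, other) {
            bA <- .bbox(m, d); bB <- .bbox(m, other)
            hit <- rep(FALSE, d$n)
            ii <- m$i[d$rows]; jj <- m$j[d$rows]
            if (d$chrom1 == other$chrom1) {
              lo <- max(bA[1L], bB[1L]); hi <- min(bA[2L], bB[2L])
              if (lo <= hi) hit <- hit | (ii >= lo & ii <= hi)
            }
            if (d$chrom2 == other$chrom2) {
              lo <- max(bA[3L], bB[3L]); hi <- min(bA[4L], bB[4L])
              if (lo <= hi) hit <- hit | (jj >= lo & jj <= hi)
            }
            hit
          }
          ha <- inreg(dl[[a]], dl[[b]]); hb <- inreg(dl[[b]], dl[[a]])
          na_ <- sum(ha); nb_ <- sum(hb)
          # both diagonals project a gap onto the overlap region: nothing to
          # truncate, leave the conflict to the graph stage
          if (na_ == 0L && nb_ == 0L) next
          loser <- if (na_ == 0L) {
            b                             # only actionable truncation
          } else if (nb_ == 0L) {
            a
          } else if (na_ != nb_) {
            if (na_ < nb_) a else b
          } else if (dl[[a]]$n != dl[[b]]$n) {
            if (dl[[a]]$n < dl[[b]]$n) a else b
          } else {
            max(a, b)                     # later in deterministic order
          }
          hit <- if (loser == a) ha else hb
          d <- dl[[loser]]
          keep <- which(!hit)
          ds <- .add_trace(ds, list(op = "truncate", diagonal = loser,
                                    removed = d$rows[hit]))
          pieces <- list()
          if (length(keep) > 0L) {
            runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
            for (rr in runs) {
              piece <- d
              piece$rows <- d$rows[rr]
              piece$n <- length(rr)
              piece$trunc_start <- d$trunc_start || rr[1L] > 1L
              piece$trunc_end <- d$trunc_end || rr[length(rr)] < d$n
              piece$kept <- TRUE
              piece$promoted <- piece$promoted && piece$n == 1L
              pieces[[length(pieces) + 1L]] <- piece
            }
          }
          dl[loser] <- NULL
          dl <- c(dl, pieces)
          ds$diagonals <- dl
          ds <- .sort_diagonals(ds)
          done <- FALSE
          break
        }
        if (!done) break
      }
    }
    if (done) break
  }
  ds
}

#' Repair incorrect ruptures by merging truncated extremities
#'
#' After truncation, a genuine synteny break may have been introduced where
#' none existed; this step merges pairs of diagonals when at least one of
#' the two facing extremities was truncated and the merged chain satisfies
#' all diagonal invariants with junction gap at most `gapMax`.
#'
#' @param ds a `diagonal_set`.
#' @param gapMax maximum Chebyshev junction gap for the repair merge.
#' @return The refined `diagonal_set`.
#' @export
merge_truncated_extremities <- function(ds, gapMax) {
  m <- ds$matrix
  repeat {
    dl <- ds$diagonals
    act <- .active_idx(dl)
    best <- NULL
    for (a in act) {
      for (b in act) {
        if (a == b) next
        da <- dl[[a]]; db <- dl[[b]]
        if (da$chrom1 != db$chrom1 || da$chrom2 != db$chrom2) next
        if (!(da$trunc_end || db$trunc_start)) next
        la <- da$rows[da$n]; fb <- db$rows[1L]
        di <- m$i[fb] - m$i[la]; dj <- m$j[fb] - m$j[la]
        if (di < 1L || dj == 0L) next
        s <- sign(dj)
        gap <- max(di, abs(dj)) - 1L
        if (gap > gapMax) next
        okdir <- function(d) {
          geom <- if (d$n >= 2L) {
            sign(m$j[d$rows[2L]] - m$j[d$rows[1L]])
          } else NA_integer_
          (is.na(d$sign) || d$sign == s) && (is.na(geom) || geom == s)
        }
        if (!okdir(da) || !okdir(db)) next
        if (is.null(best) || gap < best$gap) best <- list(a = a, b = b, gap = gap, s = s)
      }
    }
    if (is.null(best)) break
    a <- best$a; b <- best$b
    da <- dl[[a]]; db <- dl[[b]]
    merged <- da
    merged$rows <- c(da$rows, db$rows)
    merged$n <- length(merged$rows)
    merged$sign <- if (!is.na(da$sign)) da$sign else if (!is.na(db$sign)) db$sign else best$s
    merged$trunc_start <- da$trunc_start
    merged$trunc_end <- db$trunc_end
    merged$promoted <- FALSE
    ds <- .add_trace(ds, list(op = "merge_truncated",
                              rows = list(da$rows, db$rows)))
    dl[[a]] <- merged
    dl[b] <- NULL
    ds$diagonals <- dl
    ds <- .sort_diagonals(ds)
  }
  ds
}

#' Resolve remaining overlaps with a greedy conflict graph
#'
#' Builds the conflict graph whose vertices are overlapping diagonals
#' (bounding-box projections intersecting on either genome axis) and whose
#' edges are overlaps, then repeatedly selects the diagonal with the highest
#' number of homologies, discards its neighbours, automatically selects
#' newly isolated vertices, and continues until the graph is empty.  The
#' result is the union of never-conflicting and selected diagonals and is
#' pairwise non-overlapping on both genome axes; as a greedy maximal (not
#' maximum) independent set it may be suboptimal in total homologies.
#'
#' @param ds a `diagonal_set`.
#' @return The refined `diagonal_set`.
#' @export
solve_conflict_graph <- function(ds) {
  m <- ds$matrix
  dl <- ds$diagonals
  act <- .active_idx(dl)
  k <- length(act)
  if (k < 2L) return(ds)
  adj <- matrix(FALSE, k, k)
  for (u in seq_len(k)) {
    for (v in seq_len(u - 1L)) {
      if (.pair_overlap(m, dl[[act[u]]], dl[[act[v]]]) > 0L) {
        adj[u, v] <- adj[v, u] <- TRUE
      }
    }
  }
  status <- rep("keep", k)                  # never-conflicting stay kept
  inplay <- which(rowSums(adj) > 0L)
  status[inplay] <- "open"
  w <- vapply(dl[act], `[[`, 0L, "n")
  while (any(status == "open")) {
    open <- which(status == "open")
    isolated <- open[rowSums(adj[open, status == "open", drop = FALSE]) == 0L]
    if (length(isolated) > 0L) { status[isolated] <- "keep"; next }
    pick <- open[order(-w[open], open)][1L]  # heaviest, ties by det. order
    status[pick] <- "keep"
    nb <- which(adj[pick, ] & status == "open")
    status[nb] <- "drop"
  }
  dropped <- act[status == "drop"]
  if (length(dropped) > 0L) {
    ds <- .add_trace(ds, list(op = "conflict_graph",
                              discarded_rows = lapply(dl[dropped], `[[`, "rows")))
    ds$diagonals <- dl[-dropped]
    ds <- .sort_diagonals(ds)
  }
  ds
}
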