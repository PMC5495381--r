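# Fig-5-style configurations as genome pairs (see test-acceptance.R for the
# full worked examples); here the refinement operations are exercised alone.

mk_ds <- function(cells, gapMax = 2L, n1 = 20L, n2 = 20L) {
  detect_on_cells(cells, gapMax, n1, n2)
}

test_that("completely nested blocks split their host", {
  # host + diagonal with a purple - block inside its central gap
  cells <- data.frame(i = c(0:1, 4, 6:7, 2, 3),
                      j = c(0:1, 4, 6:7, 3, 2),
                      sign = c(1L, 1L, 1L, 1L, 1L, -1L, -1L))
  ds <- mk_ds(cells)
  expect_length(ds$diagonals, 2L)
  out <- identify_micro_rearrangements(ds, 1L)
  nn <- sort(vapply(out$diagonals, `[[`, 0L, "n"))
  expect_equal(nn, c(2L, 2L, 3L))
  # disjoint, non-nested diagonals are untouched
  cells2 <- data.frame(i = c(0:2, 6:8), j = c(0:2, 6:8), sign = 1L)
  ds2 <- mk_ds(cells2, gapMax = 1L)
  out2 <- identify_micro_rearrangements(ds2, 1L)
  expect_identical(diag_cell_sets(out2), diag_cell_sets(ds2))
})

test_that("partially nested blocks split the host on the nested axis", {
  cells <- data.frame(i = c(0, 1, 4, 5, 2, 3),
                      j = c(0, 1, 2, 3, 5, 4),
                      sign = c(1L, 1L, 1L, 1L, -1L, -1L))
  ds <- mk_ds(cells)
  expect_length(ds$diagonals, 2L)     # host joined across the gap + nested
  out <- identify_micro_rearrangements(ds, 1L)
  expect_length(out$diagonals, 3L)
})

test_that("opposite-sign cells nested in gaps become mono-genic segments", {
  cells <- data.frame(i = c(0, 2, 3, 1), j = c(0, 2, 3, 1),
                      sign = c(1L, 1L, 1L, -1L))
  ds <- mk_ds(cells, gapMax = 1L)
  out <- identify_monogenic_segments(ds, 1L)
  promoted <- Filter(function(d) d$promoted, out$diagonals)
  expect_length(promoted, 1L)
  expect_equal(out$matrix$sign[promoted[[1L]]$rows], -1L)
  # the host is split around the promoted cell
  expect_equal(sort(vapply(out$diagonals, `[[`, 0L, "n")), c(1L, 1L, 2L))
  # a same-sign in-gap cell is NOT promoted (it is ambient signal)
  cells2 <- data.frame(i = c(0, 2, 3, 1), j = c(0, 2, 3, 4),
                       sign = c(1L, 1L, 1L, 1L))
  out2 <- identify_monogenic_segments(mk_ds(cells2, gapMax = 1L), 1L)
  expect_length(Filter(function(d) d$promoted, out2$diagonals), 0L)
})

test_that("neighbourhood and matrix-edge rules promote isolated cells", {
  # opposite-sign cell adjacent to a diagonal extremity
  cells <- data.frame(i = c(0, 1, 2, 3), j = c(0, 1, 2, 3),
                      sign = c(1L, 1L, 1L, -1L))
  out <- identify_monogenic_segments(mk_ds(cells, gapMax = 1L), 1L)
  expect_length(Filter(function(d) d$promoted, out$diagonals), 1L)
  # far interior cell with no neighbouring diagonal: not promoted
  cells2 <- data.frame(i = 9L, j = 9L, sign = 1L)
  out2 <- identify_monogenic_segments(mk_ds(cells2, n1 = 20L, n2 = 20L), 1L)
  expect_length(Filter(function(d) d$promoted, out2$diagonals), 0L)
  # the same cell near the sub-matrix edge is promoted
  cells3 <- data.frame(i = 0L, j = 9L, sign = 1L)
  out3 <- identify_monogenic_segments(mk_ds(cells3, n1 = 20L, n2 = 20L), 1L)
  expect_length(Filter(function(d) d$promoted, out3$diagonals), 1L)
})

test_that("small overlaps are truncated from the homology-poorer side", {
  # two + diagonals overlapping by one column index on axis 2
  cells <- data.frame(i = c(0:3, 10:11), j = c(0:3, 3:4),
                      sign = 1L)
  ds <- mk_ds(cells, gapMax = 0L)
  expect_length(ds$diagonals, 2L)
  out <- truncate_overlaps(ds, 4L)
  nn <- vapply(out$diagonals, `[[`, 0L, "n")
  expect_equal(sort(nn), c(1L, 4L))            # poorer side lost its cell
  removed <- Filter(function(r) r$op == "truncate", out$trace)
  expect_length(removed, 1L)
  # the kept configuration maximises retained homologies over both choices
  expect_equal(sum(nn), nrow(ds$matrix) - 1L)
  # an overlap larger than truncationMax is left alone
  cells2 <- data.frame(i = c(0:5, 10:15), j = c(0:5, 0:5), sign = 1L)
  out2 <- truncate_overlaps(mk_ds(cells2, gapMax = 0L), 4L)
  expect_equal(sort(vapply(out2$diagonals, `[[`, 0L, "n")), c(6L, 6L))
})

test_that("truncated extremities can be re-merged to repair ruptures", {
  # diagonal A ends where diagonal B begins after truncation of B's head
  cells <- data.frame(i = c(0:3, 4:7, 3L), j = c(0:3, 4:7, 8L),
                      sign = c(rep(1L, 8L), 1L))
  ds <- mk_ds(cells, gapMax = 0L)
  tr <- truncate_overlaps(ds, 4L)
  out <- merge_truncated_extremities(tr, 1L)
  nmax <- max(vapply(out$diagonals, `[[`, 0L, "n"))
  expect_gte(nmax, 8L)                         # rupture repaired
  # without truncation the merge step is the identity
  ds2 <- mk_ds(data.frame(i = c(0:2, 6:8), j = c(0:2, 6:8), sign = 1L), 1L)
  expect_identical(diag_cell_sets(merge_truncated_extremities(ds2, 1L)),
                   diag_cell_sets(ds2))
})

test_that("the conflict graph keeps the homology-richest diagonals", {
  # 5-cell vs 3-cell overlapping: the 5-cell one is kept
  cells <- data.frame(i = c(0:4, 10:12), j = c(0:4, 2:4), sign = 1L)
  ds <- mk_ds(cells, gapMax = 0L, n1 = 30L, n2 = 30L)
  out <- solve_conflict_graph(ds)
  expect_equal(vapply(out$diagonals, `[[`, 0L, "n"), 5L)
  # path graph A(3)-B(4)-C(3): greedy keeps only B although A+C is heavier
  cells2 <- data.frame(
    i = c(0:2, 10:13, 20:22),
    j = c(0:2, 2:5, 5:7),
    sign = 1L)
  ds2 <- mk_ds(cells2, gapMax = 0L, n1 = 30L, n2 = 30L)
  expect_length(ds2$diagonals, 3L)
  out2 <- solve_conflict_graph(ds2)
  expect_equal(vapply(out2$diagonals, `[[`, 0L, "n"), 4L)
  adj <- matrix(c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 3L)
  expect_equal(oracle_mwis(adj, c(3, 4, 3)), 6)  # the optimum greedy misses
  # overlap-free input passes through unchanged
  cells3 <- data.frame(i = c(0:1, 10:11), j = c(0:1, 10:11), sign = 1L)
  ds3 <- mk_ds(cells3, gapMax = 0L, n1 = 30L, n2 = 30L)
  expect_identical(diag_cell_sets(solve_conflict_graph(ds3)), diag_cell_sets(ds3))
})

test_that("greedy conflict resolution is maximal and bounded by the optimum", {
  set.seed(77)
  for (case in 1:60) {
    k <- sample(3:8, 1L)
    adj <- matrix(FALSE, k, k)
    for (u in 2:k) for (v in 1:(u - 1L)) {
      if (runif(1) < 0.4) adj[u, v] <- adj[v, u] <- TRUE
    }
    w <- sample(1:9, k, replace = TRUE)
    # simulate the package's greedy on the abstract graph
    status <- rep("open", k)
    status[rowSums(adj) == 0L] <- "keep"
    while (any(status == "open")) {
      open <- which(status == "open")
      iso <- open[rowSums(adj[open, status == "open", drop = FALSE]) == 0L]
      if (length(iso)) { status[iso] <- "keep"; next }
      pick <- open[order(-w[open], open)][1L]
      status[pick] <- "keep"
      status[adj[pick, ] & status == "open"] <- "drop"
    }
    kept <- which(status == "keep")
    expect_true(oracle_is_independent(adj, kept))
    # maximal: every dropped vertex conflicts with a kept one
    for (d in which(status == "drop")) expect_true(any(adj[d, kept]))
    expect_lte(sum(w[kept]), oracle_mwis(adj, w))
  }
})

test_that("the full pipeline respects the option flags", {
  px <- mk_pair(c("A", "B", "C"), c(1L, -1L, 1L), c("A", "B", "C"), c(1L, 1L, 1L))
  # all refinements off: detect_diagonals output converted verbatim
  off <- conserved_segments(px$g1, px$g2, px$fams,
                            params = conseg_params(gapMax = 1L, imrGap = NA,
                                                   imcsWidth = NA,
                                                   truncationMax = NA))
  expect_equal(nrow(off$segments), 1L)           # the joined [A,C] diagonal
  expect_equal(off$segments$n_homologies, 2L)
  # with mono-genic identification the nested inversion is resolved
  on <- conserved_segments(px$g1, px$g2, px$fams, gapMax = 1L)
  expect_equal(nrow(on$segments), 3L)
  expect_equal(sum(on$segments$n_homologies == 1L), 3L)
  # empty input
  e <- conserved_segments(genome(character(), character(), integer()),
                          genome(character(), character(), integer()),
                          family_set(character(), character()))
  expect_equal(nrow(e$segments), 0L)
})

test_that("refinement preserves homology accounting against the trace", {
  set.seed(3)
  cfg <- sim_config(n_chrom = 2L, genes_per_chrom = 60L, inversions = 8L,
                    translocations = 1L, fissions = 0L, fusions = 0L,
                    duplications = 8L, deletions = 4L, births = 3L, seed = 3L)
  sim <- simulate_evolution(cfg)
  fit <- conserved_segments(sim$s1, sim$s2, sim$fams)
  m <- fit$matrix
  kept_rows <- unlist(lapply(fit$diagonals$diagonals, `[[`, "rows"))
  # every reported homology exists in the matrix exactly once
  expect_true(all(kept_rows %in% seq_len(nrow(m))))
  expect_false(any(duplicated(kept_rows)))
  # cells removed by truncation are recorded in the trace
  truncated <- unlist(lapply(Filter(function(r) r$op == "truncate", fit$trace),
                             `[[`, "removed"))
  expect_false(any(truncated %in% kept_rows))
})
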