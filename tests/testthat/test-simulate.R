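test_that("the inversion-length law discretises the gamma distribution", {
  cfg <- sim_config(seed = 1L)
  pmf <- inversion_length_pmf(cfg)
  expect_length(pmf, 1330L)
  expect_equal(sum(pmf), 1)
  # cumulative mass agrees with the gamma cdf renormalised over the support
  cdf <- pgamma(seq_len(1330L), shape = 0.1, scale = 800)
  expect_equal(cumsum(pmf), cdf / cdf[1330L], tolerance = 1e-12)
  # untruncated reference values: 53.9% mono-genic, 63.2% at most 5 genes
  expect_equal(round(100 * pgamma(c(1, 2, 5), 0.1, scale = 800), 1),
               c(53.9, 57.7, 63.2))
  set.seed(2)
  draws <- sample_inversion_length(cfg, 1e4L)
  expect_true(all(draws >= 1L & draws <= 1330L))
})

test_that("sampled inversion lengths fit the configured pmf", {
  cfg <- sim_config(seed = 1L)
  set.seed(99)
  draws <- sample_inversion_length(cfg, 1e5L)
  breaks <- c(0.5, 1.5, 2.5, 5.5, 20.5, 100.5, 1330.5)
  obs <- table(cut(draws, breaks))
  pmf <- inversion_length_pmf(cfg)
  expt <- diff(c(0, cumsum(pmf)[c(1, 2, 5, 20, 100, 1330)]))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = expt))
  expect_gt(gof$p.value, 1e-3)
})

test_that("a zero-event simulation conserves every chromosome", {
  cfg <- sim_config(n_chrom = 2L, genes_per_chrom = 5L, inversions = 0L,
                    translocations = 0L, fissions = 0L, fusions = 0L,
                    duplications = 0L, deletions = 0L, births = 0L, seed = 4L)
  sim <- simulate_evolution(cfg)
  expect_equal(nrow(sim$truth), 2L)
  expect_equal(sim$truth$n_homologies, c(5L, 5L))
  expect_equal(sim$s1$gene, sim$ancestor$gene)
  expect_equal(sim$s2$orient, sim$ancestor$orient)
})

test_that("the registry splits at breakpoints and removes deleted genes", {
  reg <- syntseg:::.registry_new(list(c("A", "B", "C")))
  anc <- list(chr1 = data.frame(id = c("A", "B", "C"), fam = c("A", "B", "C"),
                                anc = c("A", "B", "C"), orient = c(1L, 1L, 1L),
                                stringsAsFactors = FALSE))
  # mono-genic inversion of B: breakpoints on both sides -> three segments
  regA <- syntseg:::.registry_cut(reg, "A", "B")
  regA <- syntseg:::.registry_cut(regA, "B", "C")
  segA <- syntseg:::.registry_segments(regA, anc)
  expect_equal(nrow(segA), 3L)
  expect_equal(segA$families, c("A:+", "B:+", "C:+"))
  # reverse tandem duplication of B then deletion of the ancestral copy:
  # no breakpoint, one conserved segment spanning A..C without B
  regB <- syntseg:::.registry_delete(reg, "B")
  segB <- syntseg:::.registry_segments(regB, anc)
  expect_equal(nrow(segB), 1L)
  expect_equal(segB$families, "A:+,C:+")
  expect_equal(c(segB$start1, segB$end1), c(0L, 3L))
  # cutting a non-adjacent pair changes nothing; segments never re-join
  regC <- syntseg:::.registry_cut(reg, "A", "C")
  expect_identical(regC, reg)
})

test_that("breakpoints through non-ancestral genes cut the carried adjacency", {
  # extant chromosome A, C.copy, B with the copy non-ancestral: a breakpoint
  # between the copy and B cuts the ancestral A|B adjacency
  chrom <- data.frame(id = c("A", "Ccopy", "B"), fam = c("A", "C", "B"),
                      anc = c("A", NA, "B"), orient = 1L,
                      stringsAsFactors = FALSE)
  reg <- syntseg:::.registry_new(list(c("A", "B", "C")))
  reg2 <- syntseg:::.bp_cut(reg, chrom, 2L)
  expect_false(reg2[[1L]]$intact[1L])
  expect_true(reg2[[1L]]$intact[2L])
  # a breakpoint at the chromosome end cuts nothing
  expect_identical(syntseg:::.bp_cut(reg, chrom, 0L), reg)
  expect_identical(syntseg:::.bp_cut(reg, chrom, 3L), reg)
})

test_that("true segments are contiguous and collinear in both extant genomes", {
  cfg <- sim_config(n_chrom = 3L, genes_per_chrom = 60L, inversions = 10L,
                    translocations = 2L, fissions = 1L, fusions = 1L,
                    duplications = 10L, deletions = 6L, births = 4L, seed = 11L)
  sim <- simulate_evolution(cfg)
  truth <- sim$truth
  # partition: every surviving ancestral gene lies in exactly one segment
  genes <- unlist(lapply(strsplit(truth$families, ","), sub,
                         pattern = ":[+-]$", replacement = ""))
  expect_false(any(duplicated(genes)))
  for (gnm in c("s1", "s2")) {
    g <- as.data.frame(sim[[gnm]])
    seg_of <- rep(seq_len(nrow(truth)),
                  lengths(strsplit(truth$families, ",")))
    pos <- match(genes, g$gene)
    present <- !is.na(pos)
    for (s in seq_len(nrow(truth))) {
      sel <- which(seg_of == s & present)
      if (length(sel) < 2L) next
      p <- pos[sel]
      expect_length(unique(g$chrom[p]), 1L)
      # in ancestral order or exactly reversed
      expect_true(all(diff(p) > 0) || all(diff(p) < 0))
      # no gene of another segment interleaves
      rng <- seq(min(p), max(p))
      inside <- pos[present & seg_of != s]
      expect_false(any(inside %in% rng))
    }
  }
})

test_that("deleting an ancestral gene in one lineage removes it from the truth", {
  cfg <- sim_config(n_chrom = 2L, genes_per_chrom = 40L, inversions = 0L,
                    translocations = 0L, fissions = 0L, fusions = 0L,
                    duplications = 0L, deletions = 8L, births = 0L, seed = 21L)
  sim <- simulate_evolution(cfg)
  genes <- unlist(lapply(strsplit(sim$truth$families, ","), sub,
                         pattern = ":[+-]$", replacement = ""))
  deleted <- setdiff(sim$ancestor$gene, c(sim$s1$gene, sim$s2$gene))
  lost1 <- setdiff(sim$ancestor$gene, sim$s1$gene)
  lost2 <- setdiff(sim$ancestor$gene, sim$s2$gene)
  expect_false(any(c(lost1, lost2) %in% genes))
  expect_setequal(genes, setdiff(sim$ancestor$gene, union(lost1, lost2)))
})

test_that("emitted benchmark cases are reproducible and round-trip", {
  cfg <- sim_config(n_chrom = 2L, genes_per_chrom = 30L, inversions = 4L,
                    translocations = 1L, fissions = 0L, fusions = 0L,
                    duplications = 4L, deletions = 2L, births = 2L, seed = 6L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim <- emit_benchmark_case(cfg, d1)
  emit_benchmark_case(cfg, d2)
  for (f in c("s1.tsv", "s2.tsv", "families.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the output with overwhelming probability
  d3 <- withr::local_tempdir()
  emit_benchmark_case(sim_config(n_chrom = 2L, genes_per_chrom = 30L,
                                 inversions = 4L, translocations = 1L,
                                 fissions = 0L, fusions = 0L,
                                 duplications = 4L, deletions = 2L,
                                 births = 2L, seed = 7L), d3)
  expect_false(identical(readLines(file.path(d1, "s1.tsv")),
                         readLines(file.path(d3, "s1.tsv"))))
  # loadable by the package's own readers
  g1 <- load_genome(file.path(d1, "s1.tsv"))
  expect_identical(as.data.frame(g1)[, c("chrom", "gene", "orient")],
                   as.data.frame(sim$s1)[, c("chrom", "gene", "orient")])
  expect_identical(load_families(file.path(d1, "families.tsv")), sim$fams)
  tt <- load_segments(file.path(d1, "truth.tsv"))
  expect_equal(tt$families, sim$truth$families)
})
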