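#' Configuration of the two-lineage genome-evolution simulator
#'
#' Describes the ancestral genome and the numbers of events applied
#' independently on each of the two branches descending from the most
#' recent common ancestor.  Events are chromosomal rearrangements
#' (inversions, reciprocal translocations, fissions, fusions) and genic
#' events (gene duplications -- tandem or dispersed --, gene deletions,
#' de novo gene births).  Inversion lengths follow a discretised gamma
#' distribution (shape 0.1, scale 800 genes, truncated after 1330 genes).
#'
#' @param n_chrom number of ancestral chromosomes.
#' @param genes_per_chrom genes per ancestral chromosome (scalar or vector
#'   of length `n_chrom`).
#' @param inversions,translocations,fissions,fusions rearrangement counts
#'   per branch.
#' @param duplications,deletions,births genic event counts per branch.
#' @param tandem_frac fraction of duplications inserted in tandem (the rest
#'   are dispersed); tandem duplication is substantial in vertebrates
#'   (roughly 40--70% of duplications).
#' @param tandem_offset_max maximum number of genes between a tandem copy
#'   and its source (0 inserts the copy adjacent to the source).
#' @param dup_reverse_prob probability that a tandem copy is inserted in
#'   reverse orientation.
#' @param inv_shape,inv_scale,inv_trunc inversion-length law: gamma shape,
#'   scale (in genes) and truncation length.
#' @param avoid_bp_reuse when `TRUE` (default), rearrangement breakpoints
#'   are placed uniformly among *eligible* sites only: chromosome ends and
#'   inter-gene positions carrying a still-intact ancestral adjacency, so no
#'   breakpoint site is ever reused within or across lineages (breakpoint
#'   reuse is not modelled).
#' @param bp_min_sep minimal separation, in adjacency steps, between
#'   breakpoints of *different* rearrangement events when `avoid_bp_reuse`
#'   is on: 1 excludes exact-site reuse only; the default 2 also excludes
#'   the immediately flanking adjacencies, i.e. breakpoint regions of one
#'   gene are never reused.  The two breakpoints of a single event (e.g. a
#'   mono-genic inversion) are exempt.
#' @param seed integer random seed; identical seeds give identical
#'   simulations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 5L, genes_per_chrom = 100L,
                       inversions = 30L, translocations = 3L,
                       fissions = 1L, fusions = 1L,
                       duplications = 25L, deletions = 15L, births = 10L,
                       tandem_frac = 0.5, tandem_offset_max = 0L,
                       dup_reverse_prob = 0.5,
                       inv_shape = 0.1, inv_scale = 800, inv_trunc = 1330L,
                       avoid_bp_reuse = TRUE, bp_min_sep = 2L, seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              genes_per_chrom = as.integer(rep_len(genes_per_chrom, n_chrom)),
              inversions = as.integer(inversions),
              translocations = as.integer(translocations),
              fissions = as.integer(fissions), fusions = as.integer(fusions),
              duplications = as.integer(duplications),
              deletions = as.integer(deletions), births = as.integer(births),
              tandem_frac = tandem_frac,
              tandem_offset_max = as.integer(tandem_offset_max),
              dup_reverse_prob = dup_reverse_prob,
              inv_shape = inv_shape, inv_scale = inv_scale,
              inv_trunc = as.integer(inv_trunc),
              avoid_bp_reuse = isTRUE(avoid_bp_reuse),
              bp_min_sep = as.integer(bp_min_sep), seed = as.integer(seed))
  stopifnot(cfg$n_chrom >= 1L, all(cfg$genes_per_chrom >= 1L),
            cfg$inversions >= 0L, cfg$translocations >= 0L,
            cfg$fissions >= 0L, cfg$fusions >= 0L, cfg$duplications >= 0L,
            cfg$deletions >= 0L, cfg$births >= 0L,
            cfg$tandem_frac >= 0, cfg$tandem_frac <= 1,
            cfg$inv_shape > 0, cfg$inv_scale > 0, cfg$inv_trunc >= 1L)
  class(cfg) <- "sim_config"
  cfg
}

#' Sample inversion lengths from the discretised gamma law
#'
#' The probability of an integer length `L` is proportional to the gamma
#' cumulative distribution increment `F(L) - F(L-1)` (shape `inv_shape`,
#' scale `inv_scale`), renormalised over the truncated support
#' `1..inv_trunc`.  With the default parameters the untruncated law puts
#' 53.9% of its mass on mono-genic inversions and 63.2% on lengths of at
#' most 5 genes.
#'
#' @param cfg a [sim_config()].
#' @param n number of samples.
#' @return Integer vector of lengths in `[1, inv_trunc]`.
#' @export
sample_inversion_length <- function(cfg, n = 1L) {
  pmf <- inversion_length_pmf(cfg)
  sample.int(cfg$inv_trunc, n, replace = TRUE, prob = pmf)
}

#' @rdname sample_inversion_length
#' @export
inversion_length_pmf <- function(cfg) {
  l <- seq_len(cfg$inv_trunc)
  p <- stats::pgamma(l, shape = cfg$inv_shape, scale = cfg$inv_scale) -
    stats::pgamma(l - 1, shape = cfg$inv_shape, scale = cfg$inv_scale)
  p / sum(p)
}

# ---- ground-truth registry -------------------------------------------------
# ancestral chromosomes as fixed gene vectors; per chromosome: alive flags
# and intact flags for the adjacencies between consecutive *alive* genes.
# Segments are never re-joined once cut; deleting a gene joins its flanking
# adjacencies (intact only if both were).

.registry_new <- function(chrom_genes) {
  lapply(chrom_genes, function(g) {
    list(genes = g, intact = rep(TRUE, max(0L, length(g) - 1L)))
  })
}

.registry_cut <- function(reg, a, b) {
  for (k in seq_along(reg)) {
    pa <- match(a, reg[[k]]$genes); pb <- match(b, reg[[k]]$genes)
    if (!is.na(pa) && !is.na(pb) && abs(pa - pb) == 1L) {
      reg[[k]]$intact[min(pa, pb)] <- FALSE
      return(reg)
    }
  }
  reg                                   # not currently adjacent: nothing new
}

.registry_delete <- function(reg, gene) {
  for (k in seq_along(reg)) {
    p <- match(gene, reg[[k]]$genes)
    if (is.na(p)) next
    g <- reg[[k]]$genes; it <- reg[[k]]$intact
    n <- length(g)
    newit <- if (n <= 1L) logical() else if (p == 1L) it[-1L] else if (p == n)
      it[-(n - 1L)] else c(it[seq_len(p - 2L)], it[p - 1L] && it[p],
                           if (p < n - 1L) it[(p + 1L):(n - 1L)])
    reg[[k]]$genes <- g[-p]
    reg[[k]]$intact <- newit
    return(reg)
  }
  reg
}

# ---- simulator -------------------------------------------------------------

# lineage chromosomes are data.frames: id, fam (family or NA for births'
# descendants handled via fam string), anc (ancestral gene id or NA), orient

.bp_cut <- function(reg, chrom, k) {
  # breakpoint between rows k and k+1 of `chrom` (k in 0..nrow): cut the
  # ancestral adjacency carried at this position, if any is still intact
  n <- nrow(chrom)
  if (k <= 0L || k >= n) return(reg)
  left <- chrom$anc[seq_len(k)]
  right <- chrom$anc[(k + 1L):n]
  a <- rev(left[!is.na(left)])[1L]
  b <- right[!is.na(right)][1L]
  if (is.na(a) || is.na(b)) return(reg)
  .registry_cut(reg, a, b)
}

.flip_chrom <- function(df) {
  df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  df$orient <- -df$orient
  rownames(df) <- NULL
  df
}

# canonical keys of the ancestral adjacencies eligible for a fresh
# breakpoint: still intact, and (for sep >= 2) with no cut adjacency within
# sep - 1 steps on either side
.intact_keys <- function(reg, sep = 1L) {
  unlist(lapply(reg, function(ch) {
    n <- length(ch$genes)
    if (n < 2L) return(character())
    it <- ch$intact
    ok <- it
    if (sep >= 2L) {
      for (d in seq_len(sep - 1L)) {
        left <- c(rep(TRUE, d), it[seq_len(length(it) - d)])
        right <- c(it[seq_len(length(it))[-seq_len(d)]], rep(TRUE, d))
        ok <- ok & left & right
      }
    }
    k <- which(ok)
    paste(pmin(ch$genes[k], ch$genes[k + 1L]),
          pmax(ch$genes[k], ch$genes[k + 1L]))
  }), use.names = FALSE)
}

# eligibility of the n+1 breakpoint positions of one chromosome (boundary b
# before row b+1 maps to index b+1): chromosome ends, or positions whose
# carried ancestral adjacency is still intact (a fresh breakpoint site)
.elig_bounds <- function(df, keys) {
  n <- nrow(df)
  out <- rep(FALSE, n + 1L)
  out[c(1L, n + 1L)] <- TRUE
  if (n >= 2L) {
    la <- df$anc
    for (t in seq_len(n)[-1L]) if (is.na(la[t])) la[t] <- la[t - 1L]
    ra <- df$anc
    for (t in rev(seq_len(n - 1L))) if (is.na(ra[t])) ra[t] <- ra[t + 1L]
    a <- la[seq_len(n - 1L)]
    b <- ra[seq_len(n - 1L) + 1L]
    ok <- !is.na(a) & !is.na(b) & paste(pmin(a, b), pmax(a, b)) %in% keys
    out[seq_len(n - 1L) + 1L] <- ok
  }
  out
}

#' Simulate the evolution of an ancestral genome to two extant species
#'
#' Builds an ancestral genome, applies the configured numbers of events
#' (shuffled order) independently along the two branches to the extant
#' species, and maintains the ground-truth conserved segments event by
#' event: every rearrangement breakpoint cuts the ancestral adjacency it
#' disrupts (fusions, duplications and births alter no conserved segment),
#' and an ancestral gene deleted in either lineage is removed from the
#' truth.  Each duplication copy and each born gene is non-ancestral; the
#' designated ancestral instance of every gene is tracked so the truth is
#' exact even when extant arrangements are ambiguous.
#'
#' @param cfg a [sim_config()].
#' @return A list: `ancestor`, `s1`, `s2` ([genome()]s), `fams` (the
#'   [family_set()] restricted to ancestral families), and `truth` (the true
#'   conserved segments as a `conseg_segments` table in ancestral
#'   coordinates, plus the raw registry as attribute `registry`).
#' @export
simulate_evolution <- function(cfg) {
  set.seed(cfg$seed)
  total <- sum(cfg$genes_per_chrom)
  ids <- sprintf("g%05d", seq_len(total))
  chrom_of <- rep(seq_len(cfg$n_chrom), cfg$genes_per_chrom)
  orient <- sample(c(1L, -1L), total, replace = TRUE)
  anc_chroms <- lapply(seq_len(cfg$n_chrom), function(k) {
    sel <- chrom_of == k
    data.frame(id = ids[sel], fam = ids[sel], anc = ids[sel],
               orient = orient[sel], stringsAsFactors = FALSE)
  })
  names(anc_chroms) <- sprintf("chr%d", seq_len(cfg$n_chrom))
  reg <- .registry_new(lapply(anc_chroms, `[[`, "id"))

  counter <- 0L
  evlog <- list()
  evolve_branch <- function(chroms, branch) {
    events <- c(rep("inv", cfg$inversions), rep("tra", cfg$translocations),
                rep("fis", cfg$fissions), rep("fus", cfg$fusions),
                rep("dup", cfg$duplications), rep("del", cfg$deletions),
                rep("bir", cfg$births))
    events <- sample(events)
    newchr <- 0L
    lens <- function() vapply(chroms, nrow, 0L)
    pick_pos <- function() {
      # uniform gene position genome-wide: (chromosome, row)
      l <- lens()
      g <- sample.int(sum(l), 1L)
      k <- findInterval(g, cumsum(l), left.open = TRUE) + 1L
      list(k = k, p = g - c(0L, cumsum(l))[k])
    }
    for (ev in events) {
      l <- lens()
      if (ev == "inv") {
        # draw a length, then a uniform placement among eligible breakpoint
        # sites; a length with no eligible placement is re-drawn
        keys <- if (cfg$avoid_bp_reuse) .intact_keys(reg, cfg$bp_min_sep) else NULL
        eligs <- if (cfg$avoid_bp_reuse)
          lapply(chroms, .elig_bounds, keys = keys) else NULL
        placed <- NULL
        for (try_ in seq_len(100L)) {
          L <- sample_inversion_length(cfg)
          ks <- integer(); ps <- integer()
          for (k in seq_along(chroms)) {
            if (l[k] < L) next
            pp <- seq_len(l[k] - L + 1L)
            if (cfg$avoid_bp_reuse) {
              e <- eligs[[k]]
              pp <- pp[e[pp] & e[pp + L]]
            }
            ks <- c(ks, rep(k, length(pp))); ps <- c(ps, pp)
          }
          if (length(ps) > 0L) {
            pick <- if (length(ps) == 1L) 1L else sample.int(length(ps), 1L)
            placed <- list(k = ks[pick], p = ps[pick], L = L)
            break
          }
        }
        if (is.null(placed)) stop("inversion infeasible: no eligible breakpoint placement")
        k <- placed$k; p <- placed$p; L <- placed$L
        q <- p + L - 1L
        evlog[[length(evlog) + 1L]] <<- list(branch = branch, type = "inv",
          chrom = names(chroms)[k], from = p, to = q, L = L,
          chrom_len = l[k], genes = chroms[[k]]$id[c(p, q)])
        reg <<- .bp_cut(reg, chroms[[k]], p - 1L)
        reg <<- .bp_cut(reg, chroms[[k]], q)
        df <- chroms[[k]]
        df[p:q, ] <- .flip_chrom(df[p:q, , drop = FALSE])
        chroms[[k]] <- df
      } else if (ev == "tra") {
        if (length(chroms) < 2L) stop("translocation infeasible: < 2 chromosomes")
        ks <- sample(length(chroms), 2L)
        k1 <- ks[1L]; k2 <- ks[2L]
        pickb <- function(k) {
          cand <- 0L:l[k]
          if (cfg$avoid_bp_reuse) {
            e <- .elig_bounds(chroms[[k]], .intact_keys(reg, cfg$bp_min_sep))
            cand <- cand[e[cand + 1L]]
          }
          if (length(cand) == 1L) cand else sample(cand, 1L)
        }
        b1 <- pickb(k1); b2 <- pickb(k2)
        evlog[[length(evlog) + 1L]] <<- list(branch = branch, type = "tra",
          chroms = names(chroms)[ks], at = c(b1, b2))
        reg <<- .bp_cut(reg, chroms[[k1]], b1)
        reg <<- .bp_cut(reg, chroms[[k2]], b2)
        h1 <- chroms[[k1]][seq_len(b1), , drop = FALSE]
        t1 <- chroms[[k1]][seq_len(l[k1]) > b1, , drop = FALSE]
        h2 <- chroms[[k2]][seq_len(b2), , drop = FALSE]
        t2 <- chroms[[k2]][seq_len(l[k2]) > b2, , drop = FALSE]
        chroms[[k1]] <- rbind(h1, t2)
        chroms[[k2]] <- rbind(h2, t1)
        chroms <- chroms[vapply(chroms, nrow, 0L) > 0L]
      } else if (ev == "fis") {
        keys <- if (cfg$avoid_bp_reuse) .intact_keys(reg, cfg$bp_min_sep) else NULL
        cand_k <- integer(); cand_b <- integer()
        for (k in which(l >= 2L)) {
          bb <- seq_len(l[k] - 1L)
          if (cfg$avoid_bp_reuse) {
            e <- .elig_bounds(chroms[[k]], keys)
            bb <- bb[e[bb + 1L]]
          }
          cand_k <- c(cand_k, rep(k, length(bb))); cand_b <- c(cand_b, bb)
        }
        if (length(cand_b) == 0L) stop("fission infeasible: no eligible breakpoint")
        pick <- if (length(cand_b) == 1L) 1L else sample.int(length(cand_b), 1L)
        k <- cand_k[pick]; b <- cand_b[pick]
        evlog[[length(evlog) + 1L]] <<- list(branch = branch, type = "fis",
          chrom = names(chroms)[k], at = b)
        reg <<- .bp_cut(reg, chroms[[k]], b)
        newchr <- newchr + 1L
        nm <- sprintf("%s_fis%d", branch, newchr)
        chroms[[nm]] <- chroms[[k]][(b + 1L):l[k], , drop = FALSE]
        chroms[[k]] <- chroms[[k]][seq_len(b), , drop = FALSE]
      } else if (ev == "fus") {
        if (length(chroms) < 2L) stop("fusion infeasible: < 2 chromosomes")
        ks <- sample(length(chroms), 2L)
        second <- chroms[[ks[2L]]]
        if (stats::runif(1L) < 0.5) second <- .flip_chrom(second)
        chroms[[ks[1L]]] <- rbind(chroms[[ks[1L]]], second)
        chroms <- chroms[-ks[2L]]
      } else if (ev == "dup") {
        pos <- pick_pos()
        src <- chroms[[pos$k]][pos$p, ]
        counter <<- counter + 1L
        copy <- data.frame(id = sprintf("%s_d%05d", branch, counter),
                           fam = src$fam, anc = NA_character_,
                           orient = src$orient, stringsAsFactors = FALSE)
        if (stats::runif(1L) < cfg$tandem_frac) {
          if (stats::runif(1L) < cfg$dup_reverse_prob) copy$orient <- -copy$orient
          off <- if (cfg$tandem_offset_max > 0L)
            sample(0L:cfg$tandem_offset_max, 1L) else 0L
          at <- min(pos$p + off, nrow(chroms[[pos$k]]))
          df <- chroms[[pos$k]]
          chroms[[pos$k]] <- rbind(df[seq_len(at), , drop = FALSE], copy,
                                   df[seq_len(nrow(df)) > at, , drop = FALSE])
        } else {
          ins <- pick_pos()
          at <- sample(0L:nrow(chroms[[ins$k]]), 1L)
          if (stats::runif(1L) < 0.5) copy$orient <- -copy$orient
          df <- chroms[[ins$k]]
          chroms[[ins$k]] <- rbind(df[seq_len(at), , drop = FALSE], copy,
                                   df[seq_len(nrow(df)) > at, , drop = FALSE])
        }
      } else if (ev == "del") {
        pos <- pick_pos()
        victim <- chroms[[pos$k]][pos$p, ]
        if (!is.na(victim$anc)) reg <<- .registry_delete(reg, victim$anc)
        chroms[[pos$k]] <- chroms[[pos$k]][-pos$p, , drop = FALSE]
        chroms <- chroms[vapply(chroms, nrow, 0L) > 0L]
      } else if (ev == "bir") {
        counter <<- counter + 1L
        born <- data.frame(id = sprintf("%s_n%05d", branch, counter),
                           fam = sprintf("%s_n%05d", branch, counter),
                           anc = NA_character_,
                           orient = sample(c(1L, -1L), 1L),
                           stringsAsFactors = FALSE)
        ins <- pick_pos()
        at <- sample(0L:nrow(chroms[[ins$k]]), 1L)
        df <- chroms[[ins$k]]
        chroms[[ins$k]] <- rbind(df[seq_len(at), , drop = FALSE], born,
                                 df[seq_len(nrow(df)) > at, , drop = FALSE])
      }
    }
    chroms
  }

  s1_chroms <- evolve_branch(anc_chroms, "s1")
  s2_chroms <- evolve_branch(anc_chroms, "s2")

  as_genome <- function(chroms, species, prefix) {
    names(chroms) <- sprintf("%s_chr%d", prefix, seq_along(chroms))
    genome(rep(names(chroms), vapply(chroms, nrow, 0L)),
           unlist(lapply(chroms, `[[`, "id"), use.names = FALSE),
           unlist(lapply(chroms, `[[`, "orient"), use.names = FALSE),
           species = species)
  }
  ancestor <- as_genome(anc_chroms, "ancestor", "anc")
  s1 <- as_genome(s1_chroms, "s1", "s1")
  s2 <- as_genome(s2_chroms, "s2", "s2")

  # ancestral families only: descendants of MRCA genes in either lineage
  allg <- rbind(do.call(rbind, s1_chroms), do.call(rbind, s2_chroms))
  ancfam <- allg$fam %in% ids
  fams <- family_set(allg$fam[ancfam], allg$id[ancfam])

  truth <- .registry_segments(reg, anc_chroms)
  attr(truth, "registry") <- reg
  list(ancestor = ancestor, s1 = s1, s2 = s2, fams = fams, truth = truth,
       events = evlog)
}

# final true conserved segments from the registry, in ancestral coordinates
.registry_segments <- function(reg, anc_chroms) {
  rows <- list()
  for (k in seq_along(reg)) {
    genes <- reg[[k]]$genes
    if (length(genes) == 0L) next
    it <- reg[[k]]$intact
    segid <- cumsum(c(1L, !it))
    df <- anc_chroms[[k]]
    pos <- match(genes, df$id) - 1L          # 0-based ancestral index
    for (s in unique(segid)) {
      sel <- which(segid == s)
      g <- genes[sel]
      o <- df$orient[match(g, df$id)]
      nm <- names(anc_chroms)[k]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom1 = nm, start1 = pos[sel[1L]], end1 = pos[sel[length(sel)]] + 1L,
        chrom2 = nm, start2 = pos[sel[1L]], end2 = pos[sel[length(sel)]] + 1L,
        sign = 1L, n_homologies = length(g),
        families = paste(sprintf("%s:%s", g, ifelse(o > 0, "+", "-")),
                         collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
               chrom2 = character(), start2 = integer(), end2 = integer(),
               sign = integer(), n_homologies = integer(),
               families = character(), stringsAsFactors = FALSE)
  out <- cbind(segment_id = if (nrow(out)) sprintf("true%04d", seq_len(nrow(out)))
               else character(), out, stringsAsFactors = FALSE)
  class(out) <- c("conseg_segments", "data.frame")
  out
}

#' Write a simulated benchmark case to a directory
#'
#' Emits the extant genomes, family table, true-segment table and the
#' configuration (including the seed) as plain-text files that round-trip
#' through [load_genome()], [load_families()] and [load_segments()].
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return The simulation (as [simulate_evolution()]), invisibly.
#' @export
emit_benchmark_case <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_evolution(cfg)
  write_genome(sim$s1, file.path(dir, "s1.tsv"))
  write_genome(sim$s2, file.path(dir, "s2.tsv"))
  write_genome(sim$ancestor, file.path(dir, "ancestor.tsv"))
  write_families(sim$fams, file.path(dir, "families.tsv"))
  truth <- sim$truth
  df <- as.data.frame(truth)
  df$true <- 1L
  utils::write.table(df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfgv <- unclass(cfg)
  writeLines(sprintf("%s=%s", names(cfgv),
                     vapply(cfgv, function(v) paste(v, collapse = ","), "")),
             file.path(dir, "config.txt"))
  invisible(sim)
}
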