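#' Detection and refinement parameters
#'
#' Collects the tuning parameters of the conserved-segment pipeline.  All
#' gaps and widths are counted in genes.  Setting `imrGap`, `imcsWidth` or
#' `truncationMax` to `NA` disables the corresponding refinement (the
#' inactive state of the three post-processing options); an integer, even 0,
#' means the option is active.  When truncation is disabled the whole
#' overlap-resolution stage (truncation, rupture repair, conflict graph) is
#' skipped and the detected diagonals are returned verbatim.
#'
#' @param gapMax maximum Chebyshev gap inside a diagonal (default 2).
#' @param tandemGapMax maximum intervening genes within a tandem-duplicate
#'   cluster (default 5, the value used throughout the benchmark).
#' @param imrGap maximum gap between an extremity of a nested micro-segment
#'   and the nearest homology of its host diagonal (default 1).
#' @param imcsWidth width of the neighbourhood around bounding-box and
#'   matrix edges where mono-genic segments are identified (default 1).
#' @param truncationMax maximum bounding-box overlap resolved by truncation
#'   (default 4).
#' @return A list of class `conseg_params`.
#' @export
conseg_params <- function(gapMax = 2L, tandemGapMax = 5L, imrGap = 1L,
                          imcsWidth = 1L, truncationMax = 4L) {
  chk <- function(x, nm, na_ok) {
    if (is.null(x)) x <- NA_integer_
    if (is.na(x)) {
      if (!na_ok) stop(nm, " cannot be disabled")
      return(NA_integer_)
    }
    x <- as.integer(x)
    if (x < 0L) stop(nm, " must be a non-negative integer")
    x
  }
  out <- list(gapMax = chk(gapMax, "gapMax", FALSE),
              tandemGapMax = chk(tandemGapMax, "tandemGapMax", FALSE),
              imrGap = chk(imrGap, "imrGap", TRUE),
              imcsWidth = chk(imcsWidth, "imcsWidth", TRUE),
              truncationMax = chk(truncationMax, "truncationMax", TRUE))
  class(out) <- "conseg_params"
  out
}

#' @export
print.conseg_params <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "off" else v
  cat(sprintf("gapMax=%s tandemGapMax=%s imr=%s imcs=%s truncationMax=%s\n",
              x$gapMax, x$tandemGapMax, fmt(x$imrGap), fmt(x$imcsWidth),
              fmt(x$truncationMax)))
  invisible(x)
}

# original-coordinate lookup: processed genome position (chrom, idx) -> orig
.orig_lookup <- function(g) {
  if (nrow(g) == 0L) return(stats::setNames(integer(), character()))
  idx <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along) - 1L
  stats::setNames(g$orig, paste0(g$chrom, "\r", idx))
}

# orientation lookup on the same keys
.orient_lookup <- function(g) {
  if (nrow(g) == 0L) return(stats::setNames(integer(), character()))
  idx <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along) - 1L
  stats::setNames(g$orient, paste0(g$chrom, "\r", idx))
}

# convert surviving diagonals to a conserved-segment table.
# orientations in the `families` column are genome-2-frame (reference frame),
# listed in genome-2 order, so item extraction is self-contained.
.diagonals_to_segments <- function(ds, g1, g2, include_isolated = FALSE) {
  m <- ds$matrix
  dl <- ds$diagonals
  keep <- if (include_isolated) seq_along(dl) else .active_idx(dl)
  o1 <- .orig_lookup(g1); o2 <- .orig_lookup(g2)
  or1 <- .orient_lookup(g1); or2 <- .orient_lookup(g2)
  rows <- lapply(keep, function(k) {
    d <- dl[[k]]
    ii <- m$i[d$rows]; jj <- m$j[d$rows]
    fam <- m$family[d$rows]
    # reference (genome 2) frame: genome-2 order and orientations; fall back
    # on genome 1 through the homology sign when a collapsed representative
    # orientation is unknown
    o <- order(jj)
    ref_or <- or2[paste0(d$chrom2, "\r", jj[o])]
    alt <- or1[paste0(d$chrom1, "\r", ii[o])] * m$sign[d$rows][o]
    ref_or[is.na(ref_or)] <- alt[is.na(ref_or)]
    famstr <- paste(sprintf("%s:%s", fam[o],
                            ifelse(is.na(ref_or), "?",
                                   ifelse(ref_or > 0, "+", "-"))),
                    collapse = ",")
    data.frame(
      chrom1 = d$chrom1,
      start1 = unname(o1[paste0(d$chrom1, "\r", min(ii))]),
      end1 = unname(o1[paste0(d$chrom1, "\r", max(ii))]) + 1L,
      chrom2 = d$chrom2,
      start2 = unname(o2[paste0(d$chrom2, "\r", min(jj))]),
      end2 = unname(o2[paste0(d$chrom2, "\r", max(jj))]) + 1L,
      sign = if (is.na(d$sign)) 0L else d$sign,
      n_homologies = d$n,
      families = famstr,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
               chrom2 = character(), start2 = integer(), end2 = integer(),
               sign = integer(), n_homologies = integer(),
               families = character(), stringsAsFactors = FALSE)
  out <- cbind(segment_id = if (nrow(out)) sprintf("seg%04d", seq_len(nrow(out)))
               else character(), out, stringsAsFactors = FALSE)
  class(out) <- c("conseg_segments", "data.frame")
  out
}

#' Run the post-processing workflow on detected diagonals
#'
#' Applies, honouring the enabled/disabled flags of `params`:
#' micro-rearrangement identification, mono-genic segment identification,
#' overlap truncation, repair of truncated ruptures, and greedy conflict
#' resolution; then converts the surviving diagonals to conserved-segment
#' records in the original input coordinates of the two (pre-processed)
#' genomes.
#'
#' @param ds a `diagonal_set` from [detect_diagonals()].
#' @param g1,g2 the processed genomes the matrix was built from.
#' @param params a [conseg_params()].
#' @return A list with `segments` (a `conseg_segments` data frame), the
#'   final `diagonal_set`, and the refinement `trace`.
#' @export
refine_pipeline <- function(ds, g1, g2, params = conseg_params()) {
  if (!is.na(params$imrGap)) {
    ds <- identify_micro_rearrangements(ds, params$imrGap)
  }
  if (!is.na(params$imcsWidth)) {
    ds <- identify_monogenic_segments(ds, params$imcsWidth)
  }
  if (!is.na(params$truncationMax)) {
    ds <- truncate_overlaps(ds, params$truncationMax)
    ds <- merge_truncated_extremities(ds, params$gapMax)
    ds <- solve_conflict_graph(ds)
  }
  segs <- .diagonals_to_segments(ds, g1, g2)
  list(segments = segs, diagonals = ds, trace = .get_trace(ds))
}

#' Detect conserved segments from two genomes
#'
#' The main entry point: pre-processes the genomes (removing genes without a
#' homolog in the other genome, collapsing clusters of tandem duplicates),
#' builds the signed homology matrix, chains homologies into gapped
#' consistent diagonals, and refines the diagonals into non-overlapping
#' conserved segments.
#'
#' @param g1,g2 [genome()] objects, or paths to genome TSV files.
#' @param fams a [family_set()], or a path to a family TSV file.
#' @param params a [conseg_params()].
#' @param ... convenience overrides passed to [conseg_params()] when
#'   `params` is missing.
#' @return An object of class `conseg`: a list with `segments` (the
#'   conserved-segment table in input coordinates), `matrix` (the homology
#'   matrix of the processed genomes), `diagonals`, `trace`, the processed
#'   genomes, and the parameters used.
#' @export
#' @examples
#' g1 <- genome("c1", c("x1", "x2", "x3"), c(1, -1, 1), species = "s1")
#' g2 <- genome("c1", c("y1", "y2", "y3"), c(1, 1, 1), species = "s2")
#' fams <- family_set(c("A", "B", "C", "A", "B", "C"),
#'                    c("x1", "x2", "x3", "y1", "y2", "y3"))
#' fit <- conserved_segments(g1, g2, fams, gapMax = 1)
#' fit
conserved_segments <- function(g1, g2, fams, params = NULL, ...) {
  if (is.character(g1) && !inherits(g1, "genome")) g1 <- load_genome(g1)
  if (is.character(g2) && !inherits(g2, "genome")) g2 <- load_genome(g2)
  if (is.character(fams) && !inherits(fams, "family_set")) {
    fams <- load_families(fams)
  }
  if (is.null(params)) params <- conseg_params(...)
  pp <- preprocess_genomes(g1, g2, fams, params$tandemGapMax)
  m <- build_homology_matrix(pp$g1, pp$g2, fams)
  ds <- detect_diagonals(m, params$gapMax)
  ref <- refine_pipeline(ds, pp$g1, pp$g2, params)
  out <- list(segments = ref$segments, matrix = m, diagonals = ref$diagonals,
              trace = ref$trace, genome1 = pp$g1, genome2 = pp$g2,
              params = params,
              species = c(attr(g1, "species"), attr(g2, "species")))
  class(out) <- "conseg"
  out
}

#' @export
print.conseg <- function(x, ...) {
  s <- x$segments
  cat(sprintf("Conserved segments: %s vs %s\n", x$species[1L], x$species[2L]))
  print(x$params)
  cat(sprintf("%d segments (%d mono-genic) covering %d homologies\n",
              nrow(s), sum(s$n_homologies == 1L), sum(s$n_homologies)))
  invisible(x)
}

#' @export
summary.conseg <- function(object, ...) {
  s <- object$segments
  cat(sprintf("Conserved segments: %s vs %s\n",
              object$species[1L], object$species[2L]))
  print(object$params)
  cat(sprintf("homology matrix: %d cells; diagonals kept: %d\n",
              nrow(object$matrix), nrow(s)))
  if (nrow(s)) {
    cat("segment sizes (homologies):\n")
    print(summary(s$n_homologies))
    cat(sprintf("signs: %d plus, %d minus, %d unknown; mono-genic: %d\n",
                sum(s$sign == 1L), sum(s$sign == -1L), sum(s$sign == 0L),
                sum(s$n_homologies == 1L)))
  }
  invisible(object)
}

#' @export
as.data.frame.conseg <- function(x, ...) {
  out <- x$segments
  class(out) <- "data.frame"
  out
}

#' Plot the homology matrix with detected segments
#'
#' Draws the chromosome-pair sub-matrices side by side (chromosomes sorted
#' by decreasing length), one point per homology (`+` in blue, `-` in red,
#' wildcard in grey), with the bounding boxes of the detected conserved
#' segments overlaid.
#'
#' @param x a `conseg` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.conseg <- function(x, ...) {
  m <- x$matrix
  if (nrow(m) == 0L) {
    graphics::plot.new()
    graphics::title(main = "empty homology matrix")
    return(invisible(x))
  }
  d1 <- attr(m, "dims1"); d2 <- attr(m, "dims2")
  d1 <- sort(d1, decreasing = TRUE); d2 <- sort(d2, decreasing = TRUE)
  off1 <- stats::setNames(cumsum(c(0L, unname(d1[-length(d1)]))), names(d1))
  off2 <- stats::setNames(cumsum(c(0L, unname(d2[-length(d2)]))), names(d2))
  gx <- off1[m$chrom1] + m$i
  gy <- off2[m$chrom2] + m$j
  col <- ifelse(is.na(m$sign), "grey50", ifelse(m$sign > 0, "blue3", "red3"))
  graphics::plot(gx, gy, pch = ifelse(is.na(m$sign), 4L, 3L), col = col,
                 xlab = x$species[1L], ylab = x$species[2L],
                 xlim = c(-0.5, sum(d1) - 0.5), ylim = c(-0.5, sum(d2) - 0.5),
                 ...)
  graphics::abline(v = cumsum(d1)[-length(d1)] - 0.5,
                   h = cumsum(d2)[-length(d2)] - 0.5, col = "grey80")
  dl <- x$diagonals$diagonals
  for (d in dl) {
    bb <- .bbox(m, d)
    graphics::rect(off1[d$chrom1] + bb[1L] - 0.4, off2[d$chrom2] + bb[3L] - 0.4,
                   off1[d$chrom1] + bb[2L] + 0.4, off2[d$chrom2] + bb[4L] + 0.4,
                   border = "black")
  }
  invisible(x)
}

#' Write / read a conserved-segment table
#'
#' Tab-separated, one row per segment, with half-open 0-based index spans in
#' the original input coordinates of each genome and the oriented family
#' list in the reference (genome 2) frame.
#'
#' @param segs a `conseg_segments` data frame (or a `conseg` fit).
#' @param path file path.
#' @return `path` (writer) or the segment table (reader).
#' @export
write_segments <- function(segs, path) {
  if (inherits(segs, "conseg")) segs <- segs$segments
  df <- as.data.frame(segs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
load_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(chrom1 = "character",
                                            chrom2 = "character"))
  class(df) <- c("conseg_segments", "data.frame")
  df
}
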