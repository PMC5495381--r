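# Recall/precision/F1 scoring of detected conserved segments against the
# simulator's truth, over three item kinds: segment extremities, gene
# adjacencies and gene names, oriented or not.

# parse the oriented family list of a segment table into per-segment frames
.segment_frames <- function(segs) {
  lapply(strsplit(segs$families, ",", fixed = TRUE), function(v) {
    fam <- sub(":[+?-]$", "", v)
    sym <- substr(v, nchar(v), nchar(v))
    orient <- ifelse(sym == "+", 1L, ifelse(sym == "-", -1L, NA_integer_))
    data.frame(family = fam, orient = orient, stringsAsFactors = FALSE)
  })
}

# the two extremity keys of a segment frame; orientation-aware keys are
# "s:FAM" (5' start) / "e:FAM" (3' end); mirror-reading a segment yields the
# same keys.  Unknown orientations fall back to +.
.frame_extremities <- function(fr, oriented) {
  k <- nrow(fr)
  if (!oriented) return(unique(c(fr$family[1L], fr$family[k])))
  o1 <- if (is.na(fr$orient[1L])) 1L else fr$orient[1L]
  ok <- if (is.na(fr$orient[k])) 1L else fr$orient[k]
  unique(c(if (o1 > 0) paste0("s:", fr$family[1L]) else paste0("e:", fr$family[1L]),
           if (ok > 0) paste0("e:", fr$family[k]) else paste0("s:", fr$family[k])))
}

.frame_adjacencies <- function(fr, oriented) {
  k <- nrow(fr)
  if (k < 2L) return(character())
  out <- character(k - 1L)
  for (t in seq_len(k - 1L)) {
    if (oriented) {
      ol <- if (is.na(fr$orient[t])) 1L else fr$orient[t]
      or <- if (is.na(fr$orient[t + 1L])) 1L else fr$orient[t + 1L]
      a <- if (ol > 0) paste0("e:", fr$family[t]) else paste0("s:", fr$family[t])
      b <- if (or > 0) paste0("s:", fr$family[t + 1L]) else paste0("e:", fr$family[t + 1L])
    } else {
      a <- fr$family[t]; b <- fr$family[t + 1L]
    }
    out[t] <- paste(sort(c(a, b)), collapse = "--")
  }
  out
}

#' Extract scoring items from conserved segments
#'
#' Three kinds of items quantify the quality of a segment set: the
#' `extremity` items are the two terminal gene ends of each segment (a
#' mono-genic segment contributes both ends of its single gene), the
#' `adjacency` items are the consecutive gene-end pairs inside segments,
#' and the `gene_name` items are the families contained in segments.  In
#' oriented mode an extremity distinguishes the 5' start (`s:FAM`) from the
#' 3' end (`e:FAM`) of a gene; in unoriented mode extremities are gene
#' names only and adjacencies are unordered pairs of gene names.  Keys are
#' canonical (an adjacency equals its mirror) and collected with set
#' semantics.
#'
#' @param segs a `conseg_segments` table (detected or true).
#' @param kind one of `"extremity"`, `"adjacency"`, `"gene_name"`.
#' @param oriented logical.
#' @return An object of class `item_set`: a character vector of canonical
#'   keys with attributes `kind` and `oriented`.
#' @export
extract_items <- function(segs, kind = c("extremity", "adjacency", "gene_name"),
                          oriented = TRUE) {
  kind <- match.arg(kind)
  if (inherits(segs, "conseg")) segs <- segs$segments
  frames <- .segment_frames(segs)
  items <- switch(kind,
    extremity = unlist(lapply(frames, .frame_extremities, oriented = oriented)),
    adjacency = unlist(lapply(frames, .frame_adjacencies, oriented = oriented)),
    gene_name = unlist(lapply(frames, `[[`, "family"))
  )
  items <- unique(as.character(items))
  structure(sort(items), kind = kind, oriented = oriented, class = "item_set")
}

#' Score detected items against true items
#'
#' Computes the true-positive (`D` intersect `T`), false-positive
#' (`D \ T`) and false-negative (`T \ D`) item sets and the derived
#' recall `r = |Tp|/|T|`, precision `p = |Tp|/|D|` and F1 score
#' `2rp/(r+p)`.  Empty-denominator conventions: when `|T| = 0`, recall is 1
#' if `|D| = 0` and 0 otherwise (precision symmetrically); F1 is 0 when
#' `r + p = 0`.
#'
#' @param detected,truth `item_set`s of the same kind and orientation mode.
#' @return A list of class `conseg_metrics` with the item sets, their
#'   sizes, and `recall`, `precision`, `f1` in `[0, 1]`.
#' @export
score_items <- function(detected, truth) {
  if (!identical(attr(detected, "kind"), attr(truth, "kind")) ||
      !identical(attr(detected, "oriented"), attr(truth, "oriented"))) {
    stop("item sets have mismatched kind or orientation mode")
  }
  D <- as.character(detected); T_ <- as.character(truth)
  tp <- intersect(D, T_); fp <- setdiff(D, T_); fn <- setdiff(T_, D)
  r <- if (length(T_) == 0L) as.numeric(length(D) == 0L) else length(tp) / length(T_)
  p <- if (length(D) == 0L) as.numeric(length(T_) == 0L) else length(tp) / length(D)
  f1 <- if (r + p == 0) 0 else 2 * r * p / (r + p)
  structure(list(kind = attr(detected, "kind"),
                 oriented = attr(detected, "oriented"),
                 T = T_, D = D, Tp = tp, Fp = fp, Fn = fn,
                 recall = r, precision = p, f1 = f1),
            class = "conseg_metrics")
}

#' @export
print.conseg_metrics <- function(x, ...) {
  cat(sprintf("%s items (%s): |T|=%d |D|=%d |Tp|=%d |Fp|=%d |Fn|=%d\n",
              x$kind, if (x$oriented) "oriented" else "unoriented",
              length(x$T), length(x$D), length(x$Tp), length(x$Fp),
              length(x$Fn)))
  cat(sprintf("recall=%.4f precision=%.4f F1=%.4f\n",
              x$recall, x$precision, x$f1))
  invisible(x)
}

#' Score a detected segment table on all item kinds
#'
#' @param detected,truth `conseg_segments` tables (or a `conseg` fit).
#' @param oriented logical (both modes are reported by [benchmark_run()]).
#' @return data frame with one row per item kind: sizes, recall, precision,
#'   F1.
#' @export
evaluate_segments <- function(detected, truth, oriented = TRUE) {
  if (inherits(detected, "conseg")) detected <- detected$segments
  kinds <- c("extremity", "adjacency", "gene_name")
  do.call(rbind, lapply(kinds, function(k) {
    sc <- score_items(extract_items(detected, k, oriented),
                      extract_items(truth, k, oriented))
    data.frame(item = k, oriented = oriented,
               n_true = length(sc$T), n_detected = length(sc$D),
               tp = length(sc$Tp), fp = length(sc$Fp), fn = length(sc$Fn),
               recall = sc$recall, precision = sc$precision, f1 = sc$f1,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate, detect and score over a parameter grid
#'
#' For each parameter set in the grid, simulates one evolution (fixed seed
#' from `cfg`), runs the full detection pipeline on the extant genomes, and
#' scores all three item kinds in both orientation modes against the true
#' simulated segments.
#'
#' @param cfg a [sim_config()].
#' @param grid a list of [conseg_params()] (or a single one).
#' @return A tidy data frame of metrics, one row per (grid point, item
#'   kind, orientation mode), with the grid parameters as columns.
#' @export
benchmark_run <- function(cfg, grid = list(conseg_params())) {
  if (inherits(grid, "conseg_params")) grid <- list(grid)
  sim <- simulate_evolution(cfg)
  out <- lapply(seq_along(grid), function(gi) {
    par <- grid[[gi]]
    fit <- conserved_segments(sim$s1, sim$s2, sim$fams, params = par)
    res <- rbind(evaluate_segments(fit$segments, sim$truth, oriented = TRUE),
                 evaluate_segments(fit$segments, sim$truth, oriented = FALSE))
    cbind(data.frame(grid = gi, gapMax = par$gapMax,
                     tandemGapMax = par$tandemGapMax, imrGap = par$imrGap,
                     imcsWidth = par$imcsWidth,
                     truncationMax = par$truncationMax), res)
  })
  do.call(rbind, out)
}
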