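#' Construct a genome from chromosome, gene and orientation vectors
#'
#' A genome is an ordered collection of linear chromosomes, each an ordered
#' list of oriented genes.  Gene positions are implicit 0-based ranks within
#' their chromosome; chromosome order is the order of first appearance.
#' Orientations are `+1` (transcription points toward the last gene of the
#' chromosome), `-1`, or `NA` for the special "unknown" orientation that only
#' arises when a mixed-orientation cluster of tandem duplicates is collapsed
#' (never from input files).
#'
#' @param chrom character vector of chromosome identifiers, one per gene.
#' @param gene character vector of gene identifiers; must be unique within
#'   the genome.
#' @param orient integer vector of orientations in `{+1, -1, NA}`.
#' @param species optional species label.
#' @return An object of class `genome`: a data frame with columns `chrom`,
#'   `gene`, `orient` and `orig` (the original 0-based position of each gene
#'   within its chromosome, used to report detected segment spans in input
#'   coordinates after filtering and collapsing).
#' @export
#' @examples
#' g <- genome(c("chr1", "chr1", "chr1"), c("a", "b", "c"), c(1L, -1L, 1L))
#' g
genome <- function(chrom, gene, orient, species = "genome") {
  if (length(chrom) == 1L) chrom <- rep_len(chrom, length(gene))
  stopifnot(length(chrom) == length(gene), length(gene) == length(orient))
  chrom <- as.character(chrom)
  gene <- as.character(gene)
  orient <- as.integer(orient)
  if (anyDuplicated(gene)) {
    stop("duplicate gene_id in genome: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  bad <- !(orient %in% c(1L, -1L)) & !is.na(orient)
  if (any(bad)) stop("orientation must be +1, -1 or NA")
  # keep chromosome blocks contiguous, preserving within-chromosome order
  ord <- order(match(chrom, unique(chrom)))
  chrom <- chrom[ord]; gene <- gene[ord]; orient <- orient[ord]
  orig <- stats::ave(seq_along(gene), chrom, FUN = seq_along) - 1L
  out <- data.frame(chrom = chrom, gene = gene, orient = orient,
                    orig = as.integer(orig), stringsAsFactors = FALSE)
  attr(out, "species") <- species
  class(out) <- c("genome", "data.frame")
  out
}

#' @export
print.genome <- function(x, ...) {
  nchr <- length(unique(x$chrom))
  cat(sprintf("genome '%s': %d genes on %d chromosome%s\n",
              attr(x, "species"), nrow(x), nchr, if (nchr == 1) "" else "s"))
  tab <- table(factor(x$chrom, levels = unique(x$chrom)))
  cat("  ", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of genes per chromosome
#'
#' @param g a [genome()].
#' @return Named integer vector of chromosome lengths in genes, in genome
#'   order.
#' @export
chrom_lengths <- function(g) {
  tab <- table(factor(g$chrom, levels = unique(g$chrom)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a genome from a tab-separated file
#'
#' Expected dialect: a header line then one row per gene with columns
#' `chrom_id`, `gene_id`, `orientation` (orientation in `+1`/`-1`/`1`).
#' Genes appear in file order within each chromosome; rows of different
#' chromosomes may be interleaved, grouping is by `chrom_id` with order of
#' first appearance.
#'
#' @param path file path.
#' @param species species label recorded on the genome; defaults to the file
#'   base name.
#' @return A [genome()].
#' @export
load_genome <- function(path, species = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(species)) {
    species <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {
    return(genome(character(), character(), integer(), species = species))
  }
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    stop("malformed genome row at line ", which(nf != 3L)[1L] + 1L,
         " of ", path, " (expected 3 tab-separated fields)")
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  ostr <- m[, 3L]
  ok <- ostr %in% c("+1", "-1", "1")
  if (any(!ok)) {
    stop("invalid orientation '", ostr[!ok][1L], "' at line ",
         which(!ok)[1L] + 1L, " of ", path)
  }
  orient <- ifelse(ostr == "-1", -1L, 1L)
  genome(m[, 1L], m[, 2L], orient, species = species)
}

#' Write a genome to a tab-separated file
#'
#' Round-trips exactly with [load_genome()].  Genomes containing collapsed
#' unknown orientations cannot be written (the unknown value never occurs in
#' files).
#'
#' @param g a [genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  if (anyNA(g$orient)) stop("cannot write a genome with unknown orientations")
  lines <- c("chrom_id\tgene_id\torientation",
             sprintf("%s\t%s\t%s", g$chrom, g$gene,
                     ifelse(g$orient > 0, "+1", "-1")))
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene-family membership map
#'
#' A family groups all genes descending from one ancestral gene of the most
#' recent common ancestor of the compared species.  Each gene belongs to at
#' most one family; genes absent from the map are non-ancestral and are
#' removed by the pre-processing filter.
#'
#' @param family character vector of family identifiers.
#' @param gene character vector of gene identifiers (same length).
#' @return A named character vector mapping `gene_id -> family_id`, of class
#'   `family_set`.
#' @export
family_set <- function(family, gene) {
  stopifnot(length(family) == length(gene))
  family <- as.character(family); gene <- as.character(gene)
  if (length(gene) == 0L) {
    out <- stats::setNames(character(), character())
    class(out) <- "family_set"
    return(out)
  }
  key <- paste0(family, "\r", gene)
  keep <- !duplicated(key)
  family <- family[keep]; gene <- gene[keep]
  if (anyDuplicated(gene)) {
    g <- unique(gene[duplicated(gene)])
    stop("gene(s) assigned to two distinct families: ",
         paste(utils::head(g, 5L), collapse = ", "))
  }
  out <- stats::setNames(family, gene)
  class(out) <- "family_set"
  out
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("family_set: %d genes in %d families\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Read a family table from a tab-separated file
#'
#' Expected columns: `family_id`, `gene_id` (with a header line).  Repeated
#' identical rows are deduplicated; a gene listed under two distinct families
#' is an error.
#'
#' @param path file path.
#' @return A [family_set()].
#' @export
load_families <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) return(family_set(character(), character()))
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("malformed family row at line ", which(nf != 2L)[1L] + 1L, " of ", path)
  }
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  family_set(m[, 1L], m[, 2L])
}

#' Write a family table to a tab-separated file
#'
#' @param fams a [family_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_families <- function(fams, path) {
  lines <- c("family_id\tgene_id",
             sprintf("%s\t%s", unclass(fams), names(fams)))
  writeLines(lines, path)
  invisible(path)
}

# family of each gene of a genome (NA when non-ancestral / unassigned)
gene_families <- function(g, fams) {
  unname(unclass(fams)[g$gene])
}
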