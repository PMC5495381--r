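#' Parse a newick string with NHX annotations
#'
#' Minimal recursive-descent parser for gene trees carrying NHX comment tags
#' (`[&&NHX:S=species:D=Y]`).  Only the tag syntax is interpreted; branch
#' lengths are parsed and discarded.  Returns a nested-list tree where each
#' node is `list(label, tags, children)`; `tags` is a named character vector
#' of NHX keys.
#'
#' @param text a single newick string (terminating `;` optional).
#' @return The root node (nested list).
#' @export
read_nhx <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  s <- sub(";$", "", s)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  take_until <- function(stops) {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% stops)) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  parse_tags <- function() {
    # optional [&&NHX:...] comment
    if (peek() != "[") return(character())
    close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
    if (close < 0L) stop("unterminated NHX comment in tree")
    com <- substr(s, pos, pos + close - 1L)
    pos <<- pos + close
    inner <- sub("^\\[&&NHX:?", "", sub("\\]$", "", com))
    if (!nzchar(inner)) return(character())
    kv <- strsplit(strsplit(inner, ":", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    vals <- vapply(kv, function(p) if (length(p) > 1L) p[2L] else "", "")
    names(vals) <- vapply(kv, `[`, "", 1L)
    vals
  }
  parse_node <- function() {
    children <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children[[length(children) + 1L]] <- parse_node()
        ch <- peek()
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        stop("malformed newick near position ", pos)
      }
    }
    label <- take_until(c(":", ",", ")", "[", ""))
    if (peek() == ":") { pos <<- pos + 1L; take_until(c(",", ")", "[", "")) }
    tags <- parse_tags()
    list(label = label, tags = tags, children = children)
  }
  root <- parse_node()
  if (pos <= n) stop("trailing characters in newick string: ", substr(s, pos, n))
  root
}

# ancestor chain of a node in an ape phylo (node ids from node to root)
.phylo_ancestors <- function(tree, node) {
  out <- integer()
  edge <- tree$edge
  cur <- node
  repeat {
    par <- edge[edge[, 2L] == cur, 1L]
    if (length(par) == 0L) break
    out <- c(out, par)
    cur <- par
  }
  out
}

# resolve a species label (tip or internal label) to a node id
.species_node <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(label, tree$node.label)
    if (!is.na(j)) return(length(tree$tip.label) + j)
  }
  stop("species '", label, "' not found in species tree")
}

#' Derive gene families by pruning gene trees at the MRCA of two species
#'
#' Each gene tree describes the evolution of one initial gene through
#' duplications (NHX tag `D=Y`) and speciations.  Pruning at the most recent
#' common ancestor (MRCA) of the two compared species turns every gene
#' lineage present in the MRCA into one family: duplications that predate the
#' MRCA split a family into several, duplications after the MRCA do not, and
#' gene trees born strictly after the MRCA are discarded.  Families are
#' restricted to leaf genes of the two compared species.
#'
#' Internal nodes may carry an NHX `S=` species tag (a tip or internal label
#' of `species_tree`); untagged internal nodes are assigned the species-tree
#' MRCA of their children's species.  Untagged leaves must be resolvable via
#' `gene_species`.  Internal nodes without a `D` tag are treated as
#' speciations, so trees without any tags are duplication-free.
#'
#' @param gene_trees character vector of NHX newick strings (or a list of
#'   trees already parsed by [read_nhx()]).
#' @param species_tree species tree: an `ape` `phylo` object or a plain
#'   newick string with labelled internal nodes.
#' @param species_pair character vector of two tip labels of `species_tree`.
#' @param gene_species optional named character vector `gene_id -> species`
#'   used for leaves lacking an `S=` tag.
#' @return A [family_set()] mapping each retained gene to its family.  The
#'   family identifier is the lexicographically smallest gene of the family.
#' @export
families_from_pruned_trees <- function(gene_trees, species_tree, species_pair,
                                       gene_species = NULL) {
  stopifnot(length(species_pair) == 2L)
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  trees <- if (is.character(gene_trees)) lapply(gene_trees, read_nhx) else gene_trees

  ntip <- length(species_tree$tip.label)
  mrca <- if (species_pair[1L] == species_pair[2L]) {
    .species_node(species_tree, species_pair[1L])
  } else {
    ape::getMRCA(species_tree, species_pair)
  }
  # species label -> node id cache, plus ancestry predicates
  strict_anc_of_mrca <- .phylo_ancestors(species_tree, mrca)
  node_label <- function(id) {
    if (id <= ntip) species_tree$tip.label[id] else species_tree$node.label[id - ntip]
  }
  is_strict_anc <- function(id) id %in% strict_anc_of_mrca
  is_mrca <- function(id) id == mrca

  fam_gene <- character(); fam_id <- character()

  leaf_species <- function(node) {
    sp <- node$tags["S"]
    if (!is.na(sp) && nzchar(sp)) return(unname(sp))
    if (!is.null(gene_species) && node$label %in% names(gene_species)) {
      return(unname(gene_species[[node$label]]))
    }
    stop("leaf '", node$label, "' has no species annotation")
  }
  # species node id of a gene-tree node (annotated or MRCA of children)
  node_species <- function(node) {
    sp <- node$tags["S"]
    if (!is.na(sp) && nzchar(sp)) return(.species_node(species_tree, unname(sp)))
    if (length(node$children) == 0L) {
      return(.species_node(species_tree, leaf_species(node)))
    }
    kids <- vapply(node$children, node_species, 0L)
    if (length(unique(kids)) == 1L) return(kids[1L])
    ape::getMRCA(species_tree, unique(kids))
  }
  leaves_in_pair <- function(node) {
    if (length(node$children) == 0L) {
      sp <- leaf_species(node)
      if (sp %in% species_pair) return(node$label)
      return(character())
    }
    unlist(lapply(node$children, leaves_in_pair), use.names = FALSE)
  }
  add_family <- function(node) {
    genes <- leaves_in_pair(node)
    if (length(genes) == 0L) {
      message("pruned family with no genes in the compared species; omitted")
      return(invisible())
    }
    fam_gene <<- c(fam_gene, genes)
    fam_id <<- c(fam_id, rep(min(genes), length(genes)))
  }
  is_dup <- function(node) {
    d <- node$tags["D"]
    !is.na(d) && toupper(unname(d)) %in% c("Y", "T", "1", "TRUE")
  }
  walk <- function(node) {
    sid <- node_species(node)
    if (is_strict_anc(sid)) {
      if (length(node$children) == 0L) return(invisible())  # extinct above pair
      for (ch in node$children) walk(ch)
    } else if (is_mrca(sid)) {
      if (length(node$children) > 0L && is_dup(node)) {
        for (ch in node$children) walk(ch)       # duplication before speciation
      } else {
        add_family(node)                         # gene present in the MRCA
      }
    } else {
      add_family(node)                           # lineage crossed the MRCA
    }
  }
  for (tr in trees) {
    sid <- node_species(tr)
    if (!is_mrca(sid) && !is_strict_anc(sid)) next  # de novo birth after MRCA
    walk(tr)
  }
  family_set(fam_id, fam_gene)
}
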