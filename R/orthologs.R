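#' Parse a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] with stricter input checking:
#' parentheses must balance (the error reports the character offset of the
#' first imbalance) and exactly one semicolon-terminated tree is accepted.
#' Leaf labels may carry a taxon annotation after a `|` separator
#' (underscores read as spaces), e.g. `Q1|Homo_sapiens`.
#'
#' @param text a Newick string or a path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  s <- paste(read_text_lines(text), collapse = "")
  depth <- 0
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0) abort(sprintf("unbalanced parenthesis at character %d", i))
  }
  if (depth != 0) abort(sprintf("unbalanced parentheses: %d unclosed at end of input", depth))
  if (!grepl(";", s)) abort("Newick tree must be semicolon-terminated")
  tree <- ape::read.tree(text = s)
  if (is.null(tree)) abort("could not parse Newick input")
  if (inherits(tree, "multiPhylo")) abort("input contains more than one tree")
  tree
}

#' Taxon annotation of tree leaves
#'
#' @param tree an `ape::phylo` tree whose tip labels carry a taxon after
#'   `sep` (underscores become spaces).
#' @param sep separator, default `"|"`.
#' @return named character vector, tip label -> taxon (`NA` when
#'   unannotated).
#' @export
leaf_taxa <- function(tree, sep = "|") {
  labs <- tree$tip.label
  parts <- strsplit(labs, sep, fixed = TRUE)
  taxa <- vapply(parts, function(p) {
    if (length(p) >= 2) gsub("_", " ", p[[length(p)]]) else NA_character_
  }, "")
  setNames(taxa, labs)
}

#' Select the ortholog clade of a query leaf
#'
#' Walks the ancestors of the query tip toward the root and stops at the
#' first ancestor whose subtree contains a second leaf of the target taxon;
#' the previous ancestor (the last one whose subtree contains the query as
#' its only target-taxon leaf) defines the ortholog clade. When the query's
#' immediate parent already contains a second target-taxon leaf the clade is
#' the query leaf alone; when no ancestor ever does, all leaves are returned
#' with the `root_fallback` attribute set.
#'
#' @param tree a rooted `ape::phylo` tree (unrooted trees are rejected:
#'   rooting changes the answer).
#' @param query tip label of the query sequence; must carry the target
#'   taxon.
#' @param taxon target taxon, default `"Homo sapiens"`.
#' @param taxa optional named character vector tip label -> taxon; defaults
#'   to [leaf_taxa()] on the tip labels.
#' @return character vector of clade tip labels (always containing the
#'   query, always the full leaf set of one node or the query leaf itself),
#'   with attributes `node` (the selected node id, or the query tip id) and
#'   `root_fallback` (logical).
#' @export
select_ortholog_clade <- function(tree, query, taxon = "Homo sapiens", taxa = NULL) {
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (is.null(taxa)) taxa <- leaf_taxa(tree)
  q <- match(query, tree$tip.label)
  if (is.na(q)) abort(sprintf("query leaf '%s' not found", query))
  if (is.na(taxa[[query]]) || taxa[[query]] != taxon) {
    abort(sprintf("query leaf '%s' does not carry taxon '%s'", query, taxon))
  }
  target_tips <- which(tree$tip.label %in% names(taxa)[!is.na(taxa) & taxa == taxon])

  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L

  tips_below <- function(node) {
    if (node <= ape::Ntip(tree)) return(node)
    acc <- integer(0)
    stack <- node
    while (length(stack) > 0) {
      nd <- stack[length(stack)]
      stack <- stack[-length(stack)]
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      acc <- c(acc, kids[kids <= ape::Ntip(tree)])
      stack <- c(stack, kids[kids > ape::Ntip(tree)])
    }
    acc
  }

  prev <- q # last node whose subtree holds only the query among target tips
  node <- parent[q]
  repeat {
    n_target <- sum(tips_below(node) %in% target_tips)
    if (n_target >= 2) {
      tips <- tips_below(prev)
      out <- tree$tip.label[sort(tips)]
      attr(out, "node") <- prev
      attr(out, "root_fallback") <- FALSE
      return(out)
    }
    prev <- node
    if (node == root) break
    node <- parent[node]
  }
  out <- tree$tip.label
  attr(out, "node") <- root
  attr(out, "root_fallback") <- TRUE
  warn("no second target-taxon leaf anywhere: returning the root clade")
  out
}

#' Entropy-based conservation binning of an alignment
#'
#' A per-column conservation grade on the 1 (variable) to 9 (conserved)
#' scale, computed from the normalized Shannon entropy of the column's
#' residue frequencies over the 20-letter alphabet (gaps excluded) and
#' mapped onto nine equal-width bins, 9 = lowest entropy. This is a simple
#' information-theoretic grading, not the phylogeny-aware Rate4Site/ConSurf
#' method; externally computed grades can be used instead wherever a
#' conservation track is accepted.
#'
#' @param alignment character vector of aligned sequences (equal lengths,
#'   `-` or `.` as gaps), or a character matrix (sequences x columns).
#' @return tibble of class `conservation_track`: `column`, `score` (1-9,
#'   `NA` for all-gap columns), `n_residues`.
#' @export
bin_conservation <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- alignment
  } else {
    if (length(alignment) < 2) abort("alignment needs at least 2 sequences")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1) {
      abort("ragged alignment: sequences have unequal lengths")
    }
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
  }
  if (nrow(m) < 2) abort("alignment needs at least 2 sequences")
  scores <- apply(m, 2, function(col) {
    col <- col[!col %in% c("-", ".")]
    if (length(col) == 0) return(NA_real_)
    f <- table(col) / length(col)
    h <- -sum(f * log(f))
    hn <- h / log(20)
    max(1, 9 - floor(hn * 9))
  })
  out <- tibble(
    column = seq_len(ncol(m)),
    score = as.integer(scores),
    n_residues = apply(m, 2, function(col) sum(!col %in% c("-", ".")))
  )
  class(out) <- c("conservation_track", class(tibble()))
  out
}

#' Read an amino-acid FASTA alignment as a character vector
#'
#' @param path FASTA file.
#' @return named character vector of (aligned) sequences.
#' @export
read_fasta_alignment <- function(path) {
  aa <- ape::read.FASTA(path, type = "AA")
  if (length(aa) == 0) abort("no FASTA records found")
  chars <- as.character(aa)
  vapply(chars, function(x) toupper(paste(x, collapse = "")), "")
}
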