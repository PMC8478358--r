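#' Read and validate a rooted phylogeny from Newick text
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must be rooted
#' with branch lengths on every edge; tip labels are normalized (whitespace
#' trimmed, spaces unified to underscores) and must be unique after
#' normalization. Polytomies are accepted as-is; zero-length terminal branches
#' are permitted but reported with a message because they make tips
#' phylogenetically indistinguishable from their parent node.
#'
#' @param file Path to a Newick file. Exactly one of `file` or `text` must be
#'   given.
#' @param text A Newick string (with trailing semicolon).
#' @return An object of class `phylo` (ape) with normalized tip labels.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2):0;")
#' ape::Ntip(tr)
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text)) {
    stop("supply exactly one of `file` or `text`", call. = FALSE)
  }
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick string lacks a terminating semicolon", call. = FALSE)
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses in Newick string (%d '(' vs %d ')')",
                 n_open, n_close), call. = FALSE)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string", call. = FALSE)
  validate_phylo(tree)
}

#' Normalize taxon names for tree/table matching
#'
#' Trims surrounding whitespace, collapses internal runs of whitespace, and
#' unifies spaces to underscores so that `"Dorudon atrox"` and
#' `"Dorudon_atrox"` match. Matching between trees and trait tables is exact
#' after this normalization.
#'
#' @param x Character vector of taxon names.
#' @return Character vector of normalized names.
#' @export
normalize_taxon_names <- function(x) {
  x <- trimws(x)
  x <- gsub("\\s+", " ", x)
  gsub(" ", "_", x, fixed = TRUE)
}

# Shared validity checks for trees entering the pipeline.
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object", call. = FALSE)
  tree$tip.label <- normalize_taxon_names(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  neg <- which(tree$edge.length < 0)
  if (length(neg) > 0) {
    ends <- tree$edge[neg, 2]
    lab <- ifelse(ends <= ape::Ntip(tree), tree$tip.label[ends],
                  paste0("node ", ends))
    stop("negative branch length on edge to: ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  if (any(tree$edge.length[term] == 0)) {
    zt <- tree$tip.label[tree$edge[term, 2][tree$edge.length[term] == 0]]
    message("zero-length terminal branch(es): ", paste(zt, collapse = ", "))
  }
  tree
}

#' Prune a tree to a set of taxa
#'
#' Retained tips keep their original root-to-tip distances; internal nodes of
#' degree two created by the pruning are collapsed by summing branch lengths
#' (the behaviour of [ape::keep.tip()]).
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels to retain (normalized as by
#'   [normalize_taxon_names()]).
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  tree <- validate_phylo(tree)
  taxa <- normalize_taxon_names(taxa)
  if (length(taxa) == 0) stop("no taxa requested", call. = FALSE)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pruned <- ape::keep.tip(tree, taxa)
  # keep.tip re-roots at the MRCA of the retained taxa; carry the lost
  # root-to-MRCA path as a root edge so root-to-tip distances are preserved
  ref <- taxa[1]
  depth_of <- function(tr) {
    d <- ape::node.depth.edgelength(tr)
    d[match(ref, tr$tip.label)] + if (is.null(tr$root.edge)) 0 else tr$root.edge
  }
  deficit <- depth_of(tree) - depth_of(pruned)
  if (deficit > 1e-12) {
    pruned$root.edge <- (if (is.null(pruned$root.edge)) 0 else
      pruned$root.edge) + deficit
  }
  pruned
}

#' Phylogenetic covariance matrix with Pagel's lambda transform
#'
#' Builds the Brownian-motion covariance \eqn{V} implied by a rooted tree
#' (shared root-to-MRCA path lengths off the diagonal, root-to-tip distances
#' on it) and applies Pagel's lambda: off-diagonal entries are multiplied by
#' `lambda`, the diagonal is left unchanged. `lambda = 0` yields phylogenetic
#' independence (a diagonal matrix), `lambda = 1` the full Brownian structure.
#'
#' @param tree A `phylo` object with at least two tips.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param taxa Optional character vector giving the row/column order; defaults
#'   to the tree's tip order.
#' @return A symmetric positive semi-definite matrix with taxon dimnames.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' phylo_covariance(tr, lambda = 1)["A", "B"]  # 1
#' @export
phylo_covariance <- function(tree, lambda = 1, taxa = NULL) {
  tree <- validate_phylo(tree)
  if (ape::Ntip(tree) < 2) stop("tree must have >= 2 tips", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single value in [0, 1]", call. = FALSE)
  }
  V <- ape::vcv.phylo(tree)
  # a root edge (e.g. from pruning) is path shared by every pair of tips
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    V <- V + tree$root.edge
  }
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  if (!is.null(taxa)) {
    taxa <- normalize_taxon_names(taxa)
    missing <- setdiff(taxa, rownames(V))
    if (length(missing) > 0) {
      stop("taxa absent from tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    V <- V[taxa, taxa, drop = FALSE]
  }
  V
}
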