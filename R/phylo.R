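# Species correlation matrices from taxonomy tables or phylogenies.

#' Taxonomy-derived species correlation
#'
#' Converts a taxonomy table into a species correlation matrix under an
#' ultrametric tree with equal branch lengths per rank level: the correlation
#' of two species is the fraction of tree depth they share, i.e. the number of
#' leading rank columns on which they agree divided by the number of rank
#' columns.  This is the standard proxy for a phylogeny when only taxonomy is
#' available.
#'
#' @param taxonomy data frame or matrix with one row per species and ordered
#'   rank columns from coarsest to finest (e.g. family, genus, species).
#' @return correlation matrix \code{n_s x n_s} with unit diagonal; rownames
#'   and colnames taken from the finest rank.
#' @export
taxonomy_to_correlation <- function(taxonomy) {
  tax <- as.matrix(taxonomy)
  n_s <- nrow(tax)
  n_r <- ncol(tax)
  if (n_s < 1 || n_r < 1) stop("taxonomy must have at least one row and one column")
  if (n_r == 1)
    warning("single rank column: correlation degenerates to a block matrix")
  key <- apply(tax, 1, paste, collapse = "\r")
  if (anyDuplicated(key))
    stop("duplicate species identity: rows ",
         paste(which(duplicated(key) | duplicated(key, fromLast = TRUE)), collapse = ", "),
         " are identical in all ranks")
  # shared depth = length of common leading-rank prefix
  C <- matrix(0, n_s, n_s)
  agree <- matrix(TRUE, n_s, n_s)
  for (r in seq_len(n_r)) {
    agree <- agree & outer(tax[, r], tax[, r], "==")
    C <- C + agree
  }
  C <- C / n_r
  diag(C) <- 1
  sp <- tax[, n_r]
  if (!anyDuplicated(sp)) dimnames(C) <- list(sp, sp)
  C
}

#' Phylogeny-derived species correlation
#'
#' Reads a rooted Newick tree with branch lengths and converts it to a species
#' correlation matrix: the covariance of two tips is the shared root-to-MRCA
#' branch length, normalized to a correlation (equivalently, the tree is
#' ultrametrized by proportional depth scaling so every tip sits at depth 1).
#'
#' @param tree_text a Newick string, a path to a Newick file, or an
#'   \code{ape::phylo} object.
#' @param species optional character vector of species that must all be
#'   present in the tree; the result is ordered accordingly.
#' @return correlation matrix with unit diagonal, tips as dimnames.
#' @export
newick_to_correlation <- function(tree_text, species = NULL) {
  if (inherits(tree_text, "phylo")) {
    tree <- tree_text
  } else if (length(tree_text) == 1 && file.exists(tree_text)) {
    tree <- ape::read.tree(tree_text)
  } else {
    tree <- ape::read.tree(text = tree_text)
  }
  if (is.null(tree)) stop("could not parse Newick tree")
  if (!is.null(species)) {
    missing <- setdiff(species, tree$tip.label)
    if (length(missing))
      stop("species absent from tree: ", paste(missing, collapse = ", "))
  }
  V <- ape::vcv(tree)
  C <- stats::cov2cor(V)
  if (!is.null(species)) C <- C[species, species, drop = FALSE]
  diag(C) <- 1
  C
}
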