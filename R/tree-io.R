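#' Read a Newick tree
#'
#' Trees are `ape` `phylo` objects throughout the package. Branch lengths are
#' expected substitutions per site; edges without a length in the Newick text
#' get `default_branch_length` so downstream likelihoods stay finite.
#'
#' @param path Newick file path (ignored when `text` is given).
#' @param text optional Newick string instead of a file.
#' @param default_branch_length length assigned to edges lacking one
#'   (default 0.1 substitutions/site).
#' @return A `phylo` object with finite non-negative `edge.length`.
#' @export
read_tree <- function(path = NULL, text = NULL, default_branch_length = 0.1) {
  tr <- if (!is.null(text)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    tryCatch(ape::read.tree(path),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  }
  if (is.null(tr)) stop("Newick parse error: no tree found")
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(default_branch_length, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    tr$edge.length[is.na(tr$edge.length)] <- default_branch_length
  }
  validate_tree(tr)
}

#' Validate a phylogeny for use in the pipeline
#'
#' @param tree a `phylo` object.
#' @param aln optional alignment; if given, the leaf label set must equal the
#'   alignment id set.
#' @return The tree, invisibly validated.
#' @export
validate_tree <- function(tree, aln = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)))
    stop("non-finite branch length")
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  if (!is.null(aln)) {
    if (!setequal(tree$tip.label, aln_ids(aln)))
      stop("tree leaf set does not match alignment ids")
  }
  tree
}

#' Write a tree as Newick
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
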