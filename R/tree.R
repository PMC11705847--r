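#' Read a rooted phylogenetic tree from newick
#'
#' Thin validating wrapper around [ape::read.tree]: the tree must have
#' unique tip labels and non-negative branch lengths.  Trees may carry tips
#' absent from a companion OTU table; they are pruned on demand by
#' [cophenetic_dist].
#'
#' @param path path to a newick file.
#' @param default_zero_length if `TRUE`, missing branch lengths are set to 0
#'   instead of raising an error.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, default_zero_length = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unreadable newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("unreadable newick: ", path)
  validate_tree(tr, default_zero_length = default_zero_length)
}

#' Validate a phylo object for use in phylogenetic null models
#'
#' @param tr an [ape::phylo].
#' @param default_zero_length replace missing branch lengths by 0.
#' @return the validated (possibly repaired) tree.
#' @export
validate_tree <- function(tr, default_zero_length = FALSE) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tr$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    if (!default_zero_length)
      stop("tree has missing branch lengths",
           " (set default_zero_length = TRUE to zero-fill)")
    if (is.null(tr$edge.length))
      tr$edge.length <- numeric(nrow(tr$edge))
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Write a tree as newick
#' @param tr an [ape::phylo].
#' @param path output path.
#' @export
write_tree <- function(tr, path) {
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Cophenetic (patristic) distances among tips
#'
#' Branch-length path distance between every pair of the requested tips.
#' Pruning to a subset does not change distances among retained tips.
#'
#' @param tr an [ape::phylo].
#' @param taxa optional character vector of tips to retain (default all).
#' @return square symmetric matrix with zero diagonal, dimnames = taxa.
#' @export
cophenetic_dist <- function(tr, taxa = NULL) {
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, tr$tip.label)
    if (length(missing))
      stop("taxa not in tree: ", paste(utils::head(missing, 5), collapse = ", "))
    if (length(taxa) < length(tr$tip.label))
      tr <- ape::keep.tip(tr, taxa)
  } else {
    taxa <- tr$tip.label
  }
  d <- ape::cophenetic.phylo(tr)
  d <- d[taxa, taxa]
  diag(d) <- 0
  d
}
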