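#' Write a tree to a Newick file
#'
#' Leaf labels are sanitised before writing: any character with meaning in
#' the Newick grammar (parentheses, comma, colon, semicolon, quotes,
#' whitespace) is replaced by `_`. Duplicate leaf labels (after
#' sanitisation) are an error. Branch lengths are written as-is.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label <- sanitize_labels(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length(s); clamp before writing")
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Replace Newick-grammar characters in labels with "_".
sanitize_labels <- function(x) {
  gsub("[][():;,'\"[:space:]]", "_", x)
}
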