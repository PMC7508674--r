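#' Read a Newick tree
#'
#' Thin wrapper over `ape::read.tree` adding the package's strict dialect:
#' unbalanced parentheses are rejected with the character position of the
#' imbalance, and missing branch lengths default to 0.
#'
#' @param path Path to a Newick file, or a literal Newick string ending in
#'   `;` (via `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return An `ape::phylo` tree; `edge.length` is always present.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parentheses at position ", i)
  }
  if (depth != 0L) stop("unbalanced parentheses at position ", length(chars))
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick string")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  tree
}

#' Write a tree in Newick format
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
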