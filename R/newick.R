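# Tree container and Newick serialization. Trees are plain recursive lists
# (leaf: label + branch length; internal node: children + branch length).
# Serialization is canonical -- siblings are ordered lexicographically by
# their smallest descendant label -- so output is deterministic and directly
# comparable across runs.

#' Tree node constructors
#'
#' @param label leaf label
#' @param length branch length to the parent (NA = omitted)
#' @param children list of child nodes
#' @return object of class `vnar_tree`
#' @export
tree_leaf <- function(label, length = NA_real_) {
  structure(list(label = as.character(label), length = length,
                 children = NULL),
            class = "vnar_tree")
}

#' @rdname tree_leaf
#' @export
tree_node <- function(children, length = NA_real_) {
  stopifnot(length(children) >= 1L,
            all(vapply(children, inherits, logical(1), "vnar_tree")))
  structure(list(label = NULL, length = length, children = children),
            class = "vnar_tree")
}

.tree_leaf_labels <- function(node) {
  if (is.null(node$children)) return(node$label)
  unlist(lapply(node$children, .tree_leaf_labels), use.names = FALSE)
}

#' Leaf labels of a tree
#' @param tree a `vnar_tree`
#' @export
tree_labels <- function(tree) .tree_leaf_labels(tree)

.fmt_len <- function(len) {
  if (is.na(len)) "" else paste0(":", sprintf("%.10g", len))
}

.newick_build <- function(node) {
  if (is.null(node$children))
    return(list(str = paste0(node$label, .fmt_len(node$length)),
                min_label = node$label))
  parts <- lapply(node$children, .newick_build)
  mins <- vapply(parts, `[[`, character(1), "min_label")
  ord <- order(mins, method = "radix")
  inner <- paste(vapply(parts[ord], `[[`, character(1), "str"),
                 collapse = ",")
  list(str = paste0("(", inner, ")", .fmt_len(node$length)),
       min_label = mins[ord][1L])
}

#' Serialize a tree to a Newick string
#'
#' Leaf labels are preserved exactly; sibling order is canonical
#' (lexicographic by smallest descendant label). Duplicate leaf labels are
#' an error.
#'
#' @param tree a `vnar_tree`
#' @return Newick string terminated by `;`
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "vnar_tree"))
  labels <- tree_labels(tree)
  if (anyDuplicated(labels))
    stop("duplicate leaf labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  paste0(.newick_build(tree)$str, ";")
}

#' @export
print.vnar_tree <- function(x, ...) {
  cat(write_newick(x), "\n")
  invisible(x)
}
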