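## Tree input/output on top of ape's "phylo" representation.
##
## Internal node labels are the support dialect emitted by MEGA/PhyML:
## bootstrap percentages (or Bayesian posteriors) attached to the node below
## each internal branch. Supports live in node.label as numbers in [0, 100];
## the root label is conventionally empty.

#' Read a newick tree
#'
#' @param path Path to a newick file, or a newick string via `text=`.
#' @param support_dialect `"internal_label"` to interpret internal node labels
#'   as nodal supports (bootstrap/posterior, percent), `"none"` to ignore them.
#' @param allow_missing_lengths If `TRUE`, absent branch lengths become 0;
#'   otherwise they are an error.
#' @param supports_as_fraction If `TRUE` and every support is at most 1, the
#'   supports are taken to be posterior probabilities and rescaled to percent.
#' @param text Optional newick string, used instead of `path`.
#' @return An [ape::read.tree()] `phylo` object; supports, when present, are
#'   numeric strings in `node.label`.
#' @export
read_newick <- function(path = NULL, support_dialect = c("internal_label", "none"),
                        allow_missing_lengths = FALSE,
                        supports_as_fraction = FALSE, text = NULL) {
  support_dialect <- match.arg(support_dialect)
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  if (!identical(sum(strsplit(text, "")[[1]] == "("),
                 sum(strsplit(text, "")[[1]] == ")"))) {
    stop("unbalanced parentheses in newick input")
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick input")
  if (is.null(tree$edge.length)) {
    if (!allow_missing_lengths) stop("tree has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!allow_missing_lengths) stop("missing branch length(s)")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ", tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  if (support_dialect == "none") {
    tree$node.label <- NULL
  } else if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    present <- !is.na(sup)
    if (supports_as_fraction && any(present) && max(sup[present]) <= 1) {
      sup[present] <- sup[present] * 100
    }
    if (any(present & (sup < 0 | sup > 100))) {
      stop("nodal support outside [0, 100]: ",
           sup[which(present & (sup < 0 | sup > 100))][1L])
    }
    tree$node.label <- ifelse(present, as.character(sup), "")
  }
  tree
}

#' Write a tree to newick
#'
#' Supports (node labels) are written as internal labels, the dialect
#' [read_newick()] reads back.
#'
#' @param tree A `phylo` object.
#' @param path Output path; if `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 12L) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

## numeric supports aligned with internal node numbers (Ntip+1 .. Ntip+Nnode);
## NA where absent
node_supports <- function(tree) {
  if (is.null(tree$node.label)) {
    return(rep(NA_real_, tree$Nnode))
  }
  suppressWarnings(as.numeric(tree$node.label))
}

root_node <- function(tree) length(tree$tip.label) + 1L

## out-degree of the root
root_degree <- function(tree) sum(tree$edge[, 1L] == root_node(tree))
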