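## Radiation diagnostics on trees: the terminal-vs-internodal branch-length
## partition with Welch's t-test, and the relative-node-height vs
## nodal-support correlation. A rapid radiation leaves short, poorly
## supported internal branches under long terminal ones, so the diagnostic
## is: terminal mean >> internodal mean, and support decreasing with depth.

#' Partition branch lengths into terminal and internodal
#'
#' Terminal branches run from a leaf to its nearest node, internodal
#' branches from internal node to internal node. When a degree-2 root has
#' two internal children its two edges are first merged into one internodal
#' edge (such a root only splits a true internodal edge -- rooting is a
#' serialization artifact for these unrooted analyses); all other edges
#' count by their child's type.
#'
#' @param tree A `phylo` with branch lengths.
#' @return List with `terminal` and `internodal` length vectors and a
#'   `flagged` logical, set when the tree has no internodal branch.
#' @export
partition_branches <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  root <- root_node(tree)
  edge <- tree$edge
  len <- tree$edge.length
  terminal <- numeric(0)
  internodal <- numeric(0)
  if (root_degree(tree) == 2L) {
    ridx <- which(edge[, 1L] == root)
    ch <- edge[ridx, 2L]
    if (all(ch > ntip)) {
      ## rooting split a true internodal edge in two: undo it
      internodal <- sum(len[ridx])
      edge <- edge[-ridx, , drop = FALSE]
      len <- len[-ridx]
    }
  }
  is_term <- edge[, 2L] <= ntip
  terminal <- c(terminal, len[is_term])
  internodal <- c(internodal, len[!is_term])
  list(terminal = unname(terminal), internodal = unname(internodal),
       flagged = length(internodal) == 0L)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite fractional degrees of freedom
#' and a two-sided p-value.
#'
#' @param a,b Numeric samples of size >= 2.
#' @return List with `t`, `df`, `p.value`, `mean_a`, `mean_b`.
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance; t is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Relative node heights with nodal supports
#'
#' A node's height is its maximum (default) or mean path length to a
#' descendant leaf; relative height is height divided by the sum of all
#' branch lengths. One row per internal, non-root node carrying a support.
#'
#' @param tree A `phylo` with branch lengths and supports in `node.label`.
#' @param mode `"max"` (default) or `"mean"` distance to descendant leaves.
#' @return Data frame with columns `node`, `height`, `relative_height`,
#'   `support`.
#' @export
relative_node_heights <- function(tree, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  total <- sum(tree$edge.length)
  if (total == 0) stop("total branch length is zero")
  ntip <- length(tree$tip.label)
  tree_po <- stats::reorder(tree, "postorder")
  hmax <- rep(0, ntip + tree$Nnode)
  hsum <- rep(0, ntip + tree$Nnode)   # sum of path lengths to leaves
  nlv <- c(rep(1, ntip), rep(0, tree$Nnode))
  for (e in seq_len(nrow(tree_po$edge))) {
    p <- tree_po$edge[e, 1L]; ch <- tree_po$edge[e, 2L]; l <- tree_po$edge.length[e]
    hmax[p] <- max(hmax[p], hmax[ch] + l)
    hsum[p] <- hsum[p] + hsum[ch] + nlv[ch] * l
    nlv[p] <- nlv[p] + nlv[ch]
  }
  height <- if (mode == "max") hmax else hsum / nlv
  sup <- node_supports(tree)
  nodes <- ntip + seq_len(tree$Nnode)
  keep <- !is.na(sup) & nodes != root_node(tree)
  data.frame(node = nodes[keep], height = height[nodes[keep]],
             relative_height = height[nodes[keep]] / total,
             support = sup[keep])
}

#' Correlation of relative node height with nodal support
#'
#' Pearson correlation with a two-sided p-value from the t transform.
#'
#' @param table Data frame from [relative_node_heights()] (columns
#'   `relative_height`, `support`), at least 3 rows.
#' @return List with `r`, `p.value`, `n`.
#' @export
height_support_correlation <- function(table) {
  stopifnot(nrow(table) >= 3L)
  if (stats::sd(table$support) == 0 || stats::sd(table$relative_height) == 0) {
    stop("correlation undefined: constant column")
  }
  ct <- stats::cor.test(table$relative_height, table$support, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(table))
}

#' Combined radiation diagnostic
#'
#' Bundles the branch-length partition, Welch's test, the height/support
#' table, the Pearson correlation, and a verdict: radiation-consistent iff
#' terminal lengths significantly exceed internodal lengths (p < alpha) and
#' support decreases with height (r < 0, p < alpha).
#'
#' @param tree A `phylo` with branch lengths and supports.
#' @param alpha Significance level for both components.
#' @param height_mode Passed to [relative_node_heights()].
#' @return A `radiation_report` object.
#' @export
radiation_report <- function(tree, alpha = 0.05, height_mode = "max") {
  part <- partition_branches(tree)
  if (length(part$internodal) < 2L) {
    stop("too few internodal branches for the partition test")
  }
  welch <- welch_test(part$terminal, part$internodal)
  heights <- relative_node_heights(tree, mode = height_mode)
  if (nrow(heights) < 3L) stop("too few supported internal nodes")
  corr <- height_support_correlation(heights)
  verdict <- welch$p.value < alpha && welch$t > 0 &&
    corr$r < 0 && corr$p.value < alpha
  structure(list(partition = part, welch = welch, heights = heights,
                 correlation = corr, alpha = alpha,
                 radiation_consistent = verdict),
            class = "radiation_report")
}

#' @export
print.radiation_report <- function(x, ...) {
  cat("radiation diagnostic\n")
  cat(sprintf("  terminal mean   %.4f  (n=%d)\n",
              x$welch$mean_a, length(x$partition$terminal)))
  cat(sprintf("  internodal mean %.4f  (n=%d)\n",
              x$welch$mean_b, length(x$partition$internodal)))
  cat(sprintf("  Welch t = %.2f (d.f. = %.1f), p = %.3g\n",
              x$welch$t, x$welch$df, x$welch$p.value))
  cat(sprintf("  height/support Pearson r = %.3f, p = %.3g (n=%d)\n",
              x$correlation$r, x$correlation$p.value, x$correlation$n))
  cat("  verdict:", if (x$radiation_consistent) "radiation-consistent"
      else "not radiation-consistent", "\n")
  invisible(x)
}
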