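## Distance-based tree inference: p-distances with pairwise deletion,
## neighbor joining, and nonparametric bootstrap supports. This is the
## package-internal stand-in for an external minimum-evolution search;
## externally computed trees are equally valid inputs via read_newick().

#' Pairwise p-distances
#'
#' Proportion of differing residues over compared positions, excluding
#' positions where either sequence has a gap or `X` (pairwise deletion).
#'
#' @param aln A [protein_alignment()] with at least two sequences.
#' @return A symmetric matrix of distances with zero diagonal.
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"), nrow(aln) >= 2L)
  codes <- aa_codes(aln, rownames(aln))
  valid <- codes > 0L
  ## matches via one indicator cross-product per amino-acid state
  match_ct <- matrix(0, nrow(codes), nrow(codes))
  for (s in seq_len(20L)) {
    I <- (codes == s) * 1
    match_ct <- match_ct + tcrossprod(I)
  }
  compared <- tcrossprod(valid * 1)
  off <- compared == 0 & row(compared) != col(compared)
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1L, ]
    stop("no comparable positions between ", rownames(codes)[idx[1L]],
         " and ", rownames(codes)[idx[2L]])
  }
  D <- 1 - match_ct / compared
  diag(D) <- 0
  dimnames(D) <- list(rownames(aln), rownames(aln))
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration with two determinism rules: ties in the Q
#' criterion break by the lexicographically smallest (representative label)
#' pair, and a negative branch length produced at a join is clamped to zero
#' with the deficit moved to its sibling branch (their sum is preserved).
#' The output is unrooted (trifurcating root).
#'
#' @param D Symmetric distance matrix with row/column names, >= 3 taxa.
#' @return A `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n0 <- nrow(D)
  if (n0 < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must carry taxon names")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  ## each active cluster: newick fragment + representative (smallest) label
  frags <- as.list(labels)
  reps <- labels
  D <- unname(D)
  fmt <- function(x) sprintf("%.17g", max(x, 0))
  while (length(frags) > 3L) {
    n <- length(frags)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(reps[ij[1L]], reps[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frags[[i]], ":", fmt(li), ",",
                      frags[[j]], ":", fmt(lj), ")")
    newrep <- min(reps[i], reps[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frags <- c(frags[keep], newfrag)
    reps <- c(reps[keep], newrep)
  }
  if (length(frags) == 3L) {
    l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    nwk <- paste0("(", frags[[1L]], ":", fmt(l1), ",",
                  frags[[2L]], ":", fmt(l2), ",",
                  frags[[3L]], ":", fmt(l3), ");")
  }
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for an alignment-based tree
#'
#' Builds the full-data tree, resamples alignment columns with replacement
#' `n_replicates` times, rebuilds a tree per replicate, and attaches to each
#' internal node of the full-data tree the percentage of replicate trees
#' containing the same bipartition.
#'
#' @param aln A [protein_alignment()].
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param builder Function mapping an alignment to a `phylo`; defaults to
#'   NJ on p-distances.
#' @return The full-data `phylo` with supports (percent) in `node.label`;
#'   the root label is empty.
#' @export
bootstrap_supports <- function(aln, n_replicates = 100L, seed = 1L,
                               builder = function(a) neighbor_joining(p_distance(a))) {
  stopifnot(n_replicates >= 1L)
  if (ncol(aln) == 1L) {
    warning("bootstrapping a single-column alignment")
  }
  main <- builder(aln)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(aln), replace = TRUE)
    rep_aln <- unclass(aln)[, cols, drop = FALSE]
    class(rep_aln) <- "protein_alignment"
    reps[[b]] <- builder(rep_aln)
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- round(100 * counts / n_replicates, 1L)
  lab <- as.character(sup)
  lab[1L] <- ""   # root of the (trifurcating) representation: trivial split
  main$node.label <- lab
  main
}
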