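## Amino-acid substitution models: Poisson and rtREV, discrete-gamma rate
## heterogeneity, transition probabilities and Felsenstein-pruning
## log-likelihoods.
##
## States follow the canonical order A R N D C Q E G H I L K M F P S T W Y V.
## The rate matrix is built as Q = S diag(pi) with zeroed diagonal replaced by
## minus the row sum, then scaled so that -sum_i pi_i Q_ii = 1, i.e. branch
## lengths are expected substitutions per site.

## Published rtREV exchangeabilities (Dimmic et al. retroviral REV matrix),
## lower triangle of the symmetric 20x20 matrix in column-major order.
RTREV_RATES <- c(
  34, 51, 10, 439, 32, 81, 135, 30, 1, 45, 38, 235, 1, 97, 460,
  258, 5, 55, 197, 35, 30, 92, 221, 10, 41, 90, 24, 18, 593, 57,
  7, 24, 102, 64, 13, 47, 29, 384, 128, 236, 79, 94, 320, 35, 15,
  123, 1, 49, 33, 294, 148, 16, 28, 21, 1, 78, 542, 61, 91, 1,
  5, 20, 1, 1, 55, 136, 55, 1, 1, 6, 70, 1, 48, 124, 104,
  110, 16, 156, 70, 1, 75, 117, 55, 131, 295, 372, 18, 387, 33, 54,
  309, 158, 1, 68, 225, 146, 10, 45, 36, 70, 34, 1, 21, 141, 1,
  1, 52, 95, 82, 17, 1, 35, 68, 1, 3, 30, 37, 7, 17, 152,
  7, 23, 21, 3, 34, 51, 76, 116, 141, 44, 183, 49, 48, 307, 1,
  385, 34, 375, 64, 10, 4, 72, 39, 26, 1048, 23, 581, 179, 22, 24,
  25, 47, 64, 112, 134, 14, 43, 77, 110, 6, 1, 19, 247, 1, 1,
  131, 111, 74, 236, 11, 20, 69, 182, 1017, 92, 134, 62, 9, 14, 25,
  671, 14, 31, 39, 1, 34, 196, 176, 26, 59
)

## Published rtREV equilibrium amino-acid frequencies.
RTREV_FREQS <- c(
  0.0646, 0.0453, 0.0376, 0.0422, 0.0114, 0.0606, 0.0607, 0.0639, 0.0273,
  0.0679, 0.1018, 0.0751, 0.0150, 0.0287, 0.0681, 0.0488, 0.0622, 0.0251,
  0.0318, 0.0619
)

#' Discrete-gamma rate categories
#'
#' Mean rate of each of `k` equal-probability bins of a Gamma(`alpha`,
#' rate = `alpha`) distribution (Yang's quantile method). The equally
#' weighted category rates average exactly 1.
#'
#' @param alpha Gamma shape parameter, > 0.
#' @param k Number of categories.
#' @return Numeric vector of `k` relative rates.
#' @export
gamma_rates <- function(alpha, k = 4L) {
  stopifnot(is.numeric(alpha), alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  upper <- stats::pgamma(q[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(q[-(k + 1L)], shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

#' Construct an amino-acid substitution model
#'
#' `"poisson"` is the 20-state equal-rate equal-frequency model (the
#' amino-acid analogue of Jukes-Cantor, analytically tractable);
#' `"rtrev"` uses the published retroviral REV exchangeabilities and
#' frequencies. Rate heterogeneity across sites is discrete gamma with
#' `k` equally probable categories.
#'
#' @param name `"poisson"` or `"rtrev"`.
#' @param alpha Gamma shape; ignored when `k = 1`.
#' @param k Number of gamma categories (1 = homogeneous rates).
#' @param frequencies Optional length-20 frequency override (must sum to 1).
#' @return A `subst_model` object.
#' @export
substitution_model <- function(name = c("poisson", "rtrev"), alpha = 1.0,
                               k = 4L, frequencies = NULL) {
  name <- match.arg(name)
  S <- matrix(0, 20L, 20L)
  if (name == "poisson") {
    S[] <- 1
    diag(S) <- 0
    pi <- rep(1 / 20, 20L)
  } else {
    S[lower.tri(S)] <- RTREV_RATES
    S <- S + t(S)
    pi <- RTREV_FREQS / sum(RTREV_FREQS)
  }
  if (!is.null(frequencies)) {
    stopifnot(length(frequencies) == 20L, all(frequencies > 0))
    pi <- frequencies / sum(frequencies)
  }
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))          # expected 1 substitution per unit time
  ## symmetric eigendecomposition of diag(pi)^{1/2} Q diag(pi)^{-1/2}
  sp <- sqrt(pi)
  A <- Q * outer(sp, 1 / sp)
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  model <- list(
    name = name,
    S = S, pi = pi, Q = Q,
    alpha = alpha, k = as.integer(k),
    rates = gamma_rates(alpha, k),
    eigval = eig$values,
    left = eig$vectors / sp,           # diag(1/sp) %*% V
    right = t(eig$vectors * sp)        # t(diag(sp) %*% V) = t(V) diag(sp)
  )
  names(model$pi) <- AA_LETTERS
  dimnames(model$Q) <- list(AA_LETTERS, AA_LETTERS)
  class(model) <- "subst_model"
  model
}

#' @export
print.subst_model <- function(x, ...) {
  cat("amino-acid substitution model:", x$name,
      sprintf("(+G alpha=%g, k=%d)", x$alpha, x$k), "\n")
  invisible(x)
}

## P(d) for rate-scaled branch length d (no category scaling applied here)
ptrans <- function(model, d) {
  P <- model$left %*% (exp(model$eigval * d) * model$right)
  P[P < 0] <- 0
  P
}

#' Transition-probability matrix
#'
#' \eqn{P(t) = e^{Qtr}} for branch length `t` and the relative rate `r` of
#' the chosen gamma category. Rows sum to 1 and the chain is reversible with
#' respect to the model's equilibrium frequencies.
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions per site), >= 0.
#' @param category Gamma category index in `1..k`.
#' @return A 20 x 20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t, category = 1L) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("branch length must be a single non-negative number")
  }
  stopifnot(category >= 1L, category <= model$k)
  P <- ptrans(model, t * model$rates[category])
  dimnames(P) <- list(AA_LETTERS, AA_LETTERS)
  P
}

## Integer codes for alignment residues: 1..20 amino acids, 0 for '-'/'X'
## (fully ambiguous: conditional likelihood 1 for every state).
aa_codes <- function(aln, tips) {
  missing <- setdiff(tips, rownames(aln))
  if (length(missing)) stop("alignment lacks sequence(s): ",
                            paste(missing, collapse = ", "))
  m <- unclass(aln)[tips, , drop = FALSE]
  codes <- match(m, AA_LETTERS)
  codes[is.na(codes)] <- 0L
  matrix(codes, nrow = length(tips), dimnames = list(tips, NULL))
}

## collapse alignment columns to unique site patterns
compress_patterns <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = ",")
  idx <- which(!duplicated(key))
  list(codes = codes[, idx, drop = FALSE],
       counts = as.vector(table(key)[key[idx]]))
}

## 20 x npat indicator matrix for one sequence of codes
leaf_partials <- function(codes_row) {
  L <- matrix(0, 20L, length(codes_row))
  known <- codes_row > 0L
  L[cbind(codes_row[known], which(known))] <- 1
  L[, !known] <- 1
  L
}

#' Tree log-likelihood by Felsenstein pruning
#'
#' Log-likelihood of an alignment on a tree with fixed branch lengths,
#' summed over sites and averaged over the equally weighted discrete-gamma
#' categories. Gaps and `X` are fully ambiguous (likelihood 1 in every
#' state). The root placement is immaterial for these reversible models.
#'
#' @param tree A `phylo` tree whose tip labels all occur in the alignment.
#' @param aln A [protein_alignment()].
#' @param model A [substitution_model()].
#' @return The log-likelihood (a single number).
#' @export
tree_loglik <- function(tree, aln, model) {
  stopifnot(inherits(aln, "protein_alignment"), inherits(model, "subst_model"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  codes <- aa_codes(aln, tree$tip.label)
  pat <- compress_patterns(codes)
  ll_pat <- pattern_logliks(tree, pat$codes, model)
  sum(pat$counts * ll_pat)
}

## per-pattern log-likelihoods (vector over patterns)
pattern_logliks <- function(tree, codes, model) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  npat <- ncol(codes)
  edge <- tree$edge
  elen <- tree$edge.length
  root <- ntip + 1L
  percat <- matrix(0, model$k, npat)      # log lik per category per pattern
  leafL <- lapply(seq_len(ntip), function(i) leaf_partials(codes[i, ]))
  for (r in seq_len(model$k)) {
    rate <- model$rates[r]
    partial <- vector("list", ntip + nnode)
    logscale <- rep(0, npat)
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; ch <- edge[e, 2L]
      P <- ptrans(model, elen[e] * rate)
      Lc <- if (ch <= ntip) leafL[[ch]] else partial[[ch]]
      contrib <- P %*% Lc
      partial[[p]] <- if (is.null(partial[[p]])) contrib else partial[[p]] * contrib
      ## rescale finished internal nodes to avoid underflow
      if (ch > ntip) {
        mx <- apply(partial[[p]], 2L, max)
        mx[mx == 0] <- 1
        partial[[p]] <- sweep(partial[[p]], 2L, mx, "/")
        logscale <- logscale + log(mx)
      }
    }
    percat[r, ] <- log(colSums(model$pi * partial[[root]])) + logscale
  }
  ## average across categories in log space
  mx <- apply(percat, 2L, max)
  mx[!is.finite(mx)] <- 0
  log(colMeans(exp(sweep(percat, 2L, mx, "-")))) + mx
}

#' Estimate the gamma shape on a fixed tree
#'
#' One-dimensional maximum-likelihood search for the discrete-gamma shape
#' parameter, holding tree and branch lengths fixed.
#'
#' @param tree,aln,model As for [tree_loglik()]; the model's `alpha` is
#'   replaced during the search.
#' @param interval Search interval for `alpha`.
#' @return The model refitted with the estimated `alpha`.
#' @export
estimate_gamma_shape <- function(tree, aln, model, interval = c(0.05, 20)) {
  f <- function(a) {
    m <- substitution_model(model$name, alpha = a, k = model$k)
    -tree_loglik(tree, aln, m)
  }
  opt <- stats::optimize(f, interval = interval, tol = 1e-4)
  substitution_model(model$name, alpha = opt$minimum, k = model$k)
}
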