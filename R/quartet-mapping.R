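## Likelihood mapping of quartets.
##
## For each sampled four-taxon subset the maximum likelihood of the three
## unrooted topologies T1=(ab|cd), T2=(ac|bd), T3=(ad|bc) is computed, the
## log-likelihoods are turned into barycentric weights by a softmax (equal
## prior over topologies), and the weight vector is classified into one of
## seven simplex regions: three corners (resolved), three edges
## (conflicting), one center (unresolved).

REGION_LABELS <- c("corner1", "corner2", "corner3",
                   "edge12", "edge13", "edge23", "center")

#' Sample quartets uniformly at random
#'
#' Quartets are drawn without repetition within a quartet; distinct draws may
#' repeat across the sample (`n` may exceed the number of distinct quartets).
#'
#' @param taxa Character vector of at least four taxon ids.
#' @param n Number of quartets.
#' @param seed Integer seed; sampling is reproducible.
#' @return A list of length-4 character vectors.
#' @export
sample_quartets_random <- function(taxa, n, seed) {
  if (length(taxa) < 4L) stop("need at least 4 taxa to sample quartets")
  stopifnot(n >= 1L)
  set.seed(seed)
  lapply(seq_len(n), function(i) sample(taxa, 4L))
}

#' Sample quartets with one taxon per cluster
#'
#' Each quartet takes exactly one taxon, uniformly, from each of four
#' clusters, so topology T1 corresponds to (cluster1, cluster2 | cluster3,
#' cluster4).
#'
#' @param cluster_map Named vector or list mapping taxon id to cluster
#'   `1..4` (or a list of four character vectors of taxa).
#' @param n Number of quartets.
#' @param seed Integer seed.
#' @return A list of length-4 character vectors ordered cluster 1..4, with
#'   the cluster assignment in attribute `"clusters"`.
#' @export
sample_quartets_clustered <- function(cluster_map, n, seed) {
  if (is.list(cluster_map) && is.null(names(cluster_map))) {
    groups <- cluster_map
  } else {
    cl <- unlist(cluster_map)
    groups <- lapply(1:4, function(g) names(cl)[cl == g])
  }
  if (length(groups) != 4L) stop("exactly four clusters are required")
  empty <- which(vapply(groups, length, 1L) == 0L)
  if (length(empty)) stop("empty cluster(s): ", paste(empty, collapse = ", "))
  stopifnot(n >= 1L)
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    vapply(groups, function(g) if (length(g) == 1L) g else sample(g, 1L), "")
  })
  attr(out, "clusters") <- groups
  out
}

## site-likelihood vector for one quartet topology ((x1,x2),(x3,x4)) given
## messages m[[i]] = P(branch_i) %*% leaf indicator (20 x npat each)
.quartet_sitelik <- function(m, Pint, pi) {
  colSums(pi * ((m[[1L]] * m[[2L]]) * (Pint %*% (m[[3L]] * m[[4L]]))))
}

## log-likelihood of one topology at branch lengths bl (b1..b4 terminal in
## the order leaves appear in `ord`, b5 internal), averaged over categories
.quartet_loglik <- function(bl, leafL, ord, model, counts) {
  npat <- ncol(leafL[[1L]])
  percat <- matrix(0, model$k, npat)
  for (r in seq_len(model$k)) {
    rate <- model$rates[r]
    m <- lapply(1:4, function(i) ptrans(model, bl[i] * rate) %*% leafL[[ord[i]]])
    Pint <- ptrans(model, bl[5L] * rate)
    percat[r, ] <- .quartet_sitelik(m, Pint, model$pi)
  }
  sum(counts * log(colMeans(percat)))
}

## coordinate-wise ML branch lengths for one topology; returns loglik.
## While one branch length varies, the messages of the four others are
## cached; for the far-side pair the root is moved across the internal
## branch (legitimate by reversibility), so every 1-D evaluation costs a
## single transition matrix and matrix product per rate category.
.optimize_topology <- function(leafL, ord, model, counts, bounds, tol, max_sweeps) {
  k <- model$k
  npat <- ncol(leafL[[1L]])
  pi <- model$pi
  bl <- rep(0.1, 5L)
  msgs <- lapply(seq_len(k), function(r) {
    lapply(1:4, function(i) ptrans(model, bl[i] * model$rates[r]) %*% leafL[[ord[i]]])
  })
  Pint <- lapply(seq_len(k), function(r) ptrans(model, bl[5L] * model$rates[r]))
  full_ll <- function() {
    percat <- vapply(seq_len(k), function(r) {
      colSums(pi * ((msgs[[r]][[1L]] * msgs[[r]][[2L]]) *
                      (Pint[[r]] %*% (msgs[[r]][[3L]] * msgs[[r]][[4L]]))))
    }, numeric(npat))
    sum(counts * log(rowMeans(matrix(percat, npat, k))))
  }
  ll <- full_ll()
  for (sweep in seq_len(max_sweeps)) {
    ll_start <- ll
    ## terminals first, internal branch last within each sweep
    for (b in c(1L, 2L, 3L, 4L, 5L)) {
      if (b <= 4L) {
        sib <- if (b %% 2L == 1L) b + 1L else b - 1L
        far <- if (b <= 2L) c(3L, 4L) else c(1L, 2L)
        fixed <- lapply(seq_len(k), function(r) {
          msgs[[r]][[sib]] *
            (Pint[[r]] %*% (msgs[[r]][[far[1L]]] * msgs[[r]][[far[2L]]]))
        })
        Lb <- leafL[[ord[b]]]
        f <- function(x) {
          percat <- vapply(seq_len(k), function(r) {
            colSums(pi * (fixed[[r]] *
                            (ptrans(model, x * model$rates[r]) %*% Lb)))
          }, numeric(npat))
          -sum(counts * log(rowMeans(matrix(percat, npat, k))))
        }
      } else {
        near <- lapply(seq_len(k), function(r) msgs[[r]][[1L]] * msgs[[r]][[2L]])
        farm <- lapply(seq_len(k), function(r) msgs[[r]][[3L]] * msgs[[r]][[4L]])
        f <- function(x) {
          percat <- vapply(seq_len(k), function(r) {
            colSums(pi * (near[[r]] *
                            (ptrans(model, x * model$rates[r]) %*% farm[[r]])))
          }, numeric(npat))
          -sum(counts * log(rowMeans(matrix(percat, npat, k))))
        }
      }
      opt <- stats::optimize(f, interval = bounds, tol = tol)
      if (-opt$objective > ll) {
        bl[b] <- opt$minimum
        ll <- -opt$objective
        if (b <= 4L) {
          for (r in seq_len(k)) {
            msgs[[r]][[b]] <- ptrans(model, bl[b] * model$rates[r]) %*% leafL[[ord[b]]]
          }
        } else {
          for (r in seq_len(k)) {
            Pint[[r]] <- ptrans(model, bl[5L] * model$rates[r])
          }
        }
      }
    }
    if (ll - ll_start < tol) break
  }
  list(loglik = ll, bl = bl)
}

#' Maximum-likelihood quartet weights
#'
#' Restricts the alignment to the four taxa (dropping sites that are gap or
#' `X` in all four), optimizes the five branch lengths of each of the three
#' quartet topologies by coordinate-wise 1-D search, and maps the three
#' optimized log-likelihoods to barycentric weights by softmax.
#'
#' @param aln A [protein_alignment()].
#' @param quartet Character vector of four distinct taxon ids `(a, b, c, d)`;
#'   topology T1 is `(ab|cd)`, T2 `(ac|bd)`, T3 `(ad|bc)`.
#' @param model A [substitution_model()].
#' @param bounds Branch-length search interval.
#' @param tol Convergence tolerance for the 1-D searches and the sweep loop.
#' @param max_sweeps Maximum optimization sweeps per topology.
#' @return A `quartet_weights` object: list with `taxa`, `loglik` (l1..l3),
#'   `weights` (p1..p3, summing to 1), `branch_lengths` (the optimized
#'   lengths per topology: four terminals then the internal branch) and
#'   `n_sites`.
#' @export
quartet_ml <- function(aln, quartet, model, bounds = c(1e-6, 10),
                       tol = 1e-6, max_sweeps = 50L) {
  stopifnot(length(quartet) == 4L, !anyDuplicated(quartet))
  codes <- aa_codes(aln, quartet)
  usable <- colSums(codes > 0L) > 0L
  if (!any(usable)) stop("no usable site: all columns gap/unknown in the quartet")
  pat <- compress_patterns(codes[, usable, drop = FALSE])
  leafL <- lapply(seq_len(4L), function(i) leaf_partials(pat$codes[i, ]))
  orders <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
  fits <- lapply(orders, .optimize_topology, leafL = leafL, model = model,
                 counts = pat$counts, bounds = bounds, tol = tol,
                 max_sweeps = max_sweeps)
  ll <- vapply(fits, `[[`, 0, "loglik")
  structure(list(taxa = quartet, loglik = ll,
                 weights = softmax_weights(ll),
                 branch_lengths = lapply(fits, `[[`, "bl"),
                 n_sites = sum(pat$counts)),
            class = "quartet_weights")
}

#' Barycentric weights from topology log-likelihoods
#'
#' `p_i = exp(l_i - logsumexp(l))`; tolerates `-Inf` entries.
#'
#' @param loglik Numeric vector of three log-likelihoods.
#' @return Weights summing to 1.
#' @export
softmax_weights <- function(loglik) {
  stopifnot(length(loglik) == 3L)
  mx <- max(loglik)
  if (!is.finite(mx)) stop("all topology log-likelihoods are -Inf")
  w <- exp(loglik - mx)
  w / sum(w)
}

#' Classify a weight vector into a simplex region
#'
#' With `q` the largest and `s` the second-largest weight: `center` when
#' `q < center_max`; otherwise `corner<i>` (resolved) when `s < edge_min`;
#' otherwise `edge<ij>` (conflicting). Ties break toward the lower topology
#' index.
#'
#' @param w A `quartet_weights` object or numeric weight vector of length 3.
#' @param center_max Threshold on the maximum weight below which a quartet is
#'   unresolved.
#' @param edge_min Threshold on the second weight above which a quartet is
#'   conflicting rather than resolved.
#' @return One of `"corner1".."corner3"`, `"edge12"`, `"edge13"`, `"edge23"`,
#'   `"center"`.
#' @export
classify_region <- function(w, center_max = 0.5, edge_min = 1 / 3) {
  p <- if (inherits(w, "quartet_weights")) w$weights else w
  stopifnot(length(p) == 3L, all(p >= -1e-12), abs(sum(p) - 1) < 1e-6)
  i <- which.max(p)
  j <- setdiff(order(p, decreasing = TRUE), i)[1L]
  if (p[i] < center_max) return("center")
  if (p[j] < edge_min) return(paste0("corner", i))
  paste0("edge", min(i, j), max(i, j))
}

#' Summarize a likelihood-mapping run
#'
#' @param labels Character vector of region labels from [classify_region()].
#' @return A `region_counts` object: counts for the seven regions, the number
#'   of quartets, and resolved / conflicting / unresolved percentages
#'   (corners / edges / center), rounded to 0.1.
#' @export
summarize_run <- function(labels) {
  if (length(labels) == 0L) stop("no quartets to summarize")
  bad <- setdiff(unique(labels), REGION_LABELS)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(REGION_LABELS, function(r) sum(labels == r), 0L)
  n <- length(labels)
  resolved <- sum(counts[1:3]); conflicting <- sum(counts[4:6])
  structure(list(
    counts = counts, n_quartets = n,
    resolved = resolved, conflicting = conflicting, unresolved = counts[["center"]],
    percent = round(100 * c(resolved = resolved, conflicting = conflicting,
                            unresolved = counts[["center"]]) / n, 1L)
  ), class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf("likelihood mapping: %d quartets\n", x$n_quartets))
  cat(sprintf("  resolved (corners):    %5d  (%.1f%%)\n", x$resolved, x$percent[["resolved"]]))
  cat(sprintf("  conflicting (edges):   %5d  (%.1f%%)\n", x$conflicting, x$percent[["conflicting"]]))
  cat(sprintf("  unresolved (center):   %5d  (%.1f%%)\n", x$unresolved, x$percent[["unresolved"]]))
  invisible(x)
}

## collapse a region_counts object to the 3-category triple
region_triple <- function(x) {
  if (inherits(x, "region_counts")) {
    c(resolved = x$resolved, conflicting = x$conflicting, unresolved = x$unresolved)
  } else {
    stopifnot(length(x) == 3L)
    stats::setNames(as.numeric(x), c("resolved", "conflicting", "unresolved"))
  }
}

#' Compare two likelihood-mapping runs by chi-squared
#'
#' Goodness-of-fit of the test run's resolved / conflicting / unresolved
#' counts against expected counts given by the reference run's proportions
#' (df = 2). A 2 x 3 contingency test is available as an option.
#'
#' @param reference,test `region_counts` objects (or count triples).
#' @param method `"gof"` (default) or `"contingency"`.
#' @return List with `statistic`, `df`, `p.value`, and `infinite` flag (set
#'   when a reference category with zero proportion has nonzero test count).
#' @export
compare_runs_chi2 <- function(reference, test, method = c("gof", "contingency")) {
  method <- match.arg(method)
  o_ref <- region_triple(reference)
  o_test <- region_triple(test)
  if (sum(o_ref) == 0 || sum(o_test) == 0) stop("empty run")
  if (method == "contingency") {
    tab <- rbind(o_ref, o_test)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]  # empty categories carry no information
    if (ncol(tab) < 2L) {
      return(list(statistic = 0, df = 0L, p.value = 1,
                  infinite = FALSE, method = method))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p.value = ct$p.value, infinite = FALSE, method = method))
  }
  expected <- sum(o_test) * o_ref / sum(o_ref)
  infinite <- any(expected == 0 & o_test > 0)
  use <- expected > 0
  stat <- if (infinite) Inf else sum((o_test[use] - expected[use])^2 / expected[use])
  list(statistic = stat, df = 2L,
       p.value = stats::pchisq(stat, df = 2L, lower.tail = FALSE),
       infinite = infinite, method = method)
}

#' Run likelihood mapping over a sample of quartets
#'
#' Driver combining quartet sampling, per-quartet ML, region classification
#' and the run summary.
#'
#' @param aln A [protein_alignment()].
#' @param n Number of quartets.
#' @param model A [substitution_model()].
#' @param seed Integer seed for quartet sampling.
#' @param clusters Optional cluster map (see [sample_quartets_clustered()]);
#'   when given, sampling is forced from the four clusters.
#' @param ... Passed to [quartet_ml()].
#' @return List with `quartets` (a data frame: taxa, log-likelihoods,
#'   weights, region) and `summary` (a `region_counts`).
#' @export
likelihood_map <- function(aln, n, model, seed, clusters = NULL, ...) {
  quartets <- if (is.null(clusters)) {
    sample_quartets_random(rownames(aln), n, seed)
  } else {
    sample_quartets_clustered(clusters, n, seed)
  }
  rows <- lapply(quartets, function(q) {
    w <- quartet_ml(aln, q, model, ...)
    data.frame(a = q[1L], b = q[2L], c = q[3L], d = q[4L],
               l1 = w$loglik[1L], l2 = w$loglik[2L], l3 = w$loglik[3L],
               p1 = w$weights[1L], p2 = w$weights[2L], p3 = w$weights[3L],
               region = classify_region(w), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(quartets = tab, summary = summarize_run(tab$region))
}
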