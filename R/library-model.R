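## The "library" pattern: coexisting conspecific R2 lineages that never
## cluster together in the element phylogeny. The qualitative observation is
## formalized here as a nearest-neighbor statistic S (number of conspecific
## lineage pairs that are monophyletic together, i.e. their MRCA contains no
## other species) with a permutation null obtained by shuffling species
## labels across lineages. The statistic, null and one-sidedness are this
## package's formalization of the pattern, not a published procedure.

#' Species-by-clade co-occurrence matrix
#'
#' @param table A [lineage_table()] data frame.
#' @return Integer matrix of lineage counts, species in rows and clades in
#'   columns, with the species having two or more lineages listed in
#'   attribute `"multiple"`.
#' @export
build_cooccurrence <- function(table) {
  table <- lineage_table(table)
  clades <- c("A", "B", "C", "D", "unknown")
  if (nrow(table) == 0L) {
    m <- matrix(0L, 0L, length(clades), dimnames = list(NULL, clades))
    attr(m, "multiple") <- character(0)
    return(m)
  }
  m <- table(factor(table$species, levels = sort(unique(table$species))),
             factor(table$clade, levels = clades))
  m <- unclass(m)
  attr(m, "multiple") <- rownames(m)[rowSums(m) >= 2L]
  m
}

## leaf sets descending from every node, as a list indexed by node id
node_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  tree_po <- stats::reorder(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(tree_po$edge))) {
    p <- tree_po$edge[e, 1L]; ch <- tree_po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

## S for a species assignment given precomputed tree indices
.sister_stat <- function(species_by_tip, desc, mrca_fn, pairs) {
  if (nrow(pairs) == 0L) return(0L)
  s <- 0L
  detail <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    tips <- desc[[mrca_fn(i, j)]]
    detail[r] <- all(species_by_tip[tips] == species_by_tip[i])
    s <- s + detail[r]
  }
  attr(s, "detail") <- detail
  s
}

## all unordered conspecific tip pairs for an assignment
.conspecific_pairs <- function(species_by_tip) {
  by_sp <- split(seq_along(species_by_tip), species_by_tip)
  pr <- lapply(by_sp, function(v) {
    if (length(v) < 2L) return(NULL)
    t(utils::combn(v, 2L))
  })
  out <- do.call(rbind, pr)
  if (is.null(out)) matrix(integer(0), 0L, 2L) else out
}

#' Conspecific sister-pair statistic
#'
#' `S` counts the unordered pairs of lineages from the same species whose
#' most recent common ancestor has no descendant leaf from any other
#' species (the pair clusters together, possibly with further conspecific
#' lineages).
#'
#' @param tree A `phylo` whose tips are lineage ids.
#' @param table A [lineage_table()]; every `lineage_id` must be a tip.
#' @return Integer `S`, with a per-pair logical detail in attribute
#'   `"detail"` and the pair index matrix in attribute `"pairs"`.
#' @export
sister_pair_statistic <- function(tree, table) {
  table <- lineage_table(table)
  missing <- setdiff(table$lineage_id, tree$tip.label)
  if (length(missing)) stop("lineage(s) not in tree: ",
                            paste(missing, collapse = ", "))
  species_by_tip <- table$species[match(tree$tip.label, table$lineage_id)]
  desc <- node_descendants(tree)
  mrca <- ape::mrca(tree)
  mrca_fn <- function(i, j) mrca[i, j]
  pairs <- .conspecific_pairs(species_by_tip)
  s <- .sister_stat(species_by_tip, desc, mrca_fn, pairs)
  attr(s, "pairs") <- pairs
  s
}

## distinct permutations of a label vector (for exhaustive nulls)
unique_label_permutations <- function(labels) {
  rec <- function(remaining) {
    if (length(remaining) == 0L) return(list(character(0)))
    out <- list()
    for (u in sort(unique(remaining))) {
      rest <- remaining[-match(u, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(u, tail)
    }
    out
  }
  rec(labels)
}

#' Permutation test for the library pattern
#'
#' Null distribution of S under random reassignment of species labels to
#' lineages on the fixed tree; when `stratify_by_clade` the shuffle is
#' within each clade (preserving the species-by-clade margins). The p-value
#' is add-one, one-sided for the "less clustering than chance" direction:
#' `p = (1 + #\{S_null <= S_obs\}) / (n_perm + 1)`.
#'
#' @param tree A `phylo` whose tips are lineage ids.
#' @param table A [lineage_table()].
#' @param n_perm Number of permutations (>= 100), ignored when `exhaustive`.
#' @param seed Integer seed.
#' @param stratify_by_clade Shuffle species labels within clades only.
#' @param exhaustive Enumerate every distinct assignment instead of
#'   sampling (small problems only); the p-value is then exact:
#'   `#\{S_null <= S_obs\} / #assignments`.
#' @return A `library_test` object: `S_obs`, `p.value`, `null` (the null
#'   sample of S), `n_perm`, per-pair detail, and the co-occurrence matrix.
#' @export
library_permutation_test <- function(tree, table, n_perm = 1000L, seed = 1L,
                                     stratify_by_clade = FALSE,
                                     exhaustive = FALSE) {
  table <- lineage_table(table)
  s_obs <- sister_pair_statistic(tree, table)
  pairs_obs <- attr(s_obs, "pairs")
  if (nrow(pairs_obs) == 0L) stop("no conspecific lineage pair to test")
  species_by_tip <- table$species[match(tree$tip.label, table$lineage_id)]
  clade_by_tip <- table$clade[match(tree$tip.label, table$lineage_id)]
  desc <- node_descendants(tree)
  mrca <- ape::mrca(tree)
  mrca_fn <- function(i, j) mrca[i, j]
  groups <- if (stratify_by_clade) split(seq_along(species_by_tip), clade_by_tip)
            else list(seq_along(species_by_tip))
  stat_for <- function(assign) {
    .sister_stat(assign, desc, mrca_fn, .conspecific_pairs(assign))
  }
  if (exhaustive) {
    perms_by_group <- lapply(groups, function(idx) {
      unique_label_permutations(species_by_tip[idx])
    })
    grid <- expand.grid(lapply(perms_by_group, seq_along))
    if (nrow(grid) <= 1L) stop("degenerate shuffle space: one distinct assignment")
    null <- apply(grid, 1L, function(row) {
      assign <- species_by_tip
      for (g in seq_along(groups)) {
        assign[groups[[g]]] <- perms_by_group[[g]][[row[g]]]
      }
      as.integer(stat_for(assign))
    })
    p <- sum(null <= as.integer(s_obs)) / length(null)
    n_used <- length(null)
  } else {
    if (n_perm < 100L) stop("n_perm must be at least 100")
    distinct <- vapply(groups, function(idx) {
      length(unique(species_by_tip[idx])) > 1L
    }, TRUE)
    if (!any(distinct)) stop("degenerate shuffle space: one distinct assignment")
    set.seed(seed)
    null <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      assign <- species_by_tip
      for (idx in groups) assign[idx] <- sample(species_by_tip[idx])
      null[b] <- as.integer(stat_for(assign))
    }
    p <- (1 + sum(null <= as.integer(s_obs))) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(S_obs = as.integer(s_obs), p.value = p, null = null,
                 n_perm = n_used, exhaustive = exhaustive,
                 stratified = stratify_by_clade,
                 pair_detail = attr(s_obs, "detail"),
                 cooccurrence = build_cooccurrence(table)),
            class = "library_test")
}

#' @export
print.library_test <- function(x, ...) {
  cat("library-pattern permutation test\n")
  cat(sprintf("  S observed = %d of %d conspecific pairs\n",
              x$S_obs, length(x$pair_detail)))
  cat(sprintf("  null mean S = %.3f (%s, %d assignments)\n",
              mean(x$null), if (x$exhaustive) "exhaustive" else "sampled",
              x$n_perm))
  cat(sprintf("  one-sided p (less clustering than chance) = %.4g\n", x$p.value))
  invisible(x)
}
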