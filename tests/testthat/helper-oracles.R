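# Independent oracles used across the suite. They avoid the package's own
# computational paths: matrix exponentials come from Matrix::expm (not the
# package's eigendecomposition), likelihoods from explicit sums over
# internal states, and the statistics from their textbook formulas.

aa20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")

# transition matrix by scaling-and-squaring, independent of the package path
oracle_ptrans <- function(model, t, category = 1L) {
  as.matrix(Matrix::expm(model$Q * t * model$rates[category]))
}

# leaf conditional vector for one residue character
oracle_leaf_vec <- function(ch) {
  v <- rep(0, 20)
  i <- match(ch, aa20)
  if (is.na(i)) v[] <- 1 else v[i] <- 1
  v
}

# brute-force quartet log-likelihood for topology ((x1,x2),(x3,x4)):
# explicit double sum over the two internal states, averaged over gamma
# categories. seqs: named character vector of 4 aligned sequences;
# ord: which of the 4 sits at position 1..4; bl: b1..b4 terminal, b5 internal.
oracle_quartet_loglik <- function(seqs, ord, bl, model) {
  chars <- lapply(strsplit(seqs, "", fixed = TRUE), identity)
  nsite <- nchar(seqs[[1]])
  total <- 0
  for (site in seq_len(nsite)) {
    percat <- numeric(model$k)
    for (r in seq_len(model$k)) {
      P <- lapply(1:4, function(i) oracle_ptrans(model, bl[i], r))
      Pint <- oracle_ptrans(model, bl[5], r)
      lv <- lapply(1:4, function(i) oracle_leaf_vec(chars[[ord[i]]][site]))
      s <- 0
      for (u in 1:20) for (v in 1:20) {
        s <- s + model$pi[u] *
          (P[[1]][u, ] %*% lv[[1]]) * (P[[2]][u, ] %*% lv[[2]]) *
          Pint[u, v] *
          (P[[3]][v, ] %*% lv[[3]]) * (P[[4]][v, ] %*% lv[[4]])
      }
      percat[r] <- s
    }
    total <- total + log(mean(percat))
  }
  total
}

# brute-force tree log-likelihood for an arbitrary small tree: sum over all
# internal-state assignments (20^Nnode terms; keep trees tiny)
oracle_tree_loglik <- function(tree, aln, model) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  chars <- apply(unclass(aln)[tree$tip.label, , drop = FALSE], c(1, 2), identity)
  nsite <- ncol(chars)
  states_grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  total <- 0
  for (site in seq_len(nsite)) {
    percat <- numeric(model$k)
    for (r in seq_len(model$k)) {
      Pe <- lapply(seq_len(nrow(tree$edge)), function(e) {
        oracle_ptrans(model, tree$edge.length[e], r)
      })
      lv <- lapply(seq_len(ntip), function(i) oracle_leaf_vec(chars[i, site]))
      tot <- 0
      for (g in seq_len(nrow(states_grid))) {
        assign <- states_grid[g, ]
        term <- model$pi[assign[1]]          # root = node ntip+1 is column 1
        for (e in seq_len(nrow(tree$edge))) {
          p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
          sp <- assign[p - ntip]
          term <- term * if (ch <= ntip) {
            sum(Pe[[e]][sp, ] * lv[[ch]])
          } else {
            Pe[[e]][sp, assign[ch - ntip]]
          }
        }
        tot <- tot + term
      }
      percat[r] <- tot
    }
    total <- total + log(mean(percat))
  }
  total
}

# Welch's t, Satterthwaite df, two-sided p -- textbook formulas
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Pearson r and two-sided p from the t transform -- explicit formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# naive exact substring scan (0-based starts)
oracle_substring_starts <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(integer(0))
  which(vapply(seq_len(n - m + 1L),
               function(i) substr(seq, i, i + m - 1L) == motif, TRUE)) - 1L
}

# random additive tree + its exact distance matrix
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rcoal(n, tip.label = paste0("t", seq_len(n))))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# exhaustive library-test null: every distinct reassignment of species
# labels over the tips, computed with its own statistic implementation
oracle_library_null <- function(tree, table) {
  species <- table$species[match(tree$tip.label, table$lineage_id)]
  perms <- unique(combinat_perms(species))
  vapply(perms, function(assign) oracle_sister_stat(tree, assign), 0L)
}

combinat_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(unique(x))) {
    u <- unique(x)[i]
    rest <- x[-match(u, x)]
    for (p in combinat_perms(rest)) out[[length(out) + 1L]] <- c(u, p)
  }
  out
}

# sister-pair statistic recomputed from scratch with ape utilities
oracle_sister_stat <- function(tree, species_by_tip) {
  s <- 0L
  for (sp in unique(species_by_tip)) {
    tips <- which(species_by_tip == sp)
    if (length(tips) < 2L) next
    prs <- utils::combn(tips, 2L)
    for (q in seq_len(ncol(prs))) {
      mrca <- ape::getMRCA(tree, prs[, q])
      clade_tips <- ape::extract.clade(tree, mrca)$tip.label
      idx <- match(clade_tips, tree$tip.label)
      if (all(species_by_tip[idx] == sp)) s <- s + 1L
    }
  }
  s
}

# small deterministic radiation fixture shared by a few tests
fixture_alignment <- function(n_tips = 12, n_sites = 60, seed = 99) {
  model <- substitution_model("poisson", k = 1)
  tree <- simulate_tree(n_tips, 0.225, 0.042, seed = seed)
  list(tree = tree, model = model,
       aln = evolve_alignment(tree, model, n_sites, seed = seed + 1))
}
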