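## Seeded generators for every input the pipeline consumes: radiation-regime
## trees, protein alignments evolved along them, R2-like proteins with
## planted zinc-finger patterns, rDNA-like loci with planted insertions, and
## library-scenario lineage trees. Every generator is a pure function of its
## seed and returns its ground truth alongside the data.
##
## Defaults mirror the study conditions the diagnostics are aimed at:
## 87 taxa, terminal branch-length mean 0.225 and internodal mean 0.042
## (the minimum-evolution regime the partition test contrasts), and a
## 542-position protein alignment.

#' Simulate a (radiation-regime) tree
#'
#' Random coalescent-join topology, then independent exponential branch
#' lengths: internal branches with mean `internode_scale`, terminal branches
#' with mean `terminal_scale`. The tree is unrooted (basal trifurcation), so
#' an `n_tips`-leaf tree has `n_tips` terminal and `n_tips - 3` internodal
#' edges. Short internodes under long terminals emulate an ancient rapid
#' radiation.
#'
#' @param n_tips Number of leaves (>= 4).
#' @param terminal_scale Mean terminal branch length (> 0).
#' @param internode_scale Mean internodal branch length (>= 0; 0 gives the
#'   star-tree limit).
#' @param seed Integer seed.
#' @return A `phylo`; attribute `"ground_truth"` holds the true `terminal`
#'   and `internodal` length vectors.
#' @export
simulate_tree <- function(n_tips = 87L, terminal_scale = 0.225,
                          internode_scale = 0.042, seed = 1L) {
  stopifnot(n_tips >= 4L, terminal_scale > 0, internode_scale >= 0)
  set.seed(seed)
  topo <- ape::rcoal(n_tips, tip.label = paste0("t", seq_len(n_tips)))
  tree <- ape::unroot(topo)
  ntip <- length(tree$tip.label)
  is_term <- tree$edge[, 2L] <= ntip
  len <- numeric(nrow(tree$edge))
  len[is_term] <- stats::rexp(sum(is_term), rate = 1 / terminal_scale)
  if (internode_scale > 0) {
    len[!is_term] <- stats::rexp(sum(!is_term), rate = 1 / internode_scale)
  }
  tree$edge.length <- len
  attr(tree, "ground_truth") <- list(terminal = len[is_term],
                                     internodal = len[!is_term])
  tree
}

## sample child states given parent states (integer codes) and P matrix
.evolve_states <- function(parent_states, P) {
  child <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    idx <- which(parent_states == s)
    child[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[s, ])
  }
  child
}

#' Evolve a protein alignment along a tree
#'
#' Root states are drawn from the model's equilibrium frequencies; each
#' site's gamma category is drawn once and kept along the whole tree (a
#' rates-across-sites model); child states follow the model's transition
#' probabilities over each branch. No indels are simulated.
#'
#' @param tree A `phylo` with branch lengths.
#' @param model A [substitution_model()].
#' @param n_sites Number of alignment columns.
#' @param seed Integer seed.
#' @return A [protein_alignment()] with the tree's tips as sequences.
#' @export
evolve_alignment <- function(tree, model, n_sites = 542L, seed = 1L) {
  stopifnot(inherits(model, "subst_model"), n_sites >= 1L)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  cat_of_site <- sample.int(model$k, n_sites, replace = TRUE)
  states <- matrix(0L, ntip + nnode, n_sites)
  root <- root_node(tree)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
  tree_pr <- stats::reorder(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(tree_pr$edge))) {
    p <- tree_pr$edge[e, 1L]; ch <- tree_pr$edge[e, 2L]
    len <- tree_pr$edge.length[e]
    for (r in unique(cat_of_site)) {
      sites <- which(cat_of_site == r)
      P <- ptrans(model, len * model$rates[r])
      ## guard tiny negative round-off before sampling
      P[P < 0] <- 0
      states[ch, sites] <- .evolve_states(states[p, sites], P)
    }
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                function(z) paste(AA_LETTERS[z], collapse = ""))
  names(seqs) <- tree$tip.label
  protein_alignment(seqs)
}

ZF_PATTERNS <- list(A = c("CCHH", "CCHC", "CCHH"),
                    B = c("CCHC", "CCHH"),
                    C = c("CCHH", "CCHH"),
                    D = "CCHH")

## random spacer free of C and H (so planted motifs are the only matches)
.spacer <- function(n) {
  pool <- setdiff(AA_LETTERS, c("C", "H"))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

#' Generate an R2-like protein with a planted zinc-finger pattern
#'
#' Concatenates random spacers (free of C and H, drawn within the grammar's
#' spacing bounds inside motifs) and the clade's motifs in order, followed
#' by a C/H-free tail, and records the true motif spans.
#'
#' @param pattern Clade pattern, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param seed Integer seed.
#' @param grammar A [zf_grammar()] supplying the spacing bounds.
#' @param leader_range,gap_range,tail_range Length ranges for the N-terminal
#'   leader, inter-motif gaps, and C-terminal tail.
#' @return The protein string; attribute `"ground_truth"` is the data frame
#'   of planted motif types and 0-based half-open spans.
#' @export
make_r2_protein <- function(pattern = c("A", "B", "C", "D"), seed = 1L,
                            grammar = zf_grammar(),
                            leader_range = c(5L, 30L), gap_range = c(4L, 15L),
                            tail_range = c(60L, 120L)) {
  pattern <- match.arg(pattern)
  set.seed(seed)
  motifs <- ZF_PATTERNS[[pattern]]
  parts <- .spacer(sample(leader_range[1L]:leader_range[2L], 1L))
  truth <- list()
  pos <- nchar(parts)
  rng <- function(r) sample(r[1L]:r[2L], 1L)
  for (m in motifs) {
    s1 <- rng(grammar$c_spacer); s2 <- rng(grammar$h_spacer)
    s3 <- rng(grammar$end_spacer)
    body <- paste0("C", .spacer(s1), "C", .spacer(s2), "H", .spacer(s3),
                   if (m == "CCHH") "H" else "C")
    truth[[length(truth) + 1L]] <- data.frame(
      type = m, start = pos, end = pos + nchar(body))
    parts <- paste0(parts, body)
    pos <- pos + nchar(body)
    gap <- .spacer(rng(gap_range))
    parts <- paste0(parts, gap)
    pos <- pos + nchar(gap)
  }
  parts <- paste0(parts, .spacer(rng(tail_range)))
  structure(parts, ground_truth = do.call(rbind, truth), pattern = pattern)
}

## append n random nucleotides, never creating AAGG or TAGC outside planted
## segments (checked over a 4-nt window spanning what was built so far)
.grow_clean <- function(prefix, n) {
  chars <- strsplit(prefix, "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) {
    repeat {
      nt <- sample(c("A", "C", "G", "T"), 1L)
      tail4 <- paste(c(utils::tail(chars, 3L), nt), collapse = "")
      if (!grepl("AAGG|TAGC", tail4, fixed = FALSE)) break
    }
    chars <- c(chars, nt)
  }
  paste(chars, collapse = "")
}

#' Generate an rDNA-like locus with planted R2 insertions
#'
#' Builds `n_units` tandem 28S-like units, each carrying the exact target
#' motif `TTAAGG TAGCCA`; the units listed in `insert_at` (0-based) receive
#' a random element of `element_length` nucleotides between the two
#' half-sites. Random portions are generated free of the half-site 4-mers
#' `AAGG`/`TAGC`, so the planted sites are the only detectable ones.
#'
#' @param n_units Number of tandem units.
#' @param insert_at Integer vector of 0-based unit indices to insert into
#'   (may be empty).
#' @param element_length Length of each inserted element (nt).
#' @param seed Integer seed.
#' @param unit_flank Length of the random sequence on each side of the
#'   target motif within a unit.
#' @return The locus string; attribute `"ground_truth"` is a data frame of
#'   the planted sites: `cleavage`, `inserted`, `insert_start`,
#'   `insert_end` (0-based half-open).
#' @export
make_rdna_locus <- function(n_units = 3L, insert_at = integer(0),
                            element_length = 1000L, seed = 1L,
                            unit_flank = 54L) {
  stopifnot(n_units >= 1L)
  insert_at <- as.integer(insert_at)
  element_length <- as.integer(element_length)
  if (length(insert_at) && (min(insert_at) < 0L || max(insert_at) >= n_units)) {
    stop("insert_at indices must lie in 0..(n_units - 1)")
  }
  set.seed(seed)
  s <- ""
  truth <- list()
  for (u in seq_len(n_units) - 1L) {
    s <- .grow_clean(s, unit_flank)
    s <- paste0(s, "TTAAGG")
    cleav <- nchar(s)
    inserted <- u %in% insert_at
    if (inserted && element_length > 0L) {
      s <- .grow_clean(s, element_length)
    }
    truth[[u + 1L]] <- data.frame(
      cleavage = cleav, inserted = inserted && element_length > 0L,
      insert_start = cleav,
      insert_end = cleav + if (inserted) element_length else 0L)
    s <- paste0(s, "TAGCCA")
    s <- .grow_clean(s, unit_flank)
  }
  structure(s, ground_truth = do.call(rbind, truth))
}

#' Simulate a library-scenario lineage tree
#'
#' In the library scenario the lineage classes diverge on a deep star
#' before any species split; within each class the lineages then track one
#' shared species topology, and every species carries one lineage per
#' class. Conspecific lineages are therefore never sisters (ground-truth
#' S = 0). With `mode = "duplication"` the lineages instead arise by
#' duplication after speciation: each species' lineages form a cherry and
#' S is maximal.
#'
#' @param n_species Number of species (>= 2).
#' @param n_classes Number of lineage classes (>= 2, at most 4 so classes
#'   map onto clades A-D).
#' @param seed Integer seed.
#' @param mode `"library"` or `"duplication"`.
#' @param stem_length,internal_length,terminal_length Branch lengths for the
#'   class stems, species-tree internals, and terminal edges.
#' @return List with `tree` (a `phylo`) and `table` (a [lineage_table()]
#'   with lineage_id, species, clade).
#' @export
simulate_library <- function(n_species = 6L, n_classes = 2L, seed = 1L,
                             mode = c("library", "duplication"),
                             stem_length = 1.0, internal_length = 0.2,
                             terminal_length = 0.1) {
  mode <- match.arg(mode)
  stopifnot(n_species >= 2L, n_classes >= 2L, n_classes <= 4L)
  set.seed(seed)
  species <- paste0("sp", seq_len(n_species))
  classes <- LETTERS[seq_len(n_classes)]
  topo <- if (n_species == 2L) NULL else
    ape::rcoal(n_species, tip.label = species)
  species_newick <- function(labelfun) {
    if (is.null(topo)) {
      return(paste0("(", labelfun(species[1L]), ":", terminal_length, ",",
                    labelfun(species[2L]), ":", terminal_length, ")"))
    }
    t2 <- topo
    t2$tip.label <- vapply(t2$tip.label, labelfun, "")
    t2$edge.length <- ifelse(t2$edge[, 2L] <= n_species,
                             terminal_length, internal_length)
    sub("\\);$", ")", ape::write.tree(t2))
  }
  if (mode == "library") {
    frags <- vapply(classes, function(cl) {
      paste0(species_newick(function(sp) paste0(sp, "_", cl)),
             ":", stem_length)
    }, "")
    nwk <- paste0("(", paste(frags, collapse = ","), ");")
  } else {
    cherry <- function(sp) {
      paste0("(", paste0(sp, "_", classes, ":", terminal_length,
                         collapse = ","), ")")
    }
    body <- species_newick(identity)
    for (sp in species) {   # labels are unique, ":" anchors the exact tip
      body <- sub(paste0(sp, ":"), paste0(cherry(sp), ":"), body, fixed = TRUE)
    }
    nwk <- paste0(body, ";")
  }
  tree <- ape::read.tree(text = nwk)
  table <- lineage_table(data.frame(
    lineage_id = as.vector(outer(species, classes, paste, sep = "_")),
    species = rep(species, times = n_classes),
    clade = rep(classes, each = n_species),
    stringsAsFactors = FALSE))
  list(tree = tree, table = table, mode = mode)
}
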