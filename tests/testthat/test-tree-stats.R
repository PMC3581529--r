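test_that("branch partition separates terminal and internodal edges", {
  p <- partition_branches(read_newick(text = "((A:1,B:1)90:1,C:2);"))
  expect_setequal(p$terminal, c(1, 1, 2))
  expect_equal(p$internodal, 1)
  expect_false(p$flagged)

  star <- partition_branches(read_newick(text = "(A:1,B:1,C:1);"))
  expect_equal(star$terminal, c(1, 1, 1))
  expect_length(star$internodal, 0L)
  expect_true(star$flagged)

  cat5 <- partition_branches(
    read_newick(text = "(A:1,B:1,(C:1,(D:1,E:1):1):1);"))
  expect_length(cat5$terminal, 5L)
  expect_equal(cat5$internodal, c(1, 1))

  # degree-2 root between two internal nodes: its edges merge into one
  rooted <- partition_branches(
    read_newick(text = "((A:1,B:1):0.3,(C:1,D:1):0.2);"))
  expect_equal(rooted$internodal, 0.5)
  expect_length(rooted$terminal, 4L)
})

test_that("partition covers every edge on random trees (property)", {
  for (seed in 1:10) {
    tr <- simulate_tree(sample(8:30, 1), 0.3, 0.1, seed = seed)
    p <- partition_branches(tr)
    expect_length(p$terminal, length(tr$tip.label))
    expect_equal(sum(p$terminal) + sum(p$internodal), sum(tr$edge.length),
                 tolerance = 1e-12)
  }
})

test_that("Welch test matches the textbook formulas", {
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p.value, 1)

  a <- c(1, 2, 3, 4); b <- c(1, 1, 2)
  w <- welch_test(a, b)
  o <- oracle_welch(a, b)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p.value, o$p, tolerance = 1e-12)

  ws <- welch_test(b, a)
  expect_equal(ws$t, -w$t, tolerance = 1e-12)
  expect_equal(ws$p.value, w$p.value, tolerance = 1e-12)

  expect_error(welch_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Welch equals the pooled t-test for equal n and variance", {
  a <- c(1, 2, 3, 4, 5)
  b <- a + 2          # same variance, same n
  w <- welch_test(a, b)
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-10)
})

test_that("relative node heights follow the ratio definition", {
  tab <- relative_node_heights(read_newick(text = "((A:1,B:1)90:1,C:2);"))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$height, 1)
  expect_equal(tab$relative_height, 1 / 5)
  expect_equal(tab$support, 90)

  # ultrametric tree: both cherries have equal height
  ul <- read_newick(text = "((A:1,B:1)80:1,(C:1,D:1)70:1);")
  t2 <- relative_node_heights(ul)
  expect_equal(t2$height, c(1, 1))

  expect_error(relative_node_heights(
    read_newick(text = "((A:0,B:0)50:0,C:0);")), "zero")
})

test_that("node heights agree with an independent path-length oracle", {
  for (seed in 1:8) {
    tr <- simulate_tree(10, 0.4, 0.15, seed = seed)
    tr$node.label <- as.character(seq_len(tr$Nnode) * 10 %% 101)
    tab <- relative_node_heights(tr, mode = "max")
    dn <- ape::dist.nodes(tr)
    ntip <- length(tr$tip.label)
    for (row in seq_len(nrow(tab))) {
      node <- tab$node[row]
      tips_below <- ape::extract.clade(tr, node)$tip.label
      oracle_h <- max(dn[node, match(tips_below, tr$tip.label)])
      expect_equal(tab$height[row], oracle_h, tolerance = 1e-12)
    }
  }
})

test_that("mean-height mode is bounded above by max-height mode", {
  tr <- simulate_tree(15, 0.3, 0.1, seed = 77)
  tr$node.label <- as.character(rep(50, tr$Nnode))
  hmax <- relative_node_heights(tr, "max")
  hmean <- relative_node_heights(tr, "mean")
  expect_true(all(hmean$height <= hmax$height + 1e-12))
})

test_that("height/support correlation matches the formula oracle", {
  perfect <- data.frame(relative_height = c(0, 0.5, 1), support = c(100, 50, 0))
  expect_equal(height_support_correlation(perfect)$r, -1, tolerance = 1e-12)
  rising <- data.frame(relative_height = c(0, 0.5, 1), support = c(0, 50, 100))
  expect_equal(height_support_correlation(rising)$r, 1, tolerance = 1e-12)

  set.seed(12)
  tab <- data.frame(relative_height = stats::runif(10),
                    support = stats::runif(10, 0, 100))
  got <- height_support_correlation(tab)
  o <- oracle_pearson(tab$relative_height, tab$support)
  expect_equal(got$r, o$r, tolerance = 1e-12)
  expect_equal(got$p.value, o$p, tolerance = 1e-12)

  flat <- data.frame(relative_height = stats::runif(5), support = rep(80, 5))
  expect_error(height_support_correlation(flat), "constant")
})

test_that("the radiation report flags the radiation regime and not the null", {
  m <- substitution_model("poisson", k = 1)
  tr <- simulate_tree(40, 0.225, 0.042, seed = 21)
  aln <- evolve_alignment(tr, m, 300, seed = 22)
  bs <- bootstrap_supports(aln, 60, seed = 23)
  rep <- radiation_report(bs)
  expect_true(rep$radiation_consistent)
  expect_gt(rep$welch$t, 0)
  expect_lt(rep$correlation$r, 0)

  star <- read_newick(text = "(A:1,B:1,C:1);")
  expect_error(radiation_report(star), "internodal|supported")
})
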