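test_that("random quartet sampling is uniform-without-replacement and seeded", {
  expect_error(sample_quartets_random(c("a", "b", "c"), 5, 1), "4 taxa")
  q <- sample_quartets_random(c("a", "b", "c", "d"), 3, 1)
  expect_length(q, 3L)
  for (x in q) expect_setequal(x, c("a", "b", "c", "d"))
  taxa <- paste0("t", 1:87)
  big <- sample_quartets_random(taxa, 5000, 42)
  expect_length(big, 5000L)
  expect_true(all(vapply(big, function(x) length(unique(x)) == 4L, TRUE)))
  expect_identical(big, sample_quartets_random(taxa, 5000, 42))
})

test_that("clustered sampling takes one taxon per cluster", {
  cl <- list("a1", "b1", "c1", "d1")
  q <- sample_quartets_clustered(cl, 5, 1)
  expect_true(all(vapply(q, function(x) identical(x, c("a1", "b1", "c1", "d1")), TRUE)))
  expect_error(sample_quartets_clustered(list("a", character(0), "c", "d"), 1, 1),
               "empty cluster")

  clusters <- list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2"), c("d1", "d2"))
  qs <- sample_quartets_clustered(clusters, 1000, 7)
  for (g in 1:4) {
    picks <- vapply(qs, `[[`, "", g)
    expect_true(all(picks %in% clusters[[g]]))
    # binomial check: inclusion of each member ~ 0.5 within 3 sigma
    phat <- mean(picks == clusters[[g]][1])
    expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 1000))
  }
})

test_that("quartet ML weights behave at the symmetric and degenerate limits", {
  m <- substitution_model("poisson", k = 1)
  aln <- protein_alignment(c(a = "ACDE", b = "ACDE", c = "ACDE", d = "ACDE"))
  w <- quartet_ml(aln, c("a", "b", "c", "d"), m)
  expect_equal(w$weights, rep(1 / 3, 3), tolerance = 1e-9)

  expect_equal(softmax_weights(c(-10, -10, -Inf)), c(0.5, 0.5, 0))
  expect_error(softmax_weights(rep(-Inf, 3)), "-Inf")

  gap_aln <- protein_alignment(c(a = "--", b = "--", c = "--", d = "--"))
  expect_error(quartet_ml(gap_aln, c("a", "b", "c", "d"), m), "usable")
})

test_that("optimized quartet log-likelihoods match the brute-force oracle", {
  m <- substitution_model("poisson", k = 1)
  m2 <- substitution_model("rtrev", alpha = 0.9, k = 2)
  seqs <- c(a = "ACDEF", b = "ACDEY", c = "GHKLM", d = "GHKIM")
  aln <- protein_alignment(seqs)
  orders <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
  for (m_use in list(m, m2)) {
    w <- quartet_ml(aln, c("a", "b", "c", "d"), m_use)
    for (topo in 1:3) {
      bf <- oracle_quartet_loglik(seqs, orders[[topo]],
                                  w$branch_lengths[[topo]], m_use)
      expect_equal(w$loglik[topo], bf, tolerance = 1e-8)
    }
  }
})

test_that("data simulated on a resolved quartet maps to the right corner", {
  m <- substitution_model("poisson", k = 1)
  tr <- read_newick(text = "((a:0.25,b:0.25):0.6,(c:0.25,d:0.25):0.0001);")
  aln <- evolve_alignment(tr, m, 500, seed = 202)
  w <- quartet_ml(aln, c("a", "b", "c", "d"), m)
  expect_gt(w$weights[1], 0.95)
  expect_equal(classify_region(w), "corner1")
})

test_that("region classification follows the stated simplex rule", {
  expect_equal(classify_region(c(1, 0, 0)), "corner1")
  expect_equal(classify_region(c(0, 1, 0)), "corner2")
  expect_equal(classify_region(rep(1 / 3, 3)), "center")
  expect_equal(classify_region(c(0.5, 0.45, 0.05)), "edge12")
  expect_equal(classify_region(c(0.05, 0.45, 0.5)), "edge23")
  expect_equal(classify_region(c(0.6, 0.3, 0.1)), "corner1")
  # tie at the boundary breaks toward the lower topology index
  expect_equal(classify_region(c(0.5, 0.5, 0)), "edge12")
})

test_that("the seven regions partition the simplex", {
  set.seed(31)
  n <- 20000
  g <- matrix(stats::rexp(3 * n), n, 3)
  w <- g / rowSums(g)
  labels <- vapply(seq_len(n), function(i) classify_region(w[i, ]), "")
  expect_true(all(labels %in% radsig:::REGION_LABELS))
  counts <- summarize_run(labels)
  expect_equal(sum(counts$counts), n)
  expect_equal(counts$resolved + counts$conflicting + counts$unresolved, n)
})

test_that("run summaries print the published-style percentages", {
  labels <- c(rep("corner1", 10))
  s <- summarize_run(labels)
  expect_equal(unname(s$percent[["resolved"]]), 100)
  expect_error(summarize_run(character(0)), "no quartets")

  # constructed counts reproducing the random-run split 82.9/5.3/11.8
  labels2 <- c(rep("corner1", 2000), rep("corner2", 1145), rep("corner3", 1000),
               rep("edge12", 100), rep("edge13", 100), rep("edge23", 65),
               rep("center", 590))
  s2 <- summarize_run(labels2)
  expect_equal(s2$n_quartets, 5000L)
  expect_equal(unname(s2$percent), c(82.9, 5.3, 11.8))
})

test_that("chi-squared run comparison matches the hand-summed oracle", {
  ref <- c(4145, 265, 590)
  tst <- c(3415, 495, 1085)
  res <- compare_runs_chi2(ref, tst)
  expected <- sum(tst) * ref / sum(ref)
  expect_equal(res$statistic, sum((tst - expected)^2 / expected), tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_lt(res$p.value, 0.001)

  same <- compare_runs_chi2(ref, ref)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  doubled <- compare_runs_chi2(2 * ref, 2 * tst)
  expect_equal(doubled$statistic, 2 * res$statistic, tolerance = 1e-12)

  inf <- compare_runs_chi2(c(10, 0, 0), c(5, 5, 0))
  expect_true(inf$infinite)
  expect_equal(inf$statistic, Inf)
})

test_that("likelihood_map drives sampling, ML and summary coherently", {
  fx <- fixture_alignment(n_tips = 8, n_sites = 40, seed = 13)
  res <- likelihood_map(fx$aln, 5, fx$model, seed = 5)
  expect_equal(nrow(res$quartets), 5L)
  expect_equal(res$summary$n_quartets, 5L)
  expect_true(all(abs(rowSums(res$quartets[, c("p1", "p2", "p3")]) - 1) < 1e-9))
  res2 <- likelihood_map(fx$aln, 5, fx$model, seed = 5)
  expect_identical(res$quartets, res2$quartets)
})
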