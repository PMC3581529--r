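test_that("co-occurrence matrix tabulates lineages per species and clade", {
  tab <- data.frame(
    lineage_id = c("Tcas_A", "Tcas_B", "Tcas_C", "Nvit_A"),
    species = c("T_castaneum", "T_castaneum", "T_castaneum", "N_vitripennis"),
    clade = c("B", "A", "D", "D"))
  m <- build_cooccurrence(tab)
  expect_equal(sum(m["T_castaneum", ]), 3)
  expect_equal(unname(m["T_castaneum", c("A", "B", "D")]), c(1, 1, 1))
  expect_equal(attr(m, "multiple"), "T_castaneum")
  expect_equal(sum(m["N_vitripennis", ]), 1)

  empty <- build_cooccurrence(data.frame(lineage_id = character(0),
                                         species = character(0),
                                         clade = character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("sister-pair statistic counts conspecific clustering", {
  tab <- data.frame(lineage_id = c("sp1_A", "sp1_B", "sp2_A", "sp2_B"),
                    species = rep(c("sp1", "sp2"), each = 2),
                    clade = rep(c("A", "B"), 2))
  paired <- read_newick(text = "((sp1_A:1,sp1_B:1):1,(sp2_A:1,sp2_B:1):1);")
  expect_equal(as.integer(sister_pair_statistic(paired, tab)), 2L)

  inter <- read_newick(text = "((sp1_A:1,sp2_A:1):1,(sp1_B:1,sp2_B:1):1);")
  expect_equal(as.integer(sister_pair_statistic(inter, tab)), 0L)

  catr <- read_newick(text = "(((sp1_A:1,sp2_A:1):1,sp1_B:1):1,sp2_B:1);")
  expect_equal(as.integer(sister_pair_statistic(catr, tab)), 0L)

  expect_error(sister_pair_statistic(paired, data.frame(
    lineage_id = "nope", species = "s", clade = "A")), "nope")
})

test_that("statistic matches the independent MRCA-based oracle", {
  for (seed in 1:6) {
    lib <- simulate_library(4, 2, seed = seed,
                            mode = if (seed %% 2) "library" else "duplication")
    species <- lib$table$species[match(lib$tree$tip.label, lib$table$lineage_id)]
    expect_equal(as.integer(sister_pair_statistic(lib$tree, lib$table)),
                 oracle_sister_stat(lib$tree, species))
  }
})

test_that("permutation test is add-one, seeded and direction-consistent", {
  lib <- simulate_library(6, 2, seed = 9)
  r1 <- library_permutation_test(lib$tree, lib$table, n_perm = 200, seed = 4)
  r2 <- library_permutation_test(lib$tree, lib$table, n_perm = 200, seed = 4)
  expect_identical(r1$p.value, r2$p.value)
  expect_identical(r1$null, r2$null)
  expect_gt(r1$p.value, 0)            # add-one: never exactly zero
  expect_equal(r1$S_obs, 0L)

  dup <- simulate_library(6, 2, seed = 9, mode = "duplication")
  rd <- library_permutation_test(dup$tree, dup$table, n_perm = 200, seed = 4)
  expect_equal(rd$S_obs, length(rd$pair_detail))
  expect_equal(rd$p.value, 1)         # maximal clustering: p -> 1

  expect_error(library_permutation_test(lib$tree, lib$table, n_perm = 50,
                                        seed = 1), "at least 100")
})

test_that("exhaustive null equals full enumeration on a small case", {
  lib <- simulate_library(3, 2, seed = 2)
  res <- library_permutation_test(lib$tree, lib$table, seed = 1,
                                  exhaustive = TRUE)
  null_oracle <- oracle_library_null(lib$tree, lib$table)
  expect_equal(sort(res$null), sort(null_oracle))
  expect_equal(res$p.value,
               sum(null_oracle <= res$S_obs) / length(null_oracle))

  # sampled p converges to the exhaustive p
  samp <- library_permutation_test(lib$tree, lib$table, n_perm = 2000, seed = 3)
  expect_lt(abs(samp$p.value - res$p.value), 0.05)
})

test_that("a null concentrated above the observed S gives a small p", {
  # hand-built 8-leaf tree: observed assignment separates both species'
  # pairs across the two main clades while most label shuffles do not
  tr <- read_newick(text = paste0(
    "(((s1a:1,s2a:1):1,(s1b:1,s2b:1):1):1,",
    "((s3a:1,s4a:1):1,(s3b:1,s4b:1):1):1);"))
  tab <- data.frame(
    lineage_id = c("s1a", "s1b", "s2a", "s2b", "s3a", "s3b", "s4a", "s4b"),
    species = c("sp1", "sp1", "sp2", "sp2", "sp3", "sp3", "sp4", "sp4"),
    clade = "A")
  res <- library_permutation_test(tr, tab, n_perm = 500, seed = 11)
  expect_equal(res$S_obs, 0L)
  expect_lt(res$p.value, mean(res$null > 0) + 0.5)
  expect_gt(mean(res$null), res$S_obs)
})

test_that("stratified shuffling stays within clades", {
  lib <- simulate_library(6, 2, seed = 5)
  # one lineage per species per clade: within-clade shuffling can never
  # produce a conspecific pair inside a clade, so the null is all zeros
  res <- library_permutation_test(lib$tree, lib$table, n_perm = 150, seed = 2,
                                  stratify_by_clade = TRUE)
  expect_true(all(res$null == 0L))
  expect_equal(res$p.value, 1, tolerance = 1e-9)
})
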