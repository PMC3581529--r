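test_that("zinc-finger scanner matches constructed motifs", {
  g <- zf_grammar(c(1, 5), c(8, 17), c(2, 6))
  s <- paste0("C", "AA", "C", strrep("A", 12), "H", "AAA", "H")
  hits <- scan_zinc_fingers(s, grammar = g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$type, "CCHH")
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, nchar(s))

  s2 <- sub("H$", "C", s)
  hits2 <- scan_zinc_fingers(s2, grammar = g)
  expect_equal(hits2$type, "CCHC")

  expect_equal(nrow(scan_zinc_fingers(strrep("AAAA", 20))), 0L)
  expect_error(scan_zinc_fingers(""), "non-empty")
})

test_that("scanner respects the N-terminal window and non-overlap rule", {
  body <- paste0("C", "AA", "C", strrep("A", 10), "H", "AA", "H")
  far <- paste0(strrep("G", 500), body)
  expect_equal(nrow(scan_zinc_fingers(far, window = 450)), 0L)
  expect_equal(nrow(scan_zinc_fingers(far, window = 501)), 1L)

  two <- paste0(body, "GGG", body)
  hits <- scan_zinc_fingers(two)
  expect_equal(nrow(hits), 2L)
  expect_true(hits$start[2] >= hits$end[1])
})

test_that("clade calls follow the zinc-finger pattern map", {
  expect_equal(call_clade(c("CCHH", "CCHC", "CCHH"))$clade, "A")
  expect_equal(call_clade(c("CCHC", "CCHH"))$clade, "B")
  expect_equal(call_clade(c("CCHH", "CCHH"))$clade, "C")
  expect_equal(call_clade("CCHH")$clade, "D")
  expect_equal(call_clade(c("CCHH", "CCHC", "CCHH"))$classes, c("I", "II", "III"))
  expect_equal(call_clade(c("CCHC", "CCHH"))$classes, c("II", "III"))
  # unlisted patterns are a value, never an error
  expect_equal(call_clade("CCHC")$clade, "unknown")
  expect_equal(call_clade(character(0))$clade, "unknown")
  expect_equal(call_clade(rep("CCHH", 4))$clade, "unknown")
})

test_that("target-site search reports cleavage coordinates and flanks", {
  s <- paste0(strrep("A", 20), "TTAAGGTAGCCA", strrep("A", 20))
  hits <- find_target_sites(s, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$cleavage, 26L)
  expect_equal(nchar(hits$upstream_flank), 20L)
  expect_equal(nchar(hits$downstream_flank), 20L)
  expect_false(hits$truncated)

  s1 <- paste0(strrep("A", 20), "TTATGGTAGCCA", strrep("A", 20))
  expect_equal(nrow(find_target_sites(s1, max_mismatch = 0, strand = "plus")), 0L)
  h1 <- find_target_sites(s1, max_mismatch = 1, strand = "plus")
  expect_equal(h1$mismatches, 1L)

  two <- paste0(strrep("C", 5), "TTAAGGTAGCCA", strrep("C", 10),
                "TTAAGGTAGCCA", strrep("C", 5))
  h2 <- find_target_sites(two, max_mismatch = 0)
  expect_equal(h2$cleavage, c(11L, 33L))
  expect_true(all(diff(h2$cleavage) > 0))
  expect_true(any(h2$truncated))   # first flank shortened by the sequence end
})

test_that("exact target search agrees with a naive substring oracle", {
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
    hits <- find_target_sites(s, motif = "TTAAGGTA", max_mismatch = 0,
                              strand = "plus")
    expect_equal(hits$cleavage, oracle_substring_starts(s, "TTAAGGTA") + 6L)
  }
})

test_that("junction detection pairs half-sites across insertions", {
  flank <- strrep("C", 30)
  elem <- strrep("A", 1000)
  locus <- paste0(flank, "TTAAGG", elem, "TAGCCA", flank)
  j <- detect_insertion_junctions(locus)
  expect_equal(nrow(j), 1L)
  expect_equal(j$element_length, 1000L)
  expect_equal(j$insert_start, 36L)
  expect_equal(j$insert_end, 1036L)
  expect_false(j$uninserted)

  intact <- paste0(flank, "TTAAGGTAGCCA", flank)
  j2 <- detect_insertion_junctions(intact)
  expect_true(j2$uninserted)
  expect_equal(j2$element_length, 0L)
})

test_that("junction detection recovers generator ground truth", {
  for (seed in 1:10) {
    n_ins <- sample(0:2, 1)
    ins <- sort(sample(0:2, n_ins))
    loc <- make_rdna_locus(3, insert_at = ins, element_length = 400, seed = seed)
    gt <- attr(loc, "ground_truth")
    j <- detect_insertion_junctions(loc, min_element = 100)
    expect_equal(j$cleavage, gt$cleavage)
    expect_equal(j$insert_end, gt$insert_end)
    expect_equal(j$uninserted, !gt$inserted)
  }
})

test_that("family clustering applies the single-linkage >90% rule", {
  a <- strrep("ACGTTGCAAC", 10)
  expect_equal(unique(cluster_families(c(x = a, y = a))$family), "x")

  half <- paste0(strrep("A", 50), strrep("G", 50))
  other <- paste0(strrep("A", 50), strrep("C", 50))
  fam2 <- cluster_families(c(p = half, q = other))
  expect_equal(length(unique(fam2$family)), 2L)

  # chain: a~b and b~c above threshold, a~c below -> one family
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- ifelse(ch[pos] == "A", "G", "A")
    paste(ch, collapse = "")
  }
  b <- mutate_at(a, 1:8)        # 92% identity to a
  cc <- mutate_at(b, 41:48)     # 92% to b, 84% to a
  fam3 <- cluster_families(c(a = a, b = b, c = cc), threshold = 0.90)
  expect_equal(unique(fam3$family), "a")
})
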