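test_that("column maps are consistent and invert on non-gap columns", {
  frame <- toy_alignment(a = "A-C", b = "ABC")
  expect_equal(residue_to_column(frame, "a"), c(1L, 3L))
  expect_equal(column_to_residue(frame, "a"), c(1L, 0L, 2L))
  # ungapped row: identity map
  expect_equal(residue_to_column(frame, "b"), 1:3)

  cm <- build_column_map(frame)
  expect_equal(nrow(cm), 6L)
  expect_equal(cm$residue[cm$id == "a" & cm$column == 2], 0L)

  # round trip property over random frames
  for (seed in 1:5) {
    f <- random_alignment(3, 40, seed = seed)
    for (id in f$id) {
      r2c <- residue_to_column(f, id)
      c2r <- column_to_residue(f, id)
      expect_equal(c2r[r2c], seq_along(r2c))
      nongap <- which(c2r > 0)
      expect_equal(r2c[c2r[nongap]], nongap)
      expect_true(all(diff(r2c) > 0))
    }
  }
})

test_that("pairwise differences follow the documented gap rule", {
  frame <- toy_alignment(a = "ACD-F", b = "ACEGF")
  d <- pairwise_differences(frame, "a", "b")
  expect_equal(d$n_substitutions, 1L)
  expect_equal(d$n_indel_columns, 1L)
  expect_equal(d$n_compared, 5L)
  expect_equal(d$percent, 40)

  same <- pairwise_differences(frame, "a", "a")
  expect_equal(same$percent, 0)

  expect_error(pairwise_differences(frame, "a", "zz"), "not in alignment")

  # columns where both members of the pair are gapped are excluded
  f2 <- toy_alignment(a = "AC--D", b = "AC--E", c = "ACFGD")
  d2 <- pairwise_differences(f2, "a", "b")
  expect_equal(d2$n_compared, 3L)
  expect_equal(d2$n_substitutions, 1L)

  # optional rules: indels not counted / shared denominator
  d3 <- pairwise_differences(frame, "a", "b", count_indels = FALSE,
                             denominator = "shared")
  expect_equal(d3$n_differences, 1L)
  expect_equal(d3$n_compared, 4L)
})

test_that("pairwise differences are symmetric and column-drop invariant", {
  for (seed in 1:5) {
    f <- random_alignment(4, 60, seed = seed)
    ab <- pairwise_differences(f, "r1", "r2")
    ba <- pairwise_differences(f, "r2", "r1")
    expect_equal(ab$n_substitutions, ba$n_substitutions)
    expect_equal(ab$n_indel_columns, ba$n_indel_columns)
    expect_equal(ab$percent, ba$percent)
  }
  # removing a column identical in all rows changes only the denominator
  f <- toy_alignment(a = "KACDF", b = "KACEF", c = "KAC-F")
  f_drop <- toy_alignment(a = "ACDF", b = "ACEF", c = "AC-F")
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    d1 <- pairwise_differences(f, pr[1], pr[2])
    d2 <- pairwise_differences(f_drop, pr[1], pr[2])
    expect_equal(d1$n_differences, d2$n_differences)
    expect_equal(d1$n_compared, d2$n_compared + 1L)
  }
})

test_that("divergence table covers all pairs and matches single calls", {
  f <- random_alignment(4, 50, seed = 3)
  tab <- divergence_table(f)
  expect_equal(nrow(tab), 4 * 5 / 2)
  one <- pairwise_differences(f, "r2", "r4")
  row <- tab[tab$id_a == "r2" & tab$id_b == "r4", ]
  expect_equal(row$percent, one$percent)
  expect_error(divergence_table(f, ids = c("r1", "nope")), "unknown id")
})

test_that("region projection walks columns correctly", {
  # identical ungapped rows: regions unchanged
  f <- toy_alignment(ref = "ABCD", tgt = "ABCD")
  r <- new_regions("r1", 2, 3, "ref")
  p <- project_regions(f, r, "tgt")
  expect_equal(p$start, 2L); expect_equal(p$end, 3L)
  expect_equal(p$n_residues, 2L)

  # region fully deleted in the target maps to an empty interval
  f2 <- toy_alignment(ref = "ABCD", tgt = "A--D")
  p2 <- project_regions(f2, r, "tgt")
  expect_true(is.na(p2$start) && is.na(p2$end))
  expect_equal(p2$n_residues, 0L)

  # insertion in target: hand column walk over a 5-column toy.
  # ref: A B - C D (residues 1..4 at columns 1,2,4,5)
  # tgt: A B X C D (residues 1..5)
  # region (1,2) on ref -> columns 1:2 -> target residues 1..2
  f3 <- toy_alignment(ref = "AB-CD", tgt = "ABXCD")
  p3 <- project_regions(f3, new_regions("r", 1, 2, "ref"), "tgt")
  expect_equal(c(p3$start, p3$end), c(1L, 2L))
  # region (2,3) spans the insertion: columns 2 and 4 -> residues 2..4
  p4 <- project_regions(f3, new_regions("r", 2, 3, "ref"), "tgt")
  expect_equal(c(p4$start, p4$end), c(2L, 4L))
  expect_equal(p4$n_residues, 2L)

  expect_error(project_regions(f3, new_regions("r", 1, 9, "ref"), "tgt"),
               "exceeds reference length")
})

test_that("per-residue identity matches a brute-force tally", {
  f <- toy_alignment(ref = "AC-DF", x = "ACEDF", y = "GC-DA", z = "AC--F")
  out <- per_residue_identity(f, "ref")
  m <- do.call(rbind, strsplit(f$aligned, ""))
  manual <- sapply(seq_len(5), function(j) mean(m[2:4, j] == m[1, j]))
  expect_equal(out$fraction[!out$ref_gap], manual[m[1, ] != "-"])
  expect_true(all(is.na(out$fraction[out$ref_gap])))

  # all-identical frame: fraction 1 and class 'complete' everywhere
  fid <- toy_alignment(ref = "ACDF", x = "ACDF", y = "ACDF")
  oid <- per_residue_identity(fid, "ref")
  expect_true(all(oid$fraction == 1))
  expect_true(all(oid$class == "complete"))

  # 2 of 4 matching -> 0.5 -> 'moderate' under the default banding
  f24 <- toy_alignment(ref = "A", a = "A", b = "A", c = "C", d = "C")
  o24 <- per_residue_identity(f24, "ref")
  expect_equal(o24$fraction, 0.5)
  expect_equal(o24$class, "moderate")
})

test_that("planted substitution rates are recovered within binomial error", {
  cfg <- sim_config(seed = 11, length = 400, n_species = 4,
                    rate_ordered = 0.15, rate_disordered = 0.15,
                    deletion_rate = 0)
  fam <- evolve_family(cfg)
  for (sp in setdiff(fam$frame$id, "root")) {
    d <- pairwise_differences(fam$frame, "root", sp)
    p_hat <- d$percent / 100
    se <- sqrt(0.15 * 0.85 / 400)
    expect_lt(abs(p_hat - 0.15), 3 * se)
  }
})
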