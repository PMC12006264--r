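helix_pair <- function(n = 30, seed = 5, displace = NULL) {
  # two rigidly related copies of one backbone, optional displaced span
  set.seed(seed)
  a <- make_backbone(n, "helix")
  b <- a
  if (!is.null(displace)) {
    sel <- b$resno >= displace$start & b$resno <= displace$end
    b$x[sel] <- b$x[sel] + displace$magnitude
  }
  rig <- random_rigid()
  xyz <- transform_points(as.matrix(b[, c("x", "y", "z")]), rig)
  b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
  frame <- toy_alignment(a = strrep("A", n), b = strrep("A", n))
  list(frame = frame, a = new_structure(a), b = new_structure(b))
}

test_that("pair_residues pairs mutually non-gap columns with CA atoms", {
  n <- 8
  a <- make_backbone(n, "helix", sequence = "ACDEFGHK")
  frame <- toy_alignment(a = "ACDEFGHK", b = "ACDEFGHK")
  p <- pair_residues(frame, "a", "b", a, a)
  expect_equal(nrow(p), n)
  expect_equal(p$resno_a, p$resno_b)

  # one side gapped at columns 3-5
  f2 <- toy_alignment(a = "ACDEFGHK", b = "AC---GHK")
  b2 <- make_backbone(5, "helix", sequence = "ACGHK")
  p2 <- pair_residues(f2, "a", "b", a, b2)
  expect_equal(p2$column, c(1, 2, 6, 7, 8))

  # a CA-less residue drops its column with a warning
  a_noca <- suppressWarnings(
    new_structure(dplyr::filter(a, !(resno == 4 & atom == "CA")))
  )
  expect_warning(p3 <- pair_residues(frame, "a", "b", a_noca, a),
                 "missing CA")
  expect_false(4 %in% p3$column)

  # model/alignment disagreement names the offending residue
  bad <- make_backbone(n, "helix", sequence = "ACDEFGHW")
  expect_error(pair_residues(frame, "a", "b", bad, a), "residue 8")
})

test_that("kabsch_fit recovers known transforms and refuses degenerate input", {
  set.seed(7)
  a <- matrix(rnorm(45), ncol = 3)
  expect_equal(kabsch_fit(a, a)$rotation, diag(3), tolerance = 1e-12)
  expect_equal(kabsch_fit(a, a)$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(kabsch_fit(a, a)$rmsd, 0, tolerance = 1e-12)

  rig <- random_rigid()
  b <- transform_points(a, list(rotation = t(rig$rotation),
                                translation = -as.numeric(
                                  t(rig$rotation) %*% rig$translation)))
  fit <- kabsch_fit(a, b)
  expect_lt(max(abs(transform_points(b, fit) - a)), 1e-9)
  det_r <- det(fit$rotation)
  expect_equal(det_r, 1, tolerance = 1e-9)
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-9)

  expect_error(kabsch_fit(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_fit(line, line), "collinear")
})

test_that("kabsch RMSD is rigid-invariant and beats random transforms", {
  set.seed(8)
  a <- matrix(rnorm(30), ncol = 3)
  b <- a + matrix(rnorm(30, sd = 0.3), ncol = 3)
  base <- kabsch_fit(a, b)$rmsd
  for (i in 1:5) {
    rig <- random_rigid()
    expect_equal(kabsch_fit(a, transform_points(b, rig))$rmsd, base,
                 tolerance = 1e-9)
    expect_equal(kabsch_fit(transform_points(a, rig), b)$rmsd, base,
                 tolerance = 1e-9)
  }
  # no random rigid placement does better than the least-squares optimum
  rand_rmsd <- replicate(200, {
    rig <- random_rigid()
    sqrt(mean(rowSums((transform_points(b, rig) - a)^2)))
  })
  expect_true(all(base <= rand_rmsd + 1e-12))
})

test_that("matchmaker pruning isolates a displaced residue", {
  hp <- helix_pair(n = 30, seed = 13,
                   displace = list(start = 15, end = 15, magnitude = 10))
  pairing <- pair_residues(hp$frame, "a", "b", hp$a, hp$b)
  res <- matchmaker_superpose(pairing, prune_cutoff = 2)
  expect_false(res$pairs$retained[res$pairs$column == 15])
  expect_equal(sum(!res$pairs$retained), 1L)
  expect_lt(res$rmsd, 1e-6)
  expect_equal(res$pairs$deviation[res$pairs$column == 15], 10,
               tolerance = 1e-6)

  # rigidly related structures: no pruning, single iteration
  hp0 <- helix_pair(n = 20, seed = 14)
  res0 <- matchmaker_superpose(pair_residues(hp0$frame, "a", "b",
                                             hp0$a, hp0$b))
  expect_true(all(res0$pairs$retained))
  expect_equal(res0$n_iter, 1L)
  expect_true(res0$converged)

  expect_error(matchmaker_superpose(pairing[1:2, ]), "at least 3")

  # determinism: identical input gives identical output
  res2 <- matchmaker_superpose(pairing, prune_cutoff = 2)
  expect_equal(res$pairs$deviation, res2$pairs$deviation)
  expect_equal(res$rotation, res2$rotation)
})

test_that("classification applies the 2 A rule gated by confidence", {
  hp <- helix_pair(n = 12, seed = 15)
  res <- matchmaker_superpose(pair_residues(hp$frame, "a", "b", hp$a, hp$b),
                              species_a = "a", species_b = "b")
  # plant deviations directly to probe the rule at its boundary
  res$pairs$deviation <- c(1.9, 2.1, 5.0, 2.0, rep(0.1, 8))
  res$pairs$plddt_a <- c(90, 90, 40, 90, rep(90, 8))
  out <- classify_pairs(res, rmsd_threshold = 2, plddt_threshold = 70)
  expect_equal(out$pairs$class[1], "matched")     # 1.9 A, confident
  expect_equal(out$pairs$class[2], "different")   # 2.1 A, confident
  expect_equal(out$pairs$class[3], "unscored")    # 5.0 A, one side low
  expect_equal(out$pairs$class[4], "different")   # exactly 2.0 A
  # masks take precedence over raw plDDT when provided
  mask <- tibble::tibble(resno = 1:12,
                         confidence_state = c("low", rep("confident", 11)))
  out2 <- classify_pairs(res, mask_a = mask, mask_b = mask)
  expect_equal(out2$pairs$class[1], "unscored")
})

test_that("species-specific differences require focal-only support", {
  make_set <- function(displaced_species, span = 10:14, n = 40, seed = 31) {
    set.seed(seed)
    root <- make_backbone(n, "helix")
    species <- paste0("sp", 1:4)
    models <- lapply(species, function(sp) {
      m <- root
      if (sp %in% displaced_species) {
        sel <- m$resno %in% span
        m$x[sel] <- m$x[sel] + 4
      }
      rig <- random_rigid()
      xyz <- transform_points(as.matrix(m[, c("x", "y", "z")]), rig)
      m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
      new_structure(m)
    })
    names(models) <- species
    frame <- new_alignment(species, rep(strrep("A", n), 4))
    prs <- utils::combn(species, 2, simplify = FALSE)
    setNames(lapply(prs, function(pr) {
      classify_pairs(matchmaker_superpose(
        pair_residues(frame, pr[1], pr[2], models[[pr[1]]], models[[pr[2]]]),
        species_a = pr[1], species_b = pr[2]
      ))
    }), sapply(prs, paste, collapse = "|"))
  }

  # clean set: nothing is species-specific
  res0 <- make_set(character(0))
  expect_equal(nrow(species_specific_differences(res0, "sp2")), 0L)

  # displacement in one species only: exactly the planted span, focal only
  res1 <- make_set("sp2")
  hits <- species_specific_differences(res1, "sp2")
  expect_equal(hits$column, 10:14)
  expect_equal(nrow(species_specific_differences(res1, "sp1")), 0L)

  # displacement shared by two species is specific to neither
  res2 <- make_set(c("sp2", "sp3"))
  expect_equal(nrow(species_specific_differences(res2, "sp2")), 0L)
  expect_equal(nrow(species_specific_differences(res2, "sp3")), 0L)
})
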