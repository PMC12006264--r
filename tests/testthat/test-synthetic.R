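test_that("helix backbones have ideal CA spacing and are deterministic", {
  bb <- make_backbone(50, "helix")
  ca <- dplyr::filter(bb, atom == "CA")
  steps <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(abs(steps - 3.8) < 0.1))
  # same seed, same coordinates; different seed differs
  b1 <- make_backbone(30, "coil", noise_sigma = 0.5, seed = 4)
  b2 <- make_backbone(30, "coil", noise_sigma = 0.5, seed = 4)
  b3 <- make_backbone(30, "coil", noise_sigma = 0.5, seed = 5)
  expect_identical(b1, b2)
  expect_false(isTRUE(all.equal(b1$x, b3$x)))
  expect_error(make_backbone(2), "at least 3")
})

test_that("coil backbones keep CA-CA steps within physical bounds", {
  for (seed in 1:3) {
    ca <- dplyr::filter(make_backbone(100, "coil", seed = seed), atom == "CA")
    steps <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
    expect_true(all(steps > 2.5 & steps < 4.5))
  }
})

test_that("evolve_family plants substitutions only where rates allow", {
  cfg0 <- sim_config(seed = 2, length = 120, rate_ordered = 0,
                     rate_disordered = 0, deletion_rate = 0,
                     ordered_spans = list(c(1L, 60L)),
                     displacement = tibble::tibble(
                       species = character(), start = integer(),
                       end = integer(), magnitude = numeric()
                     ),
                     regions = new_regions("r", 10, 20, "root",
                                           reference_length = 120),
                     interface_span = c(30L, 50L), partner_length = 20L)
  fam0 <- evolve_family(cfg0)
  expect_equal(nrow(fam0$truth), 0L)
  expect_true(all(fam0$frame$aligned == fam0$frame$aligned[1]))

  # rate only in the disordered region: all changes fall there
  cfg1 <- sim_config(seed = 3, length = 200, rate_ordered = 0,
                     rate_disordered = 0.2, deletion_rate = 0,
                     ordered_spans = list(c(1L, 100L)),
                     regions = new_regions("r", 10, 20, "root",
                                           reference_length = 200),
                     displacement = tibble::tibble(
                       species = character(), start = integer(),
                       end = integer(), magnitude = numeric()
                     ),
                     interface_span = c(30L, 50L), partner_length = 20L)
  fam1 <- evolve_family(cfg1)
  expect_gt(nrow(fam1$truth), 0L)
  expect_true(all(fam1$truth$column > 100))

  # inferred substitutions against the root equal the planted truth
  for (sp in unique(fam1$truth$species)) {
    inf <- infer_lineage_substitutions(fam1$frame, "root", sp)
    tru <- fam1$truth[fam1$truth$species == sp, ]
    expect_equal(inf$column, tru$column)
    expect_equal(inf$derived, tru$derived)
    expect_equal(inf$ancestral, tru$ancestral)
  }
})

test_that("bundles are deterministic and round trip through their files", {
  cfg <- sim_config(seed = 17, length = 80, partner_length = 20,
                    ordered_spans = list(c(31L, 80L)),
                    displacement = tibble::tibble(
                      species = "sp2", start = 60L, end = 62L, magnitude = 4
                    ),
                    regions = new_regions("core", 40, 70, "root",
                                          reference_length = 80),
                    interface_span = c(45L, 60L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- make_comparison_bundle(cfg, dir = d1)
  b2 <- make_comparison_bundle(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # every written file is readable by the format layer
  back <- read_bundle(d1)
  expect_equal(back$frame$aligned, b1$frame$aligned)
  for (sp in names(b1$models)) {
    expect_equal(
      dplyr::filter(back$models[[sp]], atom == "CA")$x,
      dplyr::filter(b1$models[[sp]], atom == "CA")$x,
      tolerance = 1e-3
    )
    expect_equal(unclass(back$pae[[sp]]), unclass(b1$pae[[sp]]),
                 tolerance = 1e-6)
    expect_equal(back$adopt[[sp]]$score, b1$adopt[[sp]]$score,
                 tolerance = 1e-6)
  }
  expect_equal(back$regions$name, "core")
})

test_that("planted displacements and contacts are recoverable from the bundle", {
  cfg <- sim_config(seed = 23, length = 100, partner_length = 20,
                    ordered_spans = list(c(41L, 100L)),
                    rate_ordered = 0.05, rate_disordered = 0.2,
                    deletion_rate = 0,
                    displacement = tibble::tibble(
                      species = "sp1", start = 70L, end = 74L, magnitude = 4
                    ),
                    regions = new_regions("core", 50, 90, "root",
                                          reference_length = 100),
                    interface_span = c(55L, 70L))
  b <- make_comparison_bundle(cfg)
  cmp <- run_comparison(b)
  hits <- cmp$species_specific
  expect_equal(sort(unique(hits$focal)), "sp1")
  expect_equal(hits$column, 70:74)
  # all planted (low-PAE span) contacts are found
  for (sp in names(b$complexes)) {
    found <- cmp$contacts[[sp]]
    truth <- b$contacts_truth[b$contacts_truth$species == sp, ]
    span_truth <- truth[truth$resno_a %in% 55:70, ]
    missing <- dplyr::anti_join(span_truth, found,
                                by = c("resno_a", "resno_b"))
    expect_equal(nrow(missing), 0L)
  }
})
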