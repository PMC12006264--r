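# two residues with controllable donor-acceptor geometry
geometry_fixture <- function(acceptor_xyz, acceptor_resno = 20L,
                             acceptor_chain = "A") {
  atom_structure(tibble::tibble(
    chain = c("A", "A", rep(acceptor_chain, 3)),
    resno = c(10L, 10L, rep(acceptor_resno, 3)),
    resname = "ALA",
    atom = c("CA", "N", "CA", "C", "O"),
    element = c("C", "N", "C", "C", "O"),
    x = c(-1.46, 0, acceptor_xyz[1] + 2, acceptor_xyz[1] + 1, acceptor_xyz[1]),
    y = c(0, 0, rep(acceptor_xyz[2], 3)),
    z = c(0, 0, rep(acceptor_xyz[3], 3)),
    plddt = 90
  ))
}

test_that("the distance criterion is base + tolerance, boundary-exact", {
  # N...O at 3.3 + 0.3 with a straight (180 degree) angle at the donor
  expect_equal(nrow(detect_hbonds(geometry_fixture(c(3.6, 0, 0)))), 1L)
  # at 3.3 + 0.5 the pair is out of reach of the 0.4 tolerance
  expect_equal(nrow(detect_hbonds(geometry_fixture(c(3.8, 0, 0)))), 0L)
  # widening the tolerance recovers it
  expect_equal(nrow(detect_hbonds(geometry_fixture(c(3.8, 0, 0)),
                                  dist_tol = 0.6)), 1L)
})

test_that("the angle criterion is base - tolerance at the donor", {
  place <- function(theta_deg) {
    th <- theta_deg * pi / 180
    # antecedent lies along -x, so the angle at the donor equals the angle
    # of the acceptor direction from +x ... measured from the -x axis
    c(3.0 * cos(th), 3.0 * sin(th), 0)
  }
  # angle(antecedent-donor-acceptor) = 180 - theta
  expect_equal(nrow(detect_hbonds(geometry_fixture(place(100)))), 1L) # 80 deg
  expect_equal(nrow(detect_hbonds(geometry_fixture(place(120)))), 0L) # 60 deg
  expect_equal(nrow(detect_hbonds(geometry_fixture(place(120)),
                                  angle_tol = 35)), 1L)
})

test_that("intra-chain bonds obey the more-than-five-residues rule", {
  near <- geometry_fixture(c(3.0, 0, 0), acceptor_resno = 14L)  # |i-j| = 4
  far <- geometry_fixture(c(3.0, 0, 0), acceptor_resno = 16L)   # |i-j| = 6
  edge <- geometry_fixture(c(3.0, 0, 0), acceptor_resno = 15L)  # |i-j| = 5
  expect_equal(nrow(detect_hbonds(near)), 0L)
  expect_equal(nrow(detect_hbonds(edge)), 0L)  # rule is strictly greater than
  expect_equal(nrow(detect_hbonds(far)), 1L)
  # the same geometry across chains is always catalogued
  inter <- geometry_fixture(c(3.0, 0, 0), acceptor_resno = 11L,
                            acceptor_chain = "B")
  bonds <- detect_hbonds(inter)
  expect_equal(nrow(bonds), 1L)
  expect_equal(bonds$scope, "inter")
})

test_that("CA-only residues far apart yield no bonds", {
  s <- ca_structure(cbind(c(0, 10), 0, 0), resno = c(1L, 20L))
  expect_equal(nrow(detect_hbonds(s)), 0L)
})

test_that("detect_hbonds equals the brute-force scan on varied fixtures", {
  fixtures <- list(
    make_backbone(60, "helix", seed = 1),
    make_backbone(200, "coil", noise_sigma = 0.2, seed = 2),
    make_backbone(500, "coil", seed = 3),
    { # two-chain complex with a close interface
      a <- make_backbone(40, "coil", seed = 4)
      b <- make_backbone(30, "coil", seed = 5, chain = "B")
      b <- dplyr::mutate(b, x = x - mean(x) + mean(a$x) + 4,
                         y = y - mean(y) + mean(a$y),
                         z = z - mean(z) + mean(a$z))
      new_structure(dplyr::bind_rows(a, b))
    }
  )
  for (fx in fixtures) {
    got <- hbond_keys(detect_hbonds(fx))
    expect_equal(got, hbond_oracle(fx))
  }
})

test_that("relaxing tolerances is monotone over a 5 x 5 grid", {
  fx <- make_backbone(120, "coil", noise_sigma = 0.3, seed = 6)
  dist_tols <- c(0, 0.2, 0.4, 0.6, 0.8)
  angle_tols <- c(0, 10, 20, 30, 40)
  sets <- lapply(dist_tols, function(dt) {
    lapply(angle_tols, function(at) {
      hbond_keys(detect_hbonds(fx, dist_tol = dt, angle_tol = at))
    })
  })
  for (i in seq_along(dist_tols)) {
    for (j in seq_along(angle_tols)) {
      if (i < length(dist_tols)) {
        expect_true(all(sets[[i]][[j]] %in% sets[[i + 1]][[j]]))
      }
      if (j < length(angle_tols)) {
        expect_true(all(sets[[i]][[j]] %in% sets[[i]][[j + 1]]))
      }
    }
  }
})

test_that("interface contacts honour the PAE-below-5 rule exactly", {
  a <- ca_structure(cbind(0, 0, c(0, 4)), chain = "A")
  b <- ca_structure(cbind(3, 0, c(0, 4)), chain = "B")
  pae <- matrix(10, 4, 4); diag(pae) <- 0
  # pair (A1, B1): indices 1 and 3 in concatenated order
  pae[1, 3] <- 6; pae[3, 1] <- 6
  pae[2, 4] <- 4; pae[4, 2] <- 4
  ct <- interface_contacts(a, b, new_pae(pae), pae_cutoff = 5,
                           dist_cutoff = 4)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$resno_a, 2L); expect_equal(ct$resno_b, 2L)
  expect_equal(ct$pae, 4)
  # asymmetric PAE uses the conservative max of the two directions
  pae2 <- pae; pae2[2, 4] <- 4.2; pae2[4, 2] <- 5.6
  expect_equal(nrow(interface_contacts(a, b, new_pae(pae2))), 0L)
  # dimension mismatch is refused
  expect_error(interface_contacts(a, b, new_pae(matrix(1, 3, 3))),
               "3 x 3.*4 residues")
  # chains far apart: empty
  far <- ca_structure(cbind(200, 0, c(0, 4)), chain = "B")
  expect_equal(nrow(interface_contacts(a, far, new_pae(pae))), 0L)
})

test_that("interface contacts match a brute-force distance scan and swap symmetrically", {
  set.seed(9)
  a <- make_backbone(30, "coil", seed = 10)
  b <- make_backbone(25, "coil", seed = 11, chain = "B")
  b <- dplyr::mutate(b, x = x - mean(x) + mean(a$x) + 5,
                     y = y - mean(y) + mean(a$y),
                     z = z - mean(z) + mean(a$z))
  b <- new_structure(b)
  got <- interface_contacts(a, b, pae = NULL, dist_cutoff = 4.5)
  # oracle: per-residue-pair minimum over explicit atom loops
  atoms_a <- split(tibble::as_tibble(a), a$resno)
  atoms_b <- split(tibble::as_tibble(b), b$resno)
  manual <- list()
  for (i in names(atoms_a)) for (j in names(atoms_b)) {
    pa <- atoms_a[[i]]; pb <- atoms_b[[j]]
    dmin <- Inf
    for (k in seq_len(nrow(pa))) {
      dmin <- min(dmin, sqrt((pa$x[k] - pb$x)^2 + (pa$y[k] - pb$y)^2 +
                               (pa$z[k] - pb$z)^2))
    }
    if (dmin <= 4.5) manual[[paste(i, j)]] <- dmin
  }
  expect_equal(paste(got$resno_a, got$resno_b), names(manual))
  expect_equal(got$distance, unname(unlist(manual)), tolerance = 1e-12)
  # swapping the chains transposes the pair identities
  swapped <- interface_contacts(b, a, pae = NULL, dist_cutoff = 4.5)
  expect_equal(
    sort(paste(got$resno_a, got$resno_b)),
    sort(paste(swapped$resno_b, swapped$resno_a))
  )
})

test_that("catalog comparison is null for identical catalogs and flags planted imbalance", {
  frame <- toy_alignment(sp1 = strrep("A", 40), sp2 = strrep("A", 40))
  bond <- function(i, j) tibble::tibble(
    donor_chain = "A", donor_resno = i, donor_atom = "N",
    acceptor_chain = "A", acceptor_resno = j, acceptor_atom = "O",
    distance = 3, angle = 120, scope = "intra"
  )
  cat1 <- dplyr::bind_rows(lapply(1:10, function(i) bond(i, i + 10)))
  out <- compare_catalogs(list(sp1 = cat1, sp2 = cat1), frame)
  expect_equal(out$tests$p_raw, rep(1, nrow(out$tests)))

  regions <- new_regions("hot", 1, 10, "sp1")
  cat2 <- dplyr::bind_rows(lapply(21:30, function(i) bond(i, i - 10)))
  out2 <- compare_catalogs(list(sp1 = cat1, sp2 = cat2), frame,
                           regions = regions)
  row <- out2$tests[out2$tests$category == "hot", ]
  # 10 vs 0 bonds touching the region, equal exposures: the enumeration
  # oracle gives the exact p, significant before correction
  expect_equal(row$p_raw, fisher_oracle(row$n_a, row$exposure_a - row$n_a,
                                        row$n_b, row$exposure_b - row$n_b))
  expect_lt(row$p_raw, 0.05)

  # empty catalogs: zero counts, tests skipped with a reason
  empty <- cat1[0, ]
  out3 <- compare_catalogs(list(sp1 = empty, sp2 = empty), frame)
  expect_true(all(out3$counts$n == 0))
  expect_true(all(out3$tests$skipped))
  expect_match(out3$tests$reason, "degenerate")
})
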