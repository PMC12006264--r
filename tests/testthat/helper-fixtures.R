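# shared fixture builders; all randomness is locally seeded

toy_alignment <- function(...) {
  rows <- c(...)
  new_alignment(names(rows), unname(rows))
}

# random gapped alignment used by property-style tests
random_alignment <- function(n_rows, n_cols, gap_p = 0.1, seed = 1) {
  set.seed(seed)
  repeat {
    rows <- replicate(n_rows, {
      ch <- sample(c("A", "C", "D", "E", "F", "G"), n_cols, replace = TRUE)
      ch[runif(n_cols) < gap_p] <- "-"
      paste0(ch, collapse = "")
    })
    m <- do.call(rbind, strsplit(rows, ""))
    ok_cols <- colSums(m != "-") > 0
    ok_rows <- apply(m != "-", 1, any)
    if (all(ok_cols) && all(ok_rows)) {
      return(new_alignment(paste0("r", seq_len(n_rows)), rows))
    }
    seed <- seed + 1000
    set.seed(seed)
  }
}

# minimal structure: CA-only residues at given coordinates
ca_structure <- function(xyz, chain = "A", resname = "ALA", plddt = 90,
                         resno = seq_len(nrow(xyz))) {
  new_structure(tibble::tibble(
    chain = chain, resno = resno,
    resname = rep_len(resname, nrow(xyz)),
    atom = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    plddt = rep_len(plddt, nrow(xyz))
  ))
}

# place single atoms freely (for constructed hydrogen-bond geometry)
atom_structure <- function(df) {
  new_structure(tibble::as_tibble(df))
}

random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  r <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
  list(rotation = r, translation = runif(3, -10, 10))
}

transform_points <- function(p, rigid) {
  t(rigid$rotation %*% t(p)) + rep(rigid$translation, each = nrow(p))
}

# enumeration oracle for the two-sided exact test: hypergeometric
# probabilities from choose(), summed over all tables with the observed
# margins whose probability does not exceed the observed one
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- choose(c1, support) * choose(c2, r1 - support) / choose(n, r1)
  p_obs <- choose(c1, a) * choose(c2, r1 - a) / choose(n, r1)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# brute-force hydrogen-bond scan: explicit loop over donor atoms against all
# acceptor atoms, sharing no code with detect_hbonds()
hbond_oracle <- function(model, dist_tol = 0.4, angle_tol = 20,
                         min_separation = 5) {
  da <- donor_acceptor_table()
  atoms <- dplyr::filter(tibble::as_tibble(model), !is_h)
  akey <- paste(atoms$chain, atoms$resno, atoms$atom)
  hits <- list()
  for (i in seq_len(nrow(atoms))) {
    drow <- da[da$resname == atoms$resname[i] & da$atom == atoms$atom[i] &
                 da$role == "donor", ]
    if (nrow(drow) == 0) next
    ant <- match(paste(atoms$chain[i], atoms$resno[i], drow$antecedent), akey)
    if (is.na(ant)) next
    d <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    v1 <- c(atoms$x[ant], atoms$y[ant], atoms$z[ant]) - d
    for (j in seq_len(nrow(atoms))) {
      if (atoms$chain[j] == atoms$chain[i] &&
          atoms$resno[j] == atoms$resno[i]) next
      arow <- da[da$resname == atoms$resname[j] & da$atom == atoms$atom[j] &
                   da$role == "acceptor", ]
      if (nrow(arow) == 0) next
      v2 <- c(atoms$x[j] - d[1], atoms$y[j] - d[2], atoms$z[j] - d[3])
      dist <- sqrt(sum(v2^2))
      if (dist > 3.3 + dist_tol) next
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * dist)))) * 180 / pi
      if (ang < 90 - angle_tol) next
      intra <- atoms$chain[i] == atoms$chain[j]
      if (intra && abs(atoms$resno[i] - atoms$resno[j]) <= min_separation) next
      hits[[length(hits) + 1L]] <- paste(
        atoms$chain[i], atoms$resno[i], atoms$atom[i],
        atoms$chain[j], atoms$resno[j], atoms$atom[j]
      )
    }
  }
  sort(as.character(unlist(hits)))
}

hbond_keys <- function(bonds) {
  sort(paste(bonds$donor_chain, bonds$donor_resno, bonds$donor_atom,
             bonds$acceptor_chain, bonds$acceptor_resno, bonds$acceptor_atom))
}

# independent recomputation of the distance table from the property columns,
# written as an explicit double loop so it shares no code with miyata_matrix()
recompute_miyata <- function() {
  props <- miyata_properties()
  sp <- sd(props$polarity); sv <- sd(props$volume)
  m <- matrix(0, 20, 20, dimnames = list(props$aa, props$aa))
  for (i in 1:20) {
    for (j in 1:20) {
      dp <- abs(props$polarity[i] - props$polarity[j]) / sp
      dv <- abs(props$volume[i] - props$volume[j]) / sv
      m[i, j] <- sqrt(dp^2 + dv^2)
    }
  }
  m
}
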