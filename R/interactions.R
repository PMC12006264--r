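#' Hydrogen-bond donor and acceptor atoms per residue type
#'
#' Heavy-atom donor/acceptor assignments for the 20 standard residues:
#' backbone N is a donor (except proline, whose nitrogen has no hydrogen) and
#' backbone O an acceptor for every type; side-chain assignments follow
#' standard chemistry (e.g. Ser OG both roles, Lys NZ donor, Asp OD1/OD2
#' acceptors). Each entry carries the antecedent heavy atom used to measure
#' the angle at the donor.
#'
#' @return Tibble `resname`, `atom`, `role` (`donor` / `acceptor`),
#'   `antecedent`.
#' @export
donor_acceptor_table <- function() {
  bb <- purrr::map_dfr(unname(AA_THREE[AA_CODES]), function(rn) {
    tibble::tibble(
      resname = rn,
      atom = c(if (rn != "PRO") "N", "O"),
      role = c(if (rn != "PRO") "donor", "acceptor"),
      antecedent = c(if (rn != "PRO") "CA", "C")
    )
  })
  sc <- tibble::tribble(
    ~resname, ~atom, ~role, ~antecedent,
    "ARG", "NE", "donor", "CD",
    "ARG", "NH1", "donor", "CZ",
    "ARG", "NH2", "donor", "CZ",
    "ASN", "ND2", "donor", "CG",
    "ASN", "OD1", "acceptor", "CG",
    "ASP", "OD1", "acceptor", "CG",
    "ASP", "OD2", "acceptor", "CG",
    "CYS", "SG", "donor", "CB",
    "CYS", "SG", "acceptor", "CB",
    "GLN", "NE2", "donor", "CD",
    "GLN", "OE1", "acceptor", "CD",
    "GLU", "OE1", "acceptor", "CD",
    "GLU", "OE2", "acceptor", "CD",
    "HIS", "ND1", "donor", "CG",
    "HIS", "ND1", "acceptor", "CG",
    "HIS", "NE2", "donor", "CE1",
    "HIS", "NE2", "acceptor", "CE1",
    "LYS", "NZ", "donor", "CE",
    "MET", "SD", "acceptor", "CG",
    "SER", "OG", "donor", "CB",
    "SER", "OG", "acceptor", "CB",
    "THR", "OG1", "donor", "CB",
    "THR", "OG1", "acceptor", "CB",
    "TRP", "NE1", "donor", "CD1",
    "TYR", "OH", "donor", "CZ",
    "TYR", "OH", "acceptor", "CZ"
  )
  dplyr::bind_rows(bb, sc)
}

#' Detect hydrogen bonds by geometric criteria
#'
#' Calls a hydrogen bond between a donor and an acceptor heavy atom when
#' their distance is at most `base_distance + dist_tol` and the angle at the
#' donor (antecedent-donor-acceptor) is at least `base_angle - angle_tol`.
#' Hydrogens are ignored; the criterion is deliberately a single documented,
#' monotone rule (relaxing either tolerance can only add bonds). Bonds within
#' a chain are catalogued only when the partner residues are more than
#' `min_separation` residues apart; bonds between chains are all catalogued.
#'
#' @param model A `struct_tbl` (one or two chains).
#' @param dist_tol Distance relaxation in Angstrom added to `base_distance`;
#'   default 0.4.
#' @param angle_tol Angle relaxation in degrees subtracted from `base_angle`;
#'   default 20.
#' @param min_separation Minimum intra-chain residue separation (bond kept
#'   when `|i - j| > min_separation`); default 5.
#' @param base_distance,base_angle The unrelaxed criterion: 3.3 Angstrom
#'   donor-acceptor distance and 90 degrees at the donor.
#' @param da_table Donor/acceptor assignments, see [donor_acceptor_table()].
#' @return Tibble `donor_chain`, `donor_resno`, `donor_atom`,
#'   `acceptor_chain`, `acceptor_resno`, `acceptor_atom`, `distance`,
#'   `angle`, `scope` (`intra` / `inter`).
#' @export
detect_hbonds <- function(model, dist_tol = 0.4, angle_tol = 20,
                          min_separation = 5, base_distance = 3.3,
                          base_angle = 90, da_table = donor_acceptor_table()) {
  heavy <- dplyr::filter(tibble::as_tibble(model), !.data$is_h)
  unknown <- setdiff(unique(heavy$resname), unique(da_table$resname))
  if (length(unknown) > 0L) {
    warn(sprintf("unknown residue type(s) skipped: %s",
                 paste(unknown, collapse = ", ")))
  }
  key <- function(df) paste(df$chain, df$resno, df$atom)
  donors <- heavy |>
    dplyr::inner_join(
      dplyr::filter(da_table, .data$role == "donor"),
      by = c("resname", "atom"), relationship = "many-to-many"
    )
  acceptors <- heavy |>
    dplyr::inner_join(
      dplyr::filter(da_table, .data$role == "acceptor"),
      by = c("resname", "atom"), relationship = "many-to-many"
    )
  if (nrow(donors) == 0L || nrow(acceptors) == 0L) return(empty_hbonds())
  # antecedent coordinates for the angle at the donor
  ante <- donors |>
    dplyr::inner_join(
      dplyr::select(heavy, "chain", "resno", antecedent = "atom",
                    ax = "x", ay = "y", az = "z"),
      by = c("chain", "resno", "antecedent")
    )
  if (nrow(ante) < nrow(donors)) {
    warn(sprintf("%d donor(s) without antecedent atom skipped",
                 nrow(donors) - nrow(ante)))
  }
  donors <- ante
  dm <- as.matrix(donors[, c("x", "y", "z")])
  am <- as.matrix(acceptors[, c("x", "y", "z")])
  d2 <- outer(rowSums(dm^2), rep(1, nrow(am))) +
    outer(rep(1, nrow(dm)), rowSums(am^2)) - 2 * dm %*% t(am)
  d2[d2 < 0] <- 0
  max_d <- base_distance + dist_tol
  hits <- which(d2 <= max_d^2, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty_hbonds())
  di <- hits[, 1]; ai <- hits[, 2]
  same_res <- donors$chain[di] == acceptors$chain[ai] &
    donors$resno[di] == acceptors$resno[ai]
  di <- di[!same_res]; ai <- ai[!same_res]
  if (length(di) == 0L) return(empty_hbonds())
  v1 <- as.matrix(donors[di, c("ax", "ay", "az")]) - dm[di, , drop = FALSE]
  v2 <- am[ai, , drop = FALSE] - dm[di, , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ok <- angle >= base_angle - angle_tol
  di <- di[ok]; ai <- ai[ok]; angle <- angle[ok]
  if (length(di) == 0L) return(empty_hbonds())
  out <- tibble::tibble(
    donor_chain = donors$chain[di], donor_resno = donors$resno[di],
    donor_atom = donors$atom[di],
    acceptor_chain = acceptors$chain[ai], acceptor_resno = acceptors$resno[ai],
    acceptor_atom = acceptors$atom[ai],
    distance = sqrt(d2[cbind(di, ai)]),
    angle = angle,
    scope = ifelse(donors$chain[di] == acceptors$chain[ai], "intra", "inter")
  )
  out |>
    dplyr::filter(.data$scope == "inter" |
                    abs(.data$donor_resno - .data$acceptor_resno) >
                      min_separation) |>
    dplyr::arrange(.data$donor_chain, .data$donor_resno, .data$donor_atom,
                   .data$acceptor_chain, .data$acceptor_resno,
                   .data$acceptor_atom)
}

empty_hbonds <- function() {
  tibble::tibble(
    donor_chain = character(), donor_resno = integer(),
    donor_atom = character(), acceptor_chain = character(),
    acceptor_resno = integer(), acceptor_atom = character(),
    distance = numeric(), angle = numeric(), scope = character()
  )
}

#' Interface contacts between two chains, filtered by PAE
#'
#' Returns residue pairs whose minimum heavy-atom distance is within
#' `dist_cutoff` and whose predicted aligned error is below `pae_cutoff`. The
#' PAE matrix is indexed over the concatenated residues of chain A then chain
#' B, and because PAE is asymmetric the conservative combination
#' `max(PAE[i, j], PAE[j, i])` is used.
#'
#' @param model_a,model_b Single-chain `struct_tbl`s.
#' @param pae A `pae_matrix` over the concatenated residues, or `NULL` to
#'   skip the confidence filter.
#' @param pae_cutoff Keep pairs with combined PAE strictly below this value
#'   (Angstrom); default 5.
#' @param dist_cutoff Maximum minimum heavy-atom distance (Angstrom);
#'   default 4.
#' @return Tibble `chain_a`, `resno_a`, `chain_b`, `resno_b`, `distance`,
#'   `pae` (`NA` when `pae` is `NULL`).
#' @export
interface_contacts <- function(model_a, model_b, pae = NULL, pae_cutoff = 5,
                               dist_cutoff = 4) {
  ha <- dplyr::filter(tibble::as_tibble(model_a), !.data$is_h)
  hb <- dplyr::filter(tibble::as_tibble(model_b), !.data$is_h)
  res_a <- unique(ha$resno); res_b <- unique(hb$resno)
  n_total <- length(res_a) + length(res_b)
  if (!is.null(pae) && nrow(pae) != n_total) {
    abort(sprintf("PAE matrix is %d x %d but the chains have %d residues",
                  nrow(pae), ncol(pae), n_total))
  }
  ma <- as.matrix(ha[, c("x", "y", "z")])
  mb <- as.matrix(hb[, c("x", "y", "z")])
  d2 <- outer(rowSums(ma^2), rep(1, nrow(mb))) +
    outer(rep(1, nrow(ma)), rowSums(mb^2)) - 2 * ma %*% t(mb)
  d2[d2 < 0] <- 0
  hits <- which(d2 <= dist_cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty_contacts())
  pairs <- tibble::tibble(
    chain_a = ha$chain[hits[, 1]], resno_a = ha$resno[hits[, 1]],
    chain_b = hb$chain[hits[, 2]], resno_b = hb$resno[hits[, 2]],
    distance = sqrt(d2[hits])
  ) |>
    dplyr::group_by(.data$chain_a, .data$resno_a, .data$chain_b,
                    .data$resno_b) |>
    dplyr::summarise(distance = min(.data$distance), .groups = "drop")
  if (is.null(pae)) {
    pairs$pae <- NA_real_
    return(pairs)
  }
  ia <- match(pairs$resno_a, res_a)
  ib <- length(res_a) + match(pairs$resno_b, res_b)
  pairs$pae <- pmax(pae[cbind(ia, ib)], pae[cbind(ib, ia)])
  dplyr::filter(pairs, .data$pae < pae_cutoff)
}

empty_contacts <- function() {
  tibble::tibble(
    chain_a = character(), resno_a = integer(),
    chain_b = character(), resno_b = integer(),
    distance = numeric(), pae = numeric()
  )
}

#' Compare interaction catalogs across species by category
#'
#' Maps each species' hydrogen bonds (or contacts) onto alignment columns,
#' counts them per category — total, each annotated region, ordered and
#' disordered — and runs pairwise Fisher exact tests with Bonferroni
#' correction through [compare_categories()]. A bond is counted in a region
#' when either partner residue falls in it, in `ordered`/`disordered` when
#' both partners share that state. Exposures are residue counts (protein
#' length, projected region size, per-state mask size).
#'
#' @param catalogs Named list (by species, rows of `frame`) of catalogs from
#'   [detect_hbonds()] or [interface_contacts()]; complexes are compared one
#'   chain-frame at a time via `chain`.
#' @param frame The `aln_frame` naming the species.
#' @param regions Optional `region_set` on a row of `frame`.
#' @param masks Optional named list (by species) of `order_mask`s.
#' @param chain When the catalogs come from a multi-chain complex, the chain
#'   whose residues `frame` describes; endpoints on other chains are not
#'   mapped (a bond with no endpoint on `chain` still counts in `total`).
#'   `NULL` (default) treats all endpoints as lying on the frame's protein.
#' @inheritParams compare_categories
#' @return A list with `counts` (per species/category, with exposures) and
#'   `tests` (the [compare_categories()] table). Empty catalogs yield zero
#'   counts and tests skipped with an explicit reason.
#' @export
compare_catalogs <- function(catalogs, frame, regions = NULL, masks = NULL,
                             chain = NULL, construct = "count_vs_exposure",
                             family_size = NULL) {
  missing <- setdiff(names(catalogs), frame$id)
  if (length(missing) > 0L) {
    abort(sprintf("species not in alignment: %s",
                  paste(missing, collapse = ", ")))
  }
  rcols <- if (!is.null(regions)) region_columns(frame, regions)
  counts <- purrr::imap_dfr(catalogs, function(cat, sp) {
    ends <- catalog_endpoints(cat)
    if (!is.null(chain)) {
      ends$resno_1[!is.na(ends$chain_1) & ends$chain_1 != chain] <- NA_integer_
      ends$resno_2[!is.na(ends$chain_2) & ends$chain_2 != chain] <- NA_integer_
    }
    r2c <- residue_to_column(frame, sp)
    col1 <- ifelse(is.na(ends$resno_1), NA_integer_, r2c[ends$resno_1])
    col2 <- ifelse(is.na(ends$resno_2), NA_integer_, r2c[ends$resno_2])
    len <- length(r2c)
    rows <- tibble::tibble(category = "total", n = nrow(ends),
                           exposure = len)
    if (!is.null(regions)) {
      proj <- project_regions(frame, regions, sp)
      for (nm in unique(regions$name)) {
        cc <- rcols$column[rcols$name == nm]
        in1 <- !is.na(col1) & col1 %in% cc
        in2 <- !is.na(col2) & col2 %in% cc
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          category = nm,
          n = sum(in1 | in2),
          exposure = proj$n_residues[proj$name == nm]
        ))
      }
    }
    if (!is.null(masks) && !is.null(masks[[sp]])) {
      mask <- masks[[sp]]
      st <- setNames(mask$order_state, mask$resno)
      s1 <- st[as.character(ends$resno_1)]
      s2 <- st[as.character(ends$resno_2)]
      # a bond is in a state when every on-chain endpoint shares it
      for (state in c("ordered", "disordered")) {
        ok1 <- is.na(ends$resno_1) | (!is.na(s1) & s1 == state)
        ok2 <- is.na(ends$resno_2) | (!is.na(s2) & s2 == state)
        any_on <- !is.na(ends$resno_1) | !is.na(ends$resno_2)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          category = state,
          n = sum(ok1 & ok2 & any_on),
          exposure = sum(mask$order_state == state)
        ))
      }
    }
    rows$group <- sp
    rows
  })
  tests <- compare_categories(counts, construct = construct,
                              family_size = family_size)
  list(counts = dplyr::relocate(counts, "group"), tests = tests)
}

# normalize hbond / contact schemas to two endpoints with chain labels
catalog_endpoints <- function(cat) {
  if (all(c("donor_resno", "acceptor_resno") %in% names(cat))) {
    tibble::tibble(
      chain_1 = cat$donor_chain %||% NA_character_,
      resno_1 = cat$donor_resno,
      chain_2 = cat$acceptor_chain %||% NA_character_,
      resno_2 = cat$acceptor_resno
    )
  } else if (all(c("resno_a", "resno_b") %in% names(cat))) {
    tibble::tibble(
      chain_1 = cat$chain_a %||% NA_character_,
      resno_1 = cat$resno_a,
      chain_2 = cat$chain_b %||% NA_character_,
      resno_2 = cat$resno_b
    )
  } else {
    abort("catalog is neither a hydrogen-bond nor a contact table")
  }
}
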