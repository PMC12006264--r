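#' Simulation configuration for a synthetic ortholog family
#'
#' Defines the conditions of a fully seeded synthetic comparison: a star
#' phylogeny of descendants from one ancestral ("root") protein with
#' region-specific substitution rates, optional short deletions, one or more
#' planted rigid displacements, planted disorder spans (low plDDT / low
#' Z-score), and a planted two-chain interface. The defaults describe a
#' 400-residue partially disordered protein in four species, diverging faster
#' in its disordered regions than in its ordered binding regions, with one
#' species carrying a single 5-residue positional change of 4 Angstrom in a
#' confident region — the situation the comparison pipeline is designed to
#' resolve.
#'
#' @param seed Integer seed; every random draw in the bundle derives from it.
#' @param n_species Number of descendant species, default 4.
#' @param length Root protein length, default 400.
#' @param ordered_spans Two-column matrix-like list of ordered spans
#'   (1-based inclusive) on the root; everything else is disordered.
#' @param rate_ordered,rate_disordered Per-residue substitution
#'   probabilities, defaults 0.08 and 0.25.
#' @param deletion_rate Expected number of short (1-3 residue) deletions per
#'   species, placed in disordered spans; default 1.
#' @param displacement Tibble `species`, `start`, `end`, `magnitude` (root
#'   coordinates, Angstrom); default one 5-residue, 4-Angstrom displacement
#'   in the third species inside an ordered span.
#' @param regions Region annotation on the root, a `region_set`; defaults to
#'   two ordered binding regions.
#' @param interface_span Root span forming the planted interface with the
#'   partner chain.
#' @param partner_length Length of the partner chain (chain B), default 60.
#' @param noise_sigma Gaussian coordinate noise per atom, Angstrom;
#'   default 0.05.
#' @param plddt_high,plddt_low plDDT written for ordered / disordered
#'   residues (92 and 40).
#' @param pae_low,pae_high PAE written for confident / unconfident residue
#'   pairs (2 and 15 Angstrom).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 4L,
                       length = 400L,
                       ordered_spans = NULL,
                       rate_ordered = 0.08,
                       rate_disordered = 0.25,
                       deletion_rate = 1,
                       displacement = NULL,
                       regions = NULL,
                       interface_span = NULL,
                       partner_length = 60L,
                       noise_sigma = 0.05,
                       plddt_high = 92, plddt_low = 40,
                       pae_low = 2, pae_high = 15) {
  stopifnot(length >= 3L, n_species >= 2L,
            rate_ordered >= 0, rate_ordered <= 1,
            rate_disordered >= 0, rate_disordered <= 1,
            noise_sigma >= 0)
  # unstated layout elements scale with the protein length; at the reference
  # length of 400 they are ordered spans 101-200 and 261-400, a 5-residue
  # 4 A displacement at 320-324 in sp3, binding regions 120-180 and 300-360,
  # and an interface span 300-340
  at <- function(f) as.integer(floor(f * length))
  if (is.null(ordered_spans)) {
    ordered_spans <- list(c(at(0.25) + 1L, at(0.5)), c(at(0.65) + 1L, length))
  }
  if (is.null(displacement)) {
    displacement <- tibble::tibble(
      species = "sp3", start = at(0.8), end = min(length, at(0.8) + 4L),
      magnitude = 4
    )
  }
  if (is.null(interface_span)) interface_span <- c(at(0.75), at(0.85))
  if (is.null(regions)) {
    regions <- new_regions(
      c("partner_binding", "effector_binding"),
      start = c(at(0.3), at(0.75)), end = c(at(0.45), at(0.9)),
      reference_id = "root", reference_length = length
    )
  }
  if (nrow(displacement) > 0 &&
      any(displacement$end > length | displacement$start < 1)) {
    abort("displacement span outside the root sequence")
  }
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         length = as.integer(length), ordered_spans = ordered_spans,
         rate_ordered = rate_ordered, rate_disordered = rate_disordered,
         deletion_rate = deletion_rate, displacement = displacement,
         regions = regions, interface_span = as.integer(interface_span),
         partner_length = as.integer(partner_length),
         noise_sigma = noise_sigma,
         plddt_high = plddt_high, plddt_low = plddt_low,
         pae_low = pae_low, pae_high = pae_high),
    class = "sim_config"
  )
}

# run code with a local, restored RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

ordered_mask_of <- function(config) {
  m <- rep(FALSE, config$length)
  for (sp in config$ordered_spans) m[sp[1]:sp[2]] <- TRUE
  m
}

#' Idealized backbone coordinates for a toy protein
#'
#' Generates CA, N, C and O positions for each residue along either an ideal
#' alpha-helix (radius 2.3 Angstrom, rise 1.5 Angstrom and 100-degree turn
#' per residue, giving consecutive CA-CA distances near 3.8 Angstrom) or a
#' smoothed random-walk coil, with optional Gaussian coordinate noise. The
#' peptide atoms are placed by simple geometric offsets from the CA trace;
#' the result is a chemically plausible toy, not a folded protein.
#'
#' @param length Number of residues, >= 3.
#' @param kind `"helix"` or `"coil"`.
#' @param noise_sigma Gaussian noise per coordinate, Angstrom.
#' @param sequence Optional one-letter sequence (defaults to poly-alanine).
#' @param chain Chain identifier, default `"A"`.
#' @param seed Optional seed for coil/noise draws.
#' @return A `struct_tbl` with plDDT 90 throughout.
#' @export
make_backbone <- function(length, kind = c("helix", "coil"),
                          noise_sigma = 0, sequence = NULL, chain = "A",
                          seed = NULL) {
  kind <- match.arg(kind)
  if (length < 3L) abort("backbone needs at least 3 residues")
  gen <- function() {
    ca <- if (kind == "helix") {
      th <- (seq_len(length) - 1) * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(length) - 1))
    } else {
      # smoothed random walk with ~3.8 A steps
      dirs <- matrix(rnorm(3 * length), ncol = 3)
      for (i in seq_len(length)[-1]) {
        dirs[i, ] <- 0.7 * dirs[i - 1, ] + 0.3 * dirs[i, ]
      }
      dirs <- dirs / sqrt(rowSums(dirs^2))
      apply(dirs * 3.8, 2, cumsum)
    }
    if (noise_sigma > 0) {
      ca <- ca + matrix(rnorm(3 * length, sd = noise_sigma), ncol = 3)
    }
    ca
  }
  ca <- if (is.null(seed)) gen() else with_seed(seed, gen())
  prev <- rbind(2 * ca[1, ] - ca[2, ], ca[-length, ])
  nxt <- rbind(ca[-1, ], 2 * ca[length, ] - ca[length - 1, ])
  unit <- function(v) v / sqrt(rowSums(v^2))
  n_at <- ca + 1.46 * unit(prev - ca)
  c_at <- ca + 1.52 * unit(nxt - ca)
  # carbonyl O offset radially away from the local chain axis
  perp <- unit(ca - (prev + nxt) / 2 + 1e-9)
  o_at <- c_at + 1.23 * perp
  seq1 <- if (is.null(sequence)) strrep("A", length) else sequence
  aa3 <- unname(AA_THREE[stringr::str_split_1(seq1, "")])
  aa3[is.na(aa3)] <- "UNK"
  per_res <- function(m, name, elem) {
    tibble::tibble(chain = chain, resno = seq_len(length), resname = aa3,
                   atom = name, element = elem,
                   x = m[, 1], y = m[, 2], z = m[, 3])
  }
  atoms <- dplyr::bind_rows(
    per_res(n_at, "N", "N"), per_res(ca, "CA", "C"),
    per_res(c_at, "C", "C"), per_res(o_at, "O", "O")
  ) |>
    dplyr::arrange(.data$resno, match(.data$atom, c("N", "CA", "C", "O")))
  atoms$plddt <- 90
  new_structure(atoms)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Evolve a star-phylogeny ortholog family from a root sequence
#'
#' Each descendant is drawn independently from the root: every position
#' substitutes with its region's rate (to a uniformly chosen different
#' residue), and short 1-3 residue deletions are planted in disordered
#' spans. The root doubles as the ancestral-node analog, so lineage-specific
#' substitution inference against it has exact ground truth.
#'
#' @param config A `sim_config`.
#' @param root_seq Optional root sequence; random by default.
#' @return List: `frame` (an `aln_frame` with rows `root`, `sp1`..`spN`),
#'   `truth` (tibble `species`, `column`, `ancestral`, `derived`) and
#'   `deletions` (tibble `species`, `start`, `end`, root coordinates).
#' @export
evolve_family <- function(config, root_seq = NULL) {
  with_seed(config$seed, {
    L <- config$length
    ord <- ordered_mask_of(config)
    rates <- ifelse(ord, config$rate_ordered, config$rate_disordered)
    root <- if (is.null(root_seq)) {
      paste0(sample(AA_CODES, L, replace = TRUE), collapse = "")
    } else root_seq
    root_ch <- stringr::str_split_1(root, "")
    species <- paste0("sp", seq_len(config$n_species))
    rows <- c(root = root)
    truth <- list(); dels <- list()
    for (sp in species) {
      ch <- root_ch
      hit <- runif(L) < rates
      for (i in which(hit)) ch[i] <- sample(setdiff(AA_CODES, ch[i]), 1)
      n_del <- stats::rpois(1, config$deletion_rate)
      del_spans <- list()
      dis_pos <- which(!ord)
      for (k in seq_len(n_del)) {
        if (length(dis_pos) < 5L) break
        w <- sample(1:3, 1)
        s <- sample(dis_pos[dis_pos <= L - w], 1)
        del_spans <- c(del_spans, list(c(s, s + w - 1L)))
        ch[s:(s + w - 1L)] <- "-"
      }
      sub_cols <- which(ch != root_ch & ch != "-")
      truth[[sp]] <- tibble::tibble(
        species = sp, column = sub_cols,
        ancestral = root_ch[sub_cols], derived = ch[sub_cols]
      )
      dels[[sp]] <- if (length(del_spans)) {
        tibble::tibble(species = sp,
                       start = vapply(del_spans, `[`, integer(1), 1),
                       end = vapply(del_spans, `[`, integer(1), 2))
      } else {
        tibble::tibble(species = character(), start = integer(),
                       end = integer())
      }
      rows[sp] <- paste0(ch, collapse = "")
    }
    list(
      frame = new_alignment(names(rows), unname(rows)),
      truth = dplyr::bind_rows(truth),
      deletions = dplyr::bind_rows(dels)
    )
  })
}

#' Generate the full synthetic comparison bundle
#'
#' Produces every input the pipeline consumes, with known ground truth:
#' sequences and the alignment (star phylogeny, root = ancestor), one
#' structure per species (a rigid, noised copy of the root backbone with the
#' displacement plan applied to the focal species, then a random rigid
#' transform per species), a two-chain complex per species with a planted
#' interface to an invariant partner chain, per-residue plDDT and ADOPT-like
#' Z tracks following the planted disorder spans, a complex PAE matrix that
#' is low inside ordered blocks and across the planted interface, the region
#' annotation, and a truth ledger.
#'
#' @param config A `sim_config`.
#' @param dir Optional directory: when given, all inputs are also written as
#'   files (FASTA, aligned FASTA, PDB, JSON PAE, TSV tracks/regions, JSON
#'   truth ledger) and their paths returned in `$paths`.
#' @return A list with the in-memory objects (`frame`, `truth`, `deletions`,
#'   `models`, `complexes`, `partner`, `plddt`, `adopt`, `pae`, `regions`,
#'   `config`) and, when `dir` is given, `paths`.
#' @export
make_comparison_bundle <- function(config, dir = NULL) {
  fam <- evolve_family(config)
  L <- config$length
  ord <- ordered_mask_of(config)
  species <- setdiff(fam$frame$id, "root")
  with_seed(config$seed + 1L, {
    root_bb <- make_backbone(L, "helix")
    partner_seq <- paste0(sample(AA_CODES, config$partner_length,
                                 replace = TRUE), collapse = "")
    partner_bb <- make_backbone(config$partner_length, "helix",
                                chain = "B", sequence = partner_seq)
    # park the partner helix alongside the interface span of chain A:
    # translate it so its midpoint sits ~6 A off the span midpoint
    span <- config$interface_span
    span_mid <- colMeans(as.matrix(
      dplyr::filter(root_bb, .data$atom == "CA",
                    .data$resno >= span[1],
                    .data$resno <= span[2])[, c("x", "y", "z")]
    ))
    b_mid <- colMeans(as.matrix(
      dplyr::filter(partner_bb, .data$atom == "CA")[, c("x", "y", "z")]
    ))
    offset <- span_mid + c(6, 0, 0) - b_mid
    partner_bb <- dplyr::mutate(partner_bb, x = .data$x + offset[1],
                                y = .data$y + offset[2],
                                z = .data$z + offset[3])
    plddt_root <- ifelse(ord, config$plddt_high, config$plddt_low)
    models <- list(); complexes <- list()
    plddt_tracks <- list(); adopt_tracks <- list()
    for (sp in species) {
      keep <- which(column_to_residue(fam$frame, sp) > 0)  # root positions kept
      mod <- dplyr::filter(root_bb, .data$resno %in% keep)
      # species sequence on the retained residues
      sp_seq <- stringr::str_split_1(ungap(fam$frame, sp), "")
      resmap <- match(mod$resno, keep)
      mod$resname <- unname(AA_THREE[sp_seq[resmap]])
      mod$plddt <- plddt_root[mod$resno]
      disp <- config$displacement[config$displacement$species == sp, ]
      if (nrow(disp) > 0) {
        for (r in seq_len(nrow(disp))) {
          sel <- mod$resno >= disp$start[r] & mod$resno <= disp$end[r]
          mod$x[sel] <- mod$x[sel] + disp$magnitude[r]
        }
      }
      if (config$noise_sigma > 0) {
        n <- nrow(mod)
        mod$x <- mod$x + rnorm(n, sd = config$noise_sigma)
        mod$y <- mod$y + rnorm(n, sd = config$noise_sigma)
        mod$z <- mod$z + rnorm(n, sd = config$noise_sigma)
      }
      cplx_b <- partner_bb
      # random rigid placement per species, applied to the whole complex
      rot <- random_rotation(); tra <- runif(3, -20, 20)
      place <- function(m) {
        xyz <- apply_transform(as.matrix(m[, c("x", "y", "z")]), rot, tra)
        m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
        m
      }
      mod <- place(mod); cplx_b <- place(cplx_b)
      # renumber to the species' own 1..n coordinates
      mod$resno <- resmap
      mod <- new_structure(mod)
      models[[sp]] <- mod
      complexes[[sp]] <- new_structure(dplyr::bind_rows(mod, cplx_b))
      res <- structure_residues(mod)
      plddt_tracks[[sp]] <- new_score_track(
        tibble::tibble(resno = res$resno, score = res$plddt),
        id = sp, kind = "plddt"
      )
      zroot <- ifelse(ord, 8, -2) + rnorm(L, sd = 0.3)
      adopt_tracks[[sp]] <- new_score_track(
        tibble::tibble(resno = seq_along(keep), score = zroot[keep]),
        id = sp, kind = "adopt_z"
      )
    }
    # complex PAE on root coordinates is shared across species structure,
    # but each species' matrix is sized to its own residue count
    pae <- list()
    for (sp in species) {
      keep <- which(column_to_residue(fam$frame, sp) > 0)
      nA <- length(keep); nB <- config$partner_length
      n <- nA + nB
      m <- matrix(config$pae_high, n, n)
      conf <- c(ord[keep], rep(TRUE, nB))
      m[conf, conf] <- config$pae_low
      # cross-chain confidence only near the planted interface
      span_res <- match(intersect(config$interface_span[1]:
                                    config$interface_span[2], keep), keep)
      cross_hi <- matrix(config$pae_high, nA, nB)
      cross_hi[span_res, ] <- config$pae_low
      m[seq_len(nA), nA + seq_len(nB)] <- cross_hi
      m[nA + seq_len(nB), seq_len(nA)] <- t(cross_hi)
      diag(m) <- 0
      pae[[sp]] <- new_pae(m)
    }
  })
  # planted truth for contacts: brute-force distance check written here,
  # independent of interface_contacts()
  contacts_truth <- purrr::imap_dfr(complexes, function(cx, sp) {
    parts <- structure_chains(cx)
    a <- dplyr::filter(parts[[1]], !.data$is_h)
    b <- dplyr::filter(parts[[2]], !.data$is_h)
    ma <- as.matrix(a[, c("x", "y", "z")])
    mb <- as.matrix(b[, c("x", "y", "z")])
    d2 <- outer(rowSums(ma^2), rep(1, nrow(mb))) +
      outer(rep(1, nrow(ma)), rowSums(mb^2)) - 2 * ma %*% t(mb)
    hit <- which(d2 <= 16, arr.ind = TRUE)
    if (nrow(hit) == 0L) {
      return(tibble::tibble(species = character(), resno_a = integer(),
                            resno_b = integer(), distance = numeric()))
    }
    tibble::tibble(
      species = sp, resno_a = a$resno[hit[, 1]], resno_b = b$resno[hit[, 2]],
      distance = sqrt(pmax(d2[hit], 0))
    ) |>
      dplyr::group_by(.data$species, .data$resno_a, .data$resno_b) |>
      dplyr::summarise(distance = min(.data$distance), .groups = "drop")
  })
  out <- list(
    config = config, frame = fam$frame, truth = fam$truth,
    deletions = fam$deletions, models = models, complexes = complexes,
    partner = partner_bb, plddt = plddt_tracks, adopt = adopt_tracks,
    pae = pae, regions = config$regions, contacts_truth = contacts_truth
  )
  if (!is.null(dir)) out$paths <- write_bundle(out, dir)
  out
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  species <- setdiff(bundle$frame$id, "root")
  p$alignment <- file.path(dir, "family_aln.fasta")
  write_fasta(bundle$frame, p$alignment)
  seqs <- tibble::tibble(
    id = bundle$frame$id, species = bundle$frame$id,
    residues = vapply(bundle$frame$id, function(i) ungap(bundle$frame, i), "")
  )
  p$sequences <- file.path(dir, "family_seqs.fasta")
  write_fasta(seqs, p$sequences)
  p$structures <- setNames(file.path(dir, paste0(species, ".pdb")), species)
  p$complexes <- setNames(file.path(dir, paste0(species, "_complex.pdb")),
                          species)
  p$pae <- setNames(file.path(dir, paste0(species, "_pae.json")), species)
  p$adopt <- setNames(file.path(dir, paste0(species, "_adopt.tsv")), species)
  for (sp in species) {
    write_structure(bundle$models[[sp]], p$structures[[sp]])
    write_structure(bundle$complexes[[sp]], p$complexes[[sp]])
    write_pae(bundle$pae[[sp]], p$pae[[sp]])
    write_score_track(bundle$adopt[[sp]], p$adopt[[sp]])
  }
  p$regions <- file.path(dir, "regions.tsv")
  readr::write_tsv(tibble::as_tibble(bundle$regions), p$regions)
  p$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = bundle$config$seed,
         substitutions = bundle$truth,
         deletions = bundle$deletions,
         displacement = bundle$config$displacement,
         interface_span = bundle$config$interface_span,
         contacts = bundle$contacts_truth),
    p$truth, digits = NA, dataframe = "columns"
  )
  p
}
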