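#' Pair residues of two structure models through the alignment
#'
#' Builds the residue pairing used for superposition: one pair per alignment
#' column where both species have a residue and both residues have a CA atom.
#' The model sequences must match their alignment rows exactly (the pairing is
#' meaningless otherwise), and CA-less residues are dropped with a warning.
#'
#' @param frame An `aln_frame`.
#' @param id_a,id_b Alignment rows of the two species.
#' @param model_a,model_b Single-chain `struct_tbl`s for the two species.
#' @return A tibble of class `residue_pairing`: `column`, `resno_a`,
#'   `resno_b`, CA coordinates `xa,ya,za,xb,yb,zb`, `plddt_a`, `plddt_b`;
#'   attribute `n_columns` records the alignment width for cross-result
#'   consistency checks.
#' @export
pair_residues <- function(frame, id_a, id_b, model_a, model_b) {
  check_model_matches(frame, id_a, model_a)
  check_model_matches(frame, id_b, model_b)
  res_a <- structure_residues(model_a)
  res_b <- structure_residues(model_b)
  col_a <- residue_to_column(frame, id_a)
  col_b <- residue_to_column(frame, id_b)
  a <- tibble::tibble(column = col_a, resno_a = res_a$resno,
                      xa = res_a$ca_x, ya = res_a$ca_y, za = res_a$ca_z,
                      plddt_a = res_a$plddt)
  b <- tibble::tibble(column = col_b, resno_b = res_b$resno,
                      xb = res_b$ca_x, yb = res_b$ca_y, zb = res_b$ca_z,
                      plddt_b = res_b$plddt)
  pairing <- dplyr::inner_join(a, b, by = "column") |>
    dplyr::relocate("column")
  no_ca <- !stats::complete.cases(pairing[, c("xa", "xb")])
  if (any(no_ca)) {
    warn(sprintf("%d paired column(s) dropped for missing CA atoms",
                 sum(no_ca)))
    pairing <- pairing[!no_ca, ]
  }
  attr(pairing, "n_columns") <- n_columns(frame)
  class(pairing) <- c("residue_pairing", class(pairing))
  pairing
}

check_model_matches <- function(frame, id, model) {
  seq_aln <- ungap(frame, id)
  seq_mod <- structure_sequence(model)
  if (!identical(seq_aln, seq_mod)) {
    n <- min(stringr::str_length(seq_aln), stringr::str_length(seq_mod))
    a <- stringr::str_split_1(seq_aln, "")
    m <- stringr::str_split_1(seq_mod, "")
    i <- which(a[seq_len(n)] != m[seq_len(n)])
    i <- if (length(i)) i[1] else n + 1L
    abort(sprintf(
      "model for '%s' disagrees with its alignment row at residue %d (alignment '%s' vs model '%s')",
      id, i,
      ifelse(i <= length(a), a[i], "<end>"),
      ifelse(i <= length(m), m[i], "<end>")
    ))
  }
  invisible(TRUE)
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the (weighted)
#' sum of squared distances between `R %*% b + t` and the corresponding points
#' of `points_a`, i.e. maps the second point set into the frame of the first.
#' A reflection in the SVD solution is corrected so `R` is always a proper
#' rotation (determinant +1).
#'
#' @param points_a,points_b Numeric n x 3 matrices, n >= 3, not collinear.
#' @param weights Optional non-negative weights of length n.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and `rmsd`
#'   (weighted RMSD of the fit, Angstrom).
#' @export
kabsch_fit <- function(points_a, points_b, weights = NULL) {
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L) {
    abort("point sets must be equal-size n x 3 matrices")
  }
  n <- nrow(a)
  if (n < 3L) abort("rigid superposition needs at least 3 point pairs")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  ca <- colSums(a * w); cb <- colSums(b * w)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  # degenerate (collinear) sets leave the fit under-determined
  if (qr(bc * sqrt(w))$rank < 2L || qr(ac * sqrt(w))$rank < 2L) {
    abort("degenerate point set: points are collinear")
  }
  h <- t(bc * w) %*% ac
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(ca - r %*% cb)
  fitted <- t(r %*% t(b)) + rep(tr, each = n)
  rmsd <- sqrt(sum(w * rowSums((fitted - a)^2)))
  list(rotation = r, translation = tr, rmsd = rmsd)
}

apply_transform <- function(points, rotation, translation) {
  t(rotation %*% t(as.matrix(points))) +
    rep(translation, each = nrow(as.matrix(points)))
}

#' Iteratively pruned rigid superposition of a residue pairing
#'
#' Superposes species B onto species A in the Matchmaker style: fit on the
#' retained pairs, drop every retained pair whose CA-CA deviation under the
#' current transform exceeds the prune cutoff, refit, and stop when the
#' retained set no longer changes, the iteration cap is hit, or fewer than 3
#' pairs would remain. Per-pair deviations for all pairs (pruned included)
#' are reported under the final transform, so a displaced residue keeps its
#' true deviation even after being excluded from the fit.
#'
#' @param pairing A `residue_pairing` from [pair_residues()] (>= 3 pairs).
#' @param prune_cutoff Deviation above which a pair is dropped from the fit,
#'   Angstrom; default 2.
#' @param max_iter Iteration cap, default 100.
#' @param species_a,species_b Optional labels stored in the result.
#' @return An object of class `superposition`: `rotation`, `translation`,
#'   `rmsd` (over retained pairs), `n_iter`, `converged`, and `pairs` (the
#'   pairing plus `deviation` and `retained`). Use [tidy()] / [glance()] for
#'   tabular views.
#' @export
matchmaker_superpose <- function(pairing, prune_cutoff = 2, max_iter = 100,
                                 species_a = "A", species_b = "B") {
  if (nrow(pairing) < 3L) abort("pairing must contain at least 3 pairs")
  pa <- as.matrix(pairing[, c("xa", "ya", "za")])
  pb <- as.matrix(pairing[, c("xb", "yb", "zb")])
  retained <- rep(TRUE, nrow(pairing))
  fit <- kabsch_fit(pa, pb)
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    fit <- kabsch_fit(pa[retained, , drop = FALSE],
                      pb[retained, , drop = FALSE])
    dev <- sqrt(rowSums((apply_transform(pb, fit$rotation, fit$translation) -
                           pa)^2))
    keep <- retained & dev <= prune_cutoff
    if (identical(keep, retained)) { converged <- TRUE; break }
    if (sum(keep) < 3L || n_iter >= max_iter) break
    retained <- keep
  }
  dev <- sqrt(rowSums((apply_transform(pb, fit$rotation, fit$translation) -
                         pa)^2))
  pairs <- pairing
  pairs$deviation <- dev
  pairs$retained <- retained
  structure(
    list(
      species_a = species_a, species_b = species_b,
      rotation = fit$rotation, translation = fit$translation,
      rmsd = sqrt(mean(dev[retained]^2)),
      n_iter = n_iter, converged = converged,
      prune_cutoff = prune_cutoff,
      n_columns = attr(pairing, "n_columns"),
      pairs = tibble::as_tibble(pairs)
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "<superposition> %s vs %s: %d pairs (%d retained), RMSD %.3f A, %d iteration(s)%s\n",
    x$species_a, x$species_b, nrow(x$pairs), sum(x$pairs$retained),
    x$rmsd, x$n_iter, if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Classify paired residues as matched / different / unscored
#'
#' Applies the 2-Angstrom rule to the per-pair CA deviations of a
#' superposition: a confidently placed pair deviating by less than the
#' threshold is `matched`, one at or above it is `different`, and a pair
#' where either residue is low-confidence is `unscored` (positional
#' differences in unreliable regions carry no information).
#'
#' @param result A `superposition`.
#' @param mask_a,mask_b Optional `order_mask`s (or [classify_confidence()]
#'   outputs) for the two species; when absent, confidence is taken from the
#'   models' plDDT at `plddt_threshold`.
#' @param rmsd_threshold Deviation threshold in Angstrom, default 2 (equality
#'   classifies as `different`).
#' @param plddt_threshold Fallback confidence cutoff when masks are absent.
#' @return The `superposition` with a `class` column added to `$pairs`.
#' @export
classify_pairs <- function(result, mask_a = NULL, mask_b = NULL,
                           rmsd_threshold = 2, plddt_threshold = 70) {
  p <- result$pairs
  conf_a <- pair_confident(p$resno_a, p$plddt_a, mask_a, plddt_threshold)
  conf_b <- pair_confident(p$resno_b, p$plddt_b, mask_b, plddt_threshold)
  p$class <- dplyr::case_when(
    !conf_a | !conf_b ~ "unscored",
    p$deviation < rmsd_threshold ~ "matched",
    TRUE ~ "different"
  )
  result$pairs <- p
  result$rmsd_threshold <- rmsd_threshold
  result
}

pair_confident <- function(resno, plddt, mask, plddt_threshold) {
  if (is.null(mask)) return(plddt >= plddt_threshold)
  state <- setNames(mask$confidence_state, mask$resno)[as.character(resno)]
  !is.na(state) & state == "confident"
}

#' Alignment columns structurally different in exactly one species
#'
#' Given classified superpositions for every species pair over the same
#' alignment, returns the columns classified `different` in every pairing
#' that involves the focal species while being `matched` in every pairing
#' among the remaining species — the signature of a positional change
#' confined to one lineage.
#'
#' @param results List of `superposition` objects (after [classify_pairs()])
#'   covering all pairs of the species set; all must derive from the same
#'   alignment.
#' @param focal Focal species label.
#' @return Tibble `column`, `n_focal_pairings`, `n_other_pairings` for the
#'   qualifying columns.
#' @export
species_specific_differences <- function(results, focal) {
  nc <- unique(vapply(results, function(r) r$n_columns %||% NA_integer_,
                      numeric(1)))
  if (length(nc) != 1L) {
    abort("superpositions derive from different alignments (column counts differ)")
  }
  per <- purrr::map_dfr(results, function(r) {
    if (!"class" %in% names(r$pairs)) {
      abort("run classify_pairs() on every superposition first")
    }
    tibble::tibble(
      species_a = r$species_a, species_b = r$species_b,
      column = r$pairs$column, class = r$pairs$class
    )
  })
  per$has_focal <- per$species_a == focal | per$species_b == focal
  n_focal_pairings <- length(unique(paste(
    per$species_a[per$has_focal], per$species_b[per$has_focal]
  )))
  verdict <- per |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(
      n_focal = sum(.data$has_focal),
      focal_all_diff = .data$n_focal > 0 &&
        all(.data$class[.data$has_focal] == "different"),
      others_all_match = all(.data$class[!.data$has_focal] == "matched"),
      n_other = sum(!.data$has_focal),
      .groups = "drop"
    )
  verdict |>
    dplyr::filter(.data$focal_all_diff, .data$others_all_match,
                  .data$n_focal == n_focal_pairings) |>
    dplyr::transmute(
      column = .data$column,
      n_focal_pairings = .data$n_focal,
      n_other_pairings = .data$n_other
    )
}
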