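#' Read a predicted structure model (PDB or mmCIF)
#'
#' Parses ATOM records into a per-atom tibble. Following the AlphaFold/ColabFold
#' convention, the B-factor column is interpreted as per-residue plDDT and is
#' taken from each residue's CA atom (with a warning and fallback to the first
#' atom when CA is absent). Hydrogens, if present, are retained and flagged in
#' `is_h` so geometric routines can ignore them.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A tibble of class `struct_tbl` with columns `chain`, `resno`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `is_h`, `plddt`. Chains
#'   appear in file order.
#' @seealso [write_structure()], [structure_chains()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- if (format == "cif") {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  }
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0L) abort(sprintf("no ATOM records in %s", path))
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 stringr::str_extract(at$elety, "^[A-Za-z]"), at$elesy)
  out <- tibble::tibble(
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = as.integer(at$resno),
    resname = at$resid,
    atom = at$elety,
    element = toupper(elem),
    x = at$x, y = at$y, z = at$z,
    is_h = toupper(elem) == "H",
    b = at$b
  )
  new_structure(out)
}

#' Construct a structure tibble from per-atom records
#'
#' Validates the structure invariants (strictly increasing residue numbers
#' within each chain, at least one heavy atom per residue, plDDT in 0-100)
#' and assigns per-residue plDDT from the CA B-factor.
#'
#' @param atoms A data frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z` and either `b` (per-atom B-factor) or `plddt`.
#' @return A `struct_tbl` tibble.
#' @export
new_structure <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  if (!"is_h" %in% names(atoms)) atoms$is_h <- toupper(atoms$element) == "H"
  if (!"b" %in% names(atoms)) atoms$b <- atoms$plddt
  for (ch in unique(atoms$chain)) {
    rn <- unique(atoms$resno[atoms$chain == ch])
    if (any(diff(rn) <= 0)) {
      abort(sprintf("residue numbers not strictly increasing in chain %s", ch))
    }
  }
  heavy <- atoms |>
    dplyr::group_by(.data$chain, .data$resno) |>
    dplyr::summarise(n_heavy = sum(!.data$is_h), .groups = "drop")
  if (any(heavy$n_heavy == 0L)) {
    bad <- heavy[heavy$n_heavy == 0L, ][1, ]
    abort(sprintf("residue %s/%d has no heavy atoms", bad$chain, bad$resno))
  }
  plddt_tbl <- atoms |>
    dplyr::group_by(.data$chain, .data$resno) |>
    dplyr::summarise(
      plddt = {
        ca <- .data$b[.data$atom == "CA"]
        if (length(ca) >= 1L) ca[1] else .data$b[1]
      },
      has_ca = any(.data$atom == "CA"),
      .groups = "drop"
    )
  if (any(!plddt_tbl$has_ca)) {
    warn(sprintf(
      "%d residue(s) lack a CA atom; plDDT taken from their first atom",
      sum(!plddt_tbl$has_ca)
    ))
  }
  if (any(plddt_tbl$plddt < 0 | plddt_tbl$plddt > 100, na.rm = TRUE)) {
    abort("plDDT (B-factor) values outside [0, 100]")
  }
  out <- atoms |>
    dplyr::select(-dplyr::any_of("plddt")) |>
    dplyr::left_join(
      dplyr::select(plddt_tbl, "chain", "resno", "plddt"),
      by = c("chain", "resno")
    ) |>
    dplyr::select(-"b")
  class(out) <- c("struct_tbl", class(out))
  out
}

#' Split a structure tibble into per-chain models
#'
#' @param model A `struct_tbl`, possibly multi-chain.
#' @return A named list of single-chain `struct_tbl`s in file (chain) order.
#' @export
structure_chains <- function(model) {
  ids <- unique(model$chain)
  setNames(lapply(ids, function(ch) {
    out <- dplyr::filter(model, .data$chain == ch)
    class(out) <- unique(c("struct_tbl", class(out)))
    out
  }), ids)
}

#' Per-residue summary of a structure
#'
#' @param model A `struct_tbl`.
#' @return Tibble with one row per residue: `chain`, `resno`, `resname`,
#'   `plddt`, plus CA coordinates (`NA` when CA is absent).
#' @export
structure_residues <- function(model) {
  ca <- model |>
    dplyr::filter(.data$atom == "CA") |>
    dplyr::select("chain", "resno", ca_x = "x", ca_y = "y", ca_z = "z")
  model |>
    dplyr::distinct(.data$chain, .data$resno, .data$resname, .data$plddt) |>
    dplyr::left_join(ca, by = c("chain", "resno"))
}

#' One-letter sequence of a (single-chain) structure
#'
#' @param model A `struct_tbl` with one chain.
#' @return A string of one-letter codes (`X` for unknown residue names).
#' @export
structure_sequence <- function(model) {
  stopifnot(length(unique(model$chain)) == 1L)
  res <- structure_residues(model)
  one <- AA_ONE[res$resname]
  one[is.na(one)] <- "X"
  paste0(one, collapse = "")
}

#' plDDT score track of a structure chain
#'
#' @param model A single-chain `struct_tbl`.
#' @param id Track identifier.
#' @return A score-track tibble (see [read_score_track()]) of kind `"plddt"`.
#' @export
plddt_track <- function(model, id = unique(model$chain)) {
  res <- structure_residues(model)
  new_score_track(tibble::tibble(resno = res$resno, score = res$plddt),
                  id = id, kind = "plddt")
}

#' Write a structure tibble to a PDB file
#'
#' The per-residue plDDT is written to the B-factor column of every atom,
#' mirroring the AlphaFold output convention.
#'
#' @param model A `struct_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(model)),
    resno = model$resno, resid = model$resname,
    chain = model$chain, elety = model$atom,
    b = round(model$plddt, 2), o = rep(1, nrow(model)),
    elesy = model$element
  )
  invisible(path)
}
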