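#' Read a predicted aligned error (PAE) matrix from JSON
#'
#' Accepts the two common encodings of an AlphaFold PAE matrix: a list of rows
#' (n lists of n values) or a flat list of n*n values in row-major order, in
#' either case optionally wrapped in an object (or singleton array of objects)
#' under a `predicted_aligned_error` or `pae` key. PAE values are expected
#' position errors in Angstrom and must be non-negative; the matrix need not
#' be symmetric.
#'
#' @param path Path to a JSON file.
#' @return An n x n numeric matrix of class `pae_matrix`.
#' @export
read_pae <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.data.frame(obj)) obj <- as.list(obj)
  if (is.list(obj) && !is.null(names(obj))) {
    key <- intersect(c("predicted_aligned_error", "pae"), names(obj))
    if (length(key) == 0L) abort("JSON object has no PAE key")
    obj <- obj[[key[1]]]
    if (is.list(obj) && length(obj) == 1L && !is.numeric(obj)) obj <- obj[[1]]
  }
  m <- if (is.matrix(obj)) {
    obj
  } else if (is.numeric(obj)) {
    n <- sqrt(length(obj))
    if (n != round(n)) {
      abort(sprintf(
        "flat PAE list of length %d is not a square number", length(obj)
      ))
    }
    matrix(obj, nrow = n, byrow = TRUE)
  } else {
    abort("unrecognized PAE JSON layout")
  }
  new_pae(m)
}

#' Construct a PAE matrix
#' @param m A square numeric matrix of non-negative values (Angstrom).
#' @return A `pae_matrix`.
#' @export
new_pae <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    abort(sprintf("PAE matrix is %d x %d, not square", nrow(m), ncol(m)))
  }
  if (any(m < 0)) abort("PAE values must be non-negative")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  class(m) <- c("pae_matrix", class(m))
  m
}

#' Write a PAE matrix to JSON (list-of-rows dialect)
#' @param pae A `pae_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pae <- function(pae, path) {
  jsonlite::write_json(
    list(predicted_aligned_error = unclass(pae)),
    path, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' Read a per-residue score track (plDDT or disorder Z-score)
#'
#' Reads a delimited table with a residue-number column and a score column,
#' such as the per-residue Z-score tables produced by the ADOPT disorder
#' predictor.
#'
#' @param path Path to a TSV/CSV file with columns `resno` and `score` (other
#'   column names are accepted positionally: first numeric-integer column is
#'   the residue number, next numeric column the score).
#' @param kind Track kind, `"plddt"` or `"adopt_z"`.
#' @param id Track identifier; defaults to the file name.
#' @return A tibble of class `score_track` with columns `resno`, `score` and
#'   attributes `kind` and `id`.
#' @export
read_score_track <- function(path, kind = c("adopt_z", "plddt"), id = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           comment = "#", col_types = readr::cols(.default = "c"))
  if (nrow(tab) == 0L) abort(sprintf("empty score track: %s", path))
  nm <- names(tab)
  res_col <- if ("resno" %in% nm) "resno" else nm[1]
  score_col <- if ("score" %in% nm) "score" else setdiff(nm, res_col)[1]
  resno <- suppressWarnings(as.integer(tab[[res_col]]))
  score <- suppressWarnings(as.numeric(tab[[score_col]]))
  if (anyNA(resno)) {
    abort(sprintf("non-integer residue number at row %d", which(is.na(resno))[1]))
  }
  if (anyNA(score)) {
    abort(sprintf("non-numeric score at row %d", which(is.na(score))[1]))
  }
  new_score_track(tibble::tibble(resno = resno, score = score),
                  id = id %||% basename(path), kind = kind)
}

#' Construct a score track
#' @param tab Tibble with integer `resno` and numeric `score`.
#' @param id Track identifier.
#' @param kind `"plddt"` or `"adopt_z"`.
#' @return A `score_track` tibble.
#' @export
new_score_track <- function(tab, id, kind = c("adopt_z", "plddt")) {
  kind <- match.arg(kind)
  tab <- tibble::as_tibble(tab[, c("resno", "score")])
  dup <- tab$resno[duplicated(tab$resno)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate residue number(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (is.unsorted(tab$resno, strictly = TRUE)) {
    abort("residue numbers must be strictly increasing")
  }
  attr(tab, "id") <- id
  attr(tab, "kind") <- kind
  class(tab) <- c("score_track", class(tab))
  tab
}

#' Write a score track to TSV
#' @param track A `score_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  readr::write_tsv(tibble::as_tibble(track[, c("resno", "score")]), path)
  invisible(path)
}

#' Read a region annotation table
#'
#' Regions are named intervals on a reference protein's residue coordinates
#' (1-based, inclusive), e.g. functional and binding regions of a protein as
#' mapped in a reference species. Overlapping regions are allowed.
#'
#' @param path TSV/CSV with columns `name`, `start`, `end`.
#' @param reference_id Identifier of the protein the coordinates refer to.
#' @param reference_length Optional known reference length used to validate
#'   `end`.
#' @return A tibble of class `region_set` with attribute `reference_id`.
#' @export
read_regions <- function(path, reference_id, reference_length = NULL) {
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           comment = "#")
  new_regions(tab$name, tab$start, tab$end, reference_id, reference_length)
}

#' Construct a region set
#' @param name Region names (unique).
#' @param start,end 1-based inclusive residue bounds on the reference.
#' @param reference_id Protein the coordinates refer to.
#' @param reference_length Optional length bound for validation.
#' @return A `region_set` tibble.
#' @export
new_regions <- function(name, start, end, reference_id,
                        reference_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(name)) abort("region names must be unique")
  if (any(start < 1L) || any(end < start)) {
    abort("regions require 1 <= start <= end")
  }
  if (!is.null(reference_length) && any(end > reference_length)) {
    bad <- name[end > reference_length][1]
    abort(sprintf("region '%s' exceeds reference length %d", bad,
                  reference_length))
  }
  out <- tibble::tibble(name = as.character(name), start = start, end = end)
  attr(out, "reference_id") <- reference_id
  class(out) <- c("region_set", class(out))
  out
}
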