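#' Residue/column coordinate maps for an alignment
#'
#' The alignment column is the shared coordinate system of the whole pipeline:
#' substitutions, structural deviations, hydrogen bonds and contacts are all
#' compared across species through it. This returns the bidirectional map in
#' long form: one row per (id, column), with `residue` giving the 1-based
#' residue index of that row at that column, or `0` when the row is gapped
#' there.
#'
#' @param frame An `aln_frame` from [read_alignment()] or [new_alignment()].
#' @return A tibble with columns `id`, `column`, `residue` (0 = gap) and `aa`
#'   (the character at that column, `-` for gaps).
#' @export
build_column_map <- function(frame) {
  nc <- n_columns(frame)
  purrr::map2_dfr(frame$id, frame$aligned, function(id, s) {
    ch <- stringr::str_split_1(s, "")
    tibble::tibble(
      id = id,
      column = seq_len(nc),
      residue = cumsum(ch != "-") * (ch != "-"),
      aa = ch
    )
  })
}

#' Map residue indices to alignment columns for one row
#'
#' @param frame An `aln_frame`.
#' @param id Row identifier.
#' @return Integer vector: position i is the alignment column of residue i.
#' @export
residue_to_column <- function(frame, id) {
  ch <- stringr::str_split_1(aln_row(frame, id), "")
  which(ch != "-")
}

#' Map alignment columns to residue indices for one row
#'
#' @param frame An `aln_frame`.
#' @param id Row identifier.
#' @return Integer vector of length `n_columns(frame)`; gapped columns are 0.
#' @export
column_to_residue <- function(frame, id) {
  ch <- stringr::str_split_1(aln_row(frame, id), "")
  as.integer(cumsum(ch != "-") * (ch != "-"))
}

#' Pairwise sequence differences between two alignment rows
#'
#' Counts, over the alignment columns, substitutions (both rows have a residue
#' and the residues differ) and indel columns (exactly one row is gapped).
#' Columns where both rows are gapped are excluded. Under the default rule an
#' indel column counts as a difference and the percent denominator is the
#' number of columns where at least one of the pair has a residue (the union
#' length); both choices are configurable because published divergence tables
#' rarely state them.
#'
#' @param frame An `aln_frame`.
#' @param id_a,id_b Row identifiers.
#' @param count_indels Should indel columns count as differences? Default TRUE.
#' @param denominator `"union"` (columns with >= 1 residue among the pair,
#'   default), `"shared"` (columns where both have residues), or `"length_a"`
#'   (ungapped length of `id_a`).
#' @return A one-row tibble: `id_a`, `id_b`, `n_substitutions`,
#'   `n_indel_columns`, `n_compared`, `n_differences`, `percent`,
#'   `percent_rounded`.
#' @export
pairwise_differences <- function(frame, id_a, id_b, count_indels = TRUE,
                                 denominator = c("union", "shared", "length_a")) {
  denominator <- match.arg(denominator)
  a <- stringr::str_split_1(aln_row(frame, id_a), "")
  b <- stringr::str_split_1(aln_row(frame, id_b), "")
  ga <- a == "-"; gb <- b == "-"
  n_sub <- sum(!ga & !gb & a != b)
  n_indel <- sum(xor(ga, gb))
  n_union <- sum(!(ga & gb))
  n_shared <- sum(!ga & !gb)
  n_compared <- switch(denominator,
    union = n_union, shared = n_shared, length_a = sum(!ga)
  )
  n_diff <- n_sub + if (count_indels) n_indel else 0L
  percent <- 100 * n_diff / n_compared
  tibble::tibble(
    id_a = id_a, id_b = id_b,
    n_substitutions = n_sub, n_indel_columns = n_indel,
    n_compared = n_compared, n_differences = n_diff,
    percent = percent, percent_rounded = round_half_up(percent)
  )
}

#' Full pairwise divergence table of an alignment
#'
#' @param frame An `aln_frame`.
#' @param ids Row identifiers to include (default all).
#' @inheritParams pairwise_differences
#' @return A tibble with one row per unordered pair (plus self pairs with zero
#'   differences), columns as in [pairwise_differences()].
#' @export
divergence_table <- function(frame, ids = frame$id, count_indels = TRUE,
                             denominator = c("union", "shared", "length_a")) {
  denominator <- match.arg(denominator)
  missing <- setdiff(ids, frame$id)
  if (length(missing) > 0L) {
    abort(sprintf("unknown id(s): %s", paste(missing, collapse = ", ")))
  }
  pairs <- tidyr::expand_grid(id_a = ids, id_b = ids) |>
    dplyr::filter(match(.data$id_a, ids) <= match(.data$id_b, ids))
  purrr::pmap_dfr(pairs, function(id_a, id_b) {
    pairwise_differences(frame, id_a, id_b, count_indels, denominator)
  })
}

#' Project reference-coordinate regions onto another alignment row
#'
#' Maps each region, defined on the reference row's residue coordinates,
#' through the alignment columns to a residue interval on the target row.
#' Columns where the target is gapped are dropped; a region whose columns are
#' all gapped in the target projects to an empty interval (`NA` bounds with
#' `n_residues = 0`).
#'
#' @param frame An `aln_frame` containing both rows.
#' @param regions A `region_set` whose `reference_id` attribute names a row of
#'   `frame`.
#' @param target_id Row to project onto.
#' @return A `region_set` on `target_id` with an extra `n_residues` column
#'   (number of target residues actually covered).
#' @export
project_regions <- function(frame, regions, target_id) {
  ref_id <- attr(regions, "reference_id")
  ref_cols <- residue_to_column(frame, ref_id)
  tgt_res <- column_to_residue(frame, target_id)
  if (any(regions$end > length(ref_cols))) {
    bad <- regions$name[regions$end > length(ref_cols)][1]
    abort(sprintf("region '%s' exceeds reference length %d", bad,
                  length(ref_cols)))
  }
  proj <- purrr::pmap_dfr(regions, function(name, start, end, ...) {
    cols <- ref_cols[start:end]
    res <- tgt_res[cols]
    res <- res[res > 0L]
    tibble::tibble(
      name = name,
      start = if (length(res)) min(res) else NA_integer_,
      end = if (length(res)) max(res) else NA_integer_,
      n_residues = length(res)
    )
  })
  out <- proj
  attr(out, "reference_id") <- target_id
  class(out) <- c("region_set", class(out))
  out
}

#' Columns of the alignment covered by regions, per row
#'
#' Convenience used by the stratified comparisons: the set of alignment
#' columns each named region occupies on the reference row.
#'
#' @param frame An `aln_frame`.
#' @param regions A `region_set` on a row of `frame`.
#' @return A tibble `name`, `column`.
#' @export
region_columns <- function(frame, regions) {
  ref_id <- attr(regions, "reference_id")
  ref_cols <- residue_to_column(frame, ref_id)
  if (any(regions$end > length(ref_cols))) {
    abort(sprintf("region exceeds reference length %d", length(ref_cols)))
  }
  purrr::pmap_dfr(regions, function(name, start, end, ...) {
    tibble::tibble(name = name, column = ref_cols[start:end])
  })
}

#' Per-column identity to a designated reference row
#'
#' For each alignment column, the fraction of non-reference rows whose
#' character (residue or gap) equals the reference row's residue at that
#' column, together with a coarse conservation class. Columns where the
#' reference is gapped are flagged and given `NA` fraction.
#'
#' @param frame An `aln_frame`.
#' @param reference_id Row identifier of the reference (e.g. an ancestral
#'   sequence).
#' @param thresholds Named numeric vector of lower bounds (fractions) for the
#'   conservation classes, tried in order; the default reproduces the
#'   complete / >=75% / >=50% / <50% banding.
#' @return A tibble `column`, `ref_residue`, `ref_gap`, `n_match`, `n_rows`,
#'   `fraction`, `class`.
#' @export
per_residue_identity <- function(frame, reference_id,
                                 thresholds = c(complete = 1, high = 0.75,
                                                moderate = 0.5, low = 0)) {
  stopifnot(all(diff(thresholds) < 0) || length(thresholds) == 1L)
  m <- alignment_matrix_chr(frame$aligned)
  rownames(m) <- frame$id
  ref <- unname(m[reference_id, ])
  others <- m[setdiff(frame$id, reference_id), , drop = FALSE]
  n_match <- unname(colSums(others == rep(ref, each = nrow(others))))
  frac <- n_match / nrow(others)
  cls <- names(thresholds)[
    vapply(frac, function(f) which(f >= thresholds)[1], integer(1))
  ]
  tibble::tibble(
    column = seq_len(ncol(m)),
    ref_residue = ref,
    ref_gap = ref == "-",
    n_match = as.integer(n_match),
    n_rows = nrow(others),
    fraction = ifelse(ref == "-", NA_real_, frac),
    class = ifelse(ref == "-", NA_character_, cls)
  )
}

# round half away from zero, the convention used for printed percentages
round_half_up <- function(x) {
  trunc(abs(x) + 0.5) * sign(x)
}
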