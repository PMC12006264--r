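#' Infer lineage-specific amino-acid substitutions against an ancestor
#'
#' Compares an ancestral-node row of the alignment with a descendant row and
#' returns one record per alignment column where both have residues and the
#' residues differ, scored with the Miyata biochemical distance. Columns where
#' exactly one of the two is gapped are indel events, which have no defined
#' biochemical distance and are reported separately by
#' [infer_lineage_indels()].
#'
#' @param frame An `aln_frame`.
#' @param ancestor_id,descendant_id Row identifiers.
#' @param miyata_cap Class cap passed to [miyata_class()].
#' @return A tibble with columns `column`, `lineage`, `ancestral`, `derived`,
#'   `residue` (descendant residue index), `miyata_raw`, `miyata_class`
#'   (`NA` raw distance and class when either residue is `X`).
#' @export
infer_lineage_substitutions <- function(frame, ancestor_id, descendant_id,
                                        miyata_cap = 4L) {
  anc <- stringr::str_split_1(aln_row(frame, ancestor_id), "")
  der <- stringr::str_split_1(aln_row(frame, descendant_id), "")
  idx <- which(anc != "-" & der != "-" & anc != der)
  der_res <- cumsum(der != "-")
  raw <- miyata_distance(anc[idx], der[idx])
  tibble::tibble(
    column = idx,
    lineage = descendant_id,
    ancestral = anc[idx],
    derived = der[idx],
    residue = der_res[idx],
    miyata_raw = raw,
    miyata_class = ifelse(is.na(raw), NA_integer_, miyata_class(raw, miyata_cap))
  )
}

#' Lineage-specific insertion/deletion columns
#'
#' @inheritParams infer_lineage_substitutions
#' @return A tibble `column`, `lineage`, `event` (`"insertion"` when the
#'   descendant has a residue the ancestor lacks, `"deletion"` otherwise),
#'   `residue` (descendant residue index, `NA` for deletions).
#' @export
infer_lineage_indels <- function(frame, ancestor_id, descendant_id) {
  anc <- stringr::str_split_1(aln_row(frame, ancestor_id), "")
  der <- stringr::str_split_1(aln_row(frame, descendant_id), "")
  idx <- which(xor(anc == "-", der == "-"))
  der_res <- cumsum(der != "-")
  tibble::tibble(
    column = idx,
    lineage = descendant_id,
    event = as.character(ifelse(anc[idx] == "-", "insertion", "deletion")),
    residue = as.integer(ifelse(der[idx] == "-", NA_integer_, der_res[idx]))
  )
}

#' Stratify substitution records by region and order state
#'
#' Tags each record with the functional/binding regions its alignment column
#' falls in (a record inside two overlapping regions is counted once per
#' region) and with the descendant's ordered/disordered state, then counts
#' records per (category, lineage, Miyata class). Each category also carries
#' its exposure: the number of descendant residues available in that category,
#' the denominator used by the exact tests.
#'
#' @param records Substitution records from [infer_lineage_substitutions()]
#'   (rows from several lineages may be bound together).
#' @param frame The `aln_frame` the records were inferred on.
#' @param regions Optional `region_set` on a row of `frame`.
#' @param masks Optional named list (by lineage id) of order masks from
#'   [consensus_mask()] (tibbles with `resno`, `order_state`).
#' @return A tibble `lineage`, `category`, `miyata_class`, `n`, `exposure`.
#'   Categories are `"total"`, one per region name, and (when masks are
#'   given) `"ordered"`, `"disordered"`.
#' @export
stratify_substitutions <- function(records, frame, regions = NULL,
                                   masks = NULL) {
  lineages <- unique(records$lineage)
  if (length(lineages) == 0L) lineages <- character(0)
  out <- purrr::map_dfr(lineages, function(lin) {
    rec <- records[records$lineage == lin, ]
    len <- stringr::str_length(ungap(frame, lin))
    rows <- count_by_class(rec, "total", len)
    if (!is.null(regions)) {
      rcols <- region_columns(frame, regions)
      proj <- project_regions(frame, regions, lin)
      for (nm in unique(regions$name)) {
        inside <- rec[rec$column %in% rcols$column[rcols$name == nm], ]
        expo <- proj$n_residues[proj$name == nm]
        rows <- dplyr::bind_rows(rows, count_by_class(inside, nm, expo))
      }
    }
    if (!is.null(masks) && !is.null(masks[[lin]])) {
      mask <- masks[[lin]]
      state <- setNames(mask$order_state, mask$resno)[as.character(rec$residue)]
      state[is.na(state)] <- "unscored"
      for (st in c("ordered", "disordered")) {
        rows <- dplyr::bind_rows(
          rows,
          count_by_class(rec[state == st, ], st,
                         sum(mask$order_state == st))
        )
      }
    }
    rows$lineage <- lin
    rows
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(lineage = character(), category = character(),
                          miyata_class = integer(), n = integer(),
                          exposure = integer()))
  }
  dplyr::relocate(out, "lineage")
}

# zero-count rows are kept for classes 0..4 so every category carries its
# exposure even when empty; an NA-class row appears only for unscored ('X')
count_by_class <- function(rec, category, exposure) {
  classes <- 0:4
  if (anyNA(rec$miyata_class)) classes <- c(classes, NA_integer_)
  tibble::tibble(
    category = category,
    miyata_class = as.integer(classes),
    n = vapply(classes, function(k) {
      if (is.na(k)) sum(is.na(rec$miyata_class)) else
        sum(rec$miyata_class == k, na.rm = TRUE)
    }, integer(1)),
    exposure = as.integer(exposure)
  )
}

#' Ratio of substitutions (or bonds) in ordered vs disordered regions
#'
#' @param counts Output of [stratify_substitutions()] or any tibble with
#'   `lineage` (or `group`), `category` and `n`.
#' @return Per lineage: ordered count, disordered count, and their ratio,
#'   `NA` when the disordered count is zero (an explicit undefined value,
#'   never `Inf`).
#' @export
ordered_disordered_ratio <- function(counts) {
  grp <- if ("lineage" %in% names(counts)) "lineage" else "group"
  wide <- counts |>
    dplyr::filter(.data$category %in% c("ordered", "disordered")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp)), .data$category) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (col in c("ordered", "disordered")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  dplyr::mutate(wide, ratio = ifelse(.data$disordered == 0, NA_real_,
                                     .data$ordered / .data$disordered))
}

#' Exact tests on stratified substitution counts
#'
#' Aggregates the per-class counts of [stratify_substitutions()] (optionally
#' restricted to one Miyata class) and runs the category-stratified Fisher
#' comparisons between all lineage pairs via [compare_categories()].
#'
#' @param counts Output of [stratify_substitutions()].
#' @param miyata_class Optional single class to restrict to.
#' @inheritParams compare_categories
#' @return See [compare_categories()].
#' @export
compare_substitution_categories <- function(counts, miyata_class = NULL,
                                            construct = "count_vs_exposure",
                                            family_size = NULL) {
  if (!is.null(miyata_class)) {
    k <- miyata_class
    counts <- counts[!is.na(counts$miyata_class) & counts$miyata_class == k, ]
  }
  agg <- counts |>
    dplyr::group_by(group = .data$lineage, .data$category) |>
    dplyr::summarise(n = sum(.data$n), exposure = .data$exposure[1],
                     .groups = "drop")
  compare_categories(agg, construct = construct, family_size = family_size)
}
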