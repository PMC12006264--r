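#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Computes the exact two-sided p-value by the probability-mass rule: with all
#' margins fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 guards ties), the standard convention for two-sided
#' exact tests on 2 x 2 tables.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`; `a` may
#'   also be a 2 x 2 matrix with `b`, `c`, `d` missing.
#' @return The two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact(5, 5, 5, 5) # 1
#' fisher_exact(3, 0, 0, 3)
fisher_exact <- function(a, b, c, d) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)) || any(!is.finite(cells))) {
    abort("cells must be finite non-negative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0L) {
    abort("degenerate 2 x 2 table: a zero margin leaves nothing to test")
  }
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(support, c1, c2, r1)
  p_obs <- dhyper(a, c1, c2, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Bonferroni adjustment with an explicit family size
#'
#' Multiplies each raw p-value by the declared family size `m` and caps at 1.
#' Unlike `p.adjust(..., "bonferroni")`, the family size may exceed the number
#' of p-values supplied, which is needed when a family of category tests is
#' adjusted jointly but reported in separate tables.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(p)` and at least 1.
#' @return Adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) abort("family size m must be >= 1")
  if (m < length(p)) {
    abort(sprintf("family size m = %d is smaller than the %d tests supplied",
                  m, length(p)))
  }
  pmin(1, m * p)
}

#' Category-stratified exact comparisons between groups
#'
#' The shared test harness behind the substitution and interaction
#' comparisons: for every category and every unordered pair of groups, build
#' a 2 x 2 table from the per-group count and exposure, run [fisher_exact()],
#' and Bonferroni-adjust over the family of all tests actually performed.
#'
#' Two table constructions are supported. `"count_vs_exposure"` tests the
#' per-category count against the remaining exposure
#' (`rbind(c(n_a, e_a - n_a), c(n_b, e_b - n_b))`); `"count_vs_count"` tests
#' the category count against the group's remaining events
#' (`rbind(c(n_a, total_a - n_a), c(n_b, total_b - n_b))`, requiring a
#' `"total"` category).
#'
#' @param counts Tibble with columns `category`, `group`, `n` and (for the
#'   exposure construction) `exposure`.
#' @param construct Table construction, see above.
#' @param family_size Bonferroni family size `m`; default the number of tests
#'   performed here.
#' @return A tibble with one row per (category, group pair): counts,
#'   exposures, `p_raw`, `p_adjusted`, `m`, and `skipped`/`reason` for
#'   degenerate tables (zero margins), which receive `NA` p-values rather
#'   than a fabricated test.
#' @export
compare_categories <- function(counts,
                               construct = c("count_vs_exposure",
                                             "count_vs_count"),
                               family_size = NULL) {
  construct <- match.arg(construct)
  stopifnot(all(c("category", "group", "n") %in% names(counts)))
  if (construct == "count_vs_exposure" && !"exposure" %in% names(counts)) {
    abort("construct 'count_vs_exposure' needs an 'exposure' column")
  }
  if (construct == "count_vs_count") {
    tot <- counts |> dplyr::filter(.data$category == "total")
    if (nrow(tot) == 0L) abort("construct 'count_vs_count' needs a 'total' category")
    counts <- counts |>
      dplyr::left_join(dplyr::select(tot, "group", total = "n"), by = "group")
  }
  groups <- unique(counts$group)
  pairs <- tidyr::expand_grid(group_a = groups, group_b = groups) |>
    dplyr::filter(match(.data$group_a, groups) < match(.data$group_b, groups))
  grid <- tidyr::expand_grid(category = unique(counts$category), pairs)
  rows <- purrr::pmap_dfr(grid, function(category, group_a, group_b) {
    ca <- counts[counts$category == category & counts$group == group_a, ]
    cb <- counts[counts$category == category & counts$group == group_b, ]
    n_a <- if (nrow(ca)) ca$n[1] else 0L
    n_b <- if (nrow(cb)) cb$n[1] else 0L
    e_a <- switch(construct,
      count_vs_exposure = if (nrow(ca)) ca$exposure[1] else NA_real_,
      count_vs_count = if (nrow(ca)) ca$total[1] else NA_real_
    )
    e_b <- switch(construct,
      count_vs_exposure = if (nrow(cb)) cb$exposure[1] else NA_real_,
      count_vs_count = if (nrow(cb)) cb$total[1] else NA_real_
    )
    tab <- c(n_a, e_a - n_a, n_b, e_b - n_b)
    degenerate <- anyNA(tab) || any(tab < 0) ||
      min(n_a + n_b, (e_a - n_a) + (e_b - n_b), e_a, e_b) == 0
    tibble::tibble(
      category = category, group_a = group_a, group_b = group_b,
      n_a = n_a, n_b = n_b, exposure_a = e_a, exposure_b = e_b,
      p_raw = if (degenerate) NA_real_ else
        fisher_exact(n_a, e_a - n_a, n_b, e_b - n_b),
      skipped = degenerate,
      reason = if (degenerate) "degenerate margins (zero counts)" else
        NA_character_
    )
  })
  m <- family_size %||% sum(!rows$skipped)
  m <- max(m, 1L)
  rows$m <- m
  rows$p_adjusted <- ifelse(rows$skipped, NA_real_,
                            bonferroni_adjust_each(rows$p_raw, m))
  rows |>
    dplyr::relocate("p_adjusted", .after = "p_raw")
}

# vectorized min(1, m*p) preserving NA without family-size length checks
bonferroni_adjust_each <- function(p, m) pmin(1, m * p)
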