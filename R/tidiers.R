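#' Tidy a superposition into its per-pair table
#'
#' @param x A `superposition`.
#' @param ... Unused.
#' @return A tibble with one row per residue pair: species labels, alignment
#'   column, residue numbers, deviation, retained flag and (after
#'   [classify_pairs()]) the matched/different/unscored class.
#' @method tidy superposition
#' @export
tidy.superposition <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(species_a = x$species_a, species_b = x$species_b),
    x$pairs
  )
}

#' One-row summary of a superposition
#'
#' @param x A `superposition`.
#' @param ... Unused.
#' @return A one-row tibble: RMSD over retained pairs, pair counts, iteration
#'   count, convergence flag and per-class tallies when classified.
#' @method glance superposition
#' @export
glance.superposition <- function(x, ...) {
  out <- tibble::tibble(
    species_a = x$species_a, species_b = x$species_b,
    n_pairs = nrow(x$pairs), n_retained = sum(x$pairs$retained),
    rmsd = x$rmsd, n_iter = x$n_iter, converged = x$converged
  )
  if ("class" %in% names(x$pairs)) {
    out$n_matched <- sum(x$pairs$class == "matched")
    out$n_different <- sum(x$pairs$class == "different")
    out$n_unscored <- sum(x$pairs$class == "unscored")
  }
  out
}

#' One-row summary of a full comparison
#'
#' @param x An `ortho_comparison` from [run_comparison()].
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities: species count,
#'   divergence range, substitution and indel totals, species-specific
#'   difference columns, and significant interaction categories.
#' @method glance ortho_comparison
#' @export
glance.ortho_comparison <- function(x, ...) {
  div <- x$divergence[x$divergence$id_a != x$divergence$id_b, ]
  sig <- function(cmp) {
    if (is.null(cmp)) NA_integer_
    else sum(cmp$tests$p_adjusted < 0.05, na.rm = TRUE)
  }
  tibble::tibble(
    n_species = length(x$species),
    min_percent_divergence = min(div$percent),
    max_percent_divergence = max(div$percent),
    n_substitutions = nrow(x$substitutions),
    n_indel_columns = nrow(x$indels),
    n_species_specific_columns = if (is.null(x$species_specific)) NA_integer_
      else nrow(x$species_specific),
    n_sig_substitution_categories =
      sum(x$substitution_tests$p_adjusted < 0.05, na.rm = TRUE),
    n_sig_hbond_categories = sig(x$hbond_comparison),
    n_sig_contact_categories = sig(x$contact_comparison)
  )
}

#' Per-residue deviation plot of a superposition
#'
#' @param object A `superposition` (ideally after [classify_pairs()]).
#' @param ... Unused.
#' @return A ggplot: CA deviation per alignment column, colored by class,
#'   with the matched/different threshold drawn when available.
#' @method autoplot superposition
#' @export
autoplot.superposition <- function(object, ...) {
  d <- tidy(object)
  if (!"class" %in% names(d)) d$class <- ifelse(d$retained, "retained",
                                                "pruned")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = .data$deviation,
                                       colour = .data$class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "alignment column", y = "CA deviation (Å)",
      title = sprintf("%s vs %s", object$species_a, object$species_b),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$rmsd_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$rmsd_threshold,
                                 linetype = "dashed")
  }
  p
}

#' Heatmap of pairwise sequence divergence
#'
#' @param divergence Output of [divergence_table()].
#' @param value `"percent"` or `"n_differences"`.
#' @return A ggplot tile plot of the symmetric divergence matrix.
#' @export
plot_divergence <- function(divergence, value = c("percent",
                                                  "n_differences")) {
  value <- match.arg(value)
  sym <- dplyr::bind_rows(
    divergence,
    divergence |>
      dplyr::filter(.data$id_a != .data$id_b) |>
      dplyr::rename(id_a = "id_b", id_b = "id_a")
  )
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                    fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (value == "percent") sprintf("%.0f", .data$percent)
      else .data$n_differences
    ), colour = "white", size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal()
}

#' Per-residue score track plot with an optional threshold
#'
#' @param object A `score_track`.
#' @param threshold Optional horizontal threshold line.
#' @param ... Unused.
#' @return A ggplot of score against residue number.
#' @method autoplot score_track
#' @export
autoplot.score_track <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$resno, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = attr(object, "kind"),
                  title = attr(object, "id")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
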