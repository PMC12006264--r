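#' Classify per-residue model confidence from a plDDT track
#'
#' A residue is `confident` when its plDDT is at or above the threshold and
#' `low` otherwise. Low-confidence regions of AlphaFold models are generally
#' disordered or flexible and carry no reliable positional information, which
#' is why downstream structural classification gates on this state.
#'
#' @param track A `score_track` of kind `"plddt"`.
#' @param threshold Confidence threshold, default 70 (standard AlphaFold
#'   practice for "confident" backbone placement).
#' @return Tibble `resno`, `plddt`, `confidence_state`.
#' @export
classify_confidence <- function(track, threshold = 70) {
  stopifnot(attr(track, "kind") == "plddt")
  tibble::tibble(
    resno = track$resno,
    plddt = track$score,
    confidence_state = ifelse(track$score >= threshold, "confident", "low")
  )
}

#' Classify per-residue structural order from a disorder Z-score track
#'
#' A residue is `ordered` when its Z-score (e.g. from the ADOPT disorder
#' predictor, trained on NMR chemical shifts) is at or above the threshold,
#' `disordered` otherwise.
#'
#' @param track A `score_track` of kind `"adopt_z"`.
#' @param threshold Order threshold on the Z scale, default 3.
#' @return Tibble `resno`, `adopt_z`, `order_state`.
#' @export
classify_order <- function(track, threshold = 3) {
  stopifnot(attr(track, "kind") == "adopt_z")
  tibble::tibble(
    resno = track$resno,
    adopt_z = track$score,
    order_state = ifelse(track$score >= threshold, "ordered", "disordered")
  )
}

#' Combine confidence and order tracks into a per-residue order mask
#'
#' Builds the mask used by every stratified comparison. Under the default
#' policy the order state comes from the disorder-predictor track when it is
#' available and falls back to the plDDT confidence state otherwise
#' (confident residues are taken as ordered); the `"plddt_only"` policy
#' ignores the Z-track so the choice of classifier is explicit in the output.
#'
#' @param confidence Output of [classify_confidence()] (or `NULL`).
#' @param order Output of [classify_order()] (or `NULL`).
#' @param policy `"adopt_first"` (default) or `"plddt_only"`.
#' @return A tibble of class `order_mask`: `resno`, `plddt`, `adopt_z`,
#'   `confidence_state`, `order_state`, with the thresholds' provenance in
#'   the `policy` attribute.
#' @export
consensus_mask <- function(confidence = NULL, order = NULL,
                           policy = c("adopt_first", "plddt_only")) {
  policy <- match.arg(policy)
  if (is.null(confidence) && is.null(order)) {
    abort("at least one of confidence/order is required")
  }
  if (!is.null(confidence) && !is.null(order)) {
    if (!identical(confidence$resno, order$resno)) {
      abort(sprintf(
        "confidence (%d residues) and order (%d residues) tracks do not align",
        nrow(confidence), nrow(order)
      ))
    }
  }
  resno <- if (!is.null(confidence)) confidence$resno else order$resno
  out <- tibble::tibble(
    resno = resno,
    plddt = if (!is.null(confidence)) confidence$plddt else NA_real_,
    adopt_z = if (!is.null(order)) order$adopt_z else NA_real_,
    confidence_state = if (!is.null(confidence)) confidence$confidence_state
      else NA_character_
  )
  from_conf <- ifelse(out$confidence_state == "confident",
                      "ordered", "disordered")
  out$order_state <- if (policy == "adopt_first" && !is.null(order)) {
    order$order_state
  } else if (!is.null(confidence)) {
    from_conf
  } else {
    order$order_state
  }
  attr(out, "policy") <- policy
  class(out) <- c("order_mask", class(out))
  out
}

#' Write an order mask to TSV
#' @param mask An `order_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  readr::write_tsv(tibble::as_tibble(mask), path)
  invisible(path)
}
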