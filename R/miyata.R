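#' Amino-acid polarity and volume properties behind the Miyata distance
#'
#' The Miyata biochemical distance between two amino acids combines their
#' difference in side-chain polarity and in volume, each normalized by the
#' standard deviation of that property across the 20 canonical residues:
#' \deqn{d(a,b) = \sqrt{(\Delta p / \sigma_p)^2 + (\Delta v / \sigma_v)^2}.}
#' The property columns are Grantham's (1974) polarity and volume values, the
#' physicochemical scales from which Miyata's distance was constructed.
#'
#' @return A tibble with columns `aa`, `polarity`, `volume`.
#' @export
miyata_properties <- function() {
  tibble::tibble(
    aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    polarity = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                 4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    volume = c(31, 124, 56, 54, 55, 85, 83, 3, 96, 111,
               111, 119, 105, 132, 32.5, 32, 61, 170, 136, 84)
  )
}

#' The full 20 x 20 Miyata distance matrix
#'
#' @param properties Property tibble as from [miyata_properties()]; exposed so
#'   the table can be audited or swapped.
#' @return A symmetric, zero-diagonal 20 x 20 numeric matrix with dimnames the
#'   one-letter codes.
#' @export
miyata_matrix <- function(properties = miyata_properties()) {
  p <- properties$polarity / sd(properties$polarity)
  v <- properties$volume / sd(properties$volume)
  m <- sqrt(outer(p, p, "-")^2 + outer(v, v, "-")^2)
  dimnames(m) <- list(properties$aa, properties$aa)
  m
}

#' Miyata biochemical distance between two amino acids
#'
#' @param aa1,aa2 One-letter codes (vectorized, equal length or recyclable).
#' @return Numeric distances; `NA` for `X` or any non-canonical code (unknown
#'   residues are never silently scored as 0).
#' @export
#' @examples
#' miyata_distance("A", "A") # 0
#' miyata_distance("G", "W") # the table maximum
miyata_distance <- function(aa1, aa2) {
  m <- miyata_cache()
  out <- rep(NA_real_, max(length(aa1), length(aa2)))
  aa1 <- rep_len(toupper(aa1), length(out))
  aa2 <- rep_len(toupper(aa2), length(out))
  ok <- aa1 %in% rownames(m) & aa2 %in% rownames(m)
  out[ok] <- m[cbind(aa1[ok], aa2[ok])]
  out
}

#' Integer Miyata class of a raw distance
#'
#' Bins a raw Miyata distance into the integer classes 0 (most biochemically
#' similar) through `cap` (least similar): class = min(cap, round-half-up(d)).
#' The cap reconciles the published 0-4 class range with raw distances that
#' can exceed 4 for the most extreme pairs.
#'
#' @param raw Non-negative raw distances (`NA` propagates).
#' @param cap Maximum class, default 4.
#' @return Integer classes.
#' @export
miyata_class <- function(raw, cap = 4L) {
  if (any(raw < 0, na.rm = TRUE)) abort("Miyata distances must be >= 0")
  as.integer(pmin(cap, round_half_up(raw)))
}

# memoized matrix
miyata_env <- new.env(parent = emptyenv())
miyata_cache <- function() {
  if (is.null(miyata_env$m)) miyata_env$m <- miyata_matrix()
  miyata_env$m
}
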