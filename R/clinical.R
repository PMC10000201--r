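# Clinical contingency tables: reconstruction from printed percentages,
# an exact two-tailed Fisher test, and the xenograft tumor-volume formula.

#' Reconstruct integer counts from printed cohort percentages
#'
#' Clinical characteristics tables often print each stratum cell as a
#' percentage of the whole cohort. This inverts that: each count is the
#' percentage times the cohort size, rounded half-away-from-zero to the
#' nearest integer. When the expected row total is known (printed alongside
#' the percentages), the reconstruction is checked against it and a
#' discrepancy is an error.
#'
#' @param total cohort size (positive integer).
#' @param percentages numeric vector of cell percentages (>= 0).
#' @param expected_total optional known sum of the reconstructed counts.
#' @return Integer vector of counts, same length as `percentages`.
#' @examples
#' counts_from_percent(102, c(37.25, 8.83))  # 38 9
#' @export
counts_from_percent <- function(total, percentages, expected_total = NULL) {
  stopifnot(total > 0, all(percentages >= 0))
  counts <- as.integer(round_half_up(total * percentages / 100))
  if (!is.null(expected_total) && sum(counts) != expected_total) {
    stop(sprintf("reconstructed counts sum to %d, expected %d (percentages: %s)",
                 sum(counts), expected_total,
                 paste(percentages, collapse = ", ")))
  }
  counts
}

#' Exact two-tailed Fisher test for a 2x2 contingency table
#'
#' Computes the two-tailed p-value by exact enumeration: with all margins
#' fixed, every feasible table is generated, and the p-value is the sum of
#' the point probabilities (hypergeometric masses) of all tables whose
#' probability does not exceed that of the observed table. This
#' point-probability criterion is the dominant two-tail convention. A small
#' relative tolerance guards the comparison against floating-point noise in
#' equal-probability ties.
#'
#' @param t 2x2 matrix (or 4-vector `a, b, c, d` filled by row) of
#'   non-negative integer cells; all four margins must be positive.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_exact_two_tail(matrix(c(38, 9, 38, 17), 2, byrow = TRUE))
#' @export
fisher_exact_two_tail <- function(t) {
  if (is.vector(t) && length(t) == 4L) t <- matrix(t, 2L, byrow = TRUE)
  stopifnot(is.matrix(t), all(dim(t) == 2L))
  if (any(t < 0) || any(t != round(t))) {
    stop("cells must be non-negative integers")
  }
  r1 <- sum(t[1L, ]); r2 <- sum(t[2L, ])
  c1 <- sum(t[, 1L]); c2 <- sum(t[, 2L])
  if (min(r1, r2, c1, c2) == 0) stop("degenerate table: a margin is zero")
  # cell (1,1) ranges over all tables with these margins
  x <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(t[1L, 1L], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Xenograft tumor volume from caliper measurements
#'
#' The standard caliper estimate
#' `volume (cm^3) = 0.5 * length (cm) * width^2 (cm^2)`, where length is the
#' larger of the two measured dimensions. Width exceeding length violates
#' the caliper convention and is an error.
#'
#' @param length tumor length in cm (vectorized).
#' @param width tumor width in cm, `0 < width <= length`.
#' @return Volume in cubic centimeters.
#' @examples
#' tumor_volume(2, 1)  # 1 cm^3
#' @export
tumor_volume <- function(length, width) {
  if (any(width <= 0) || any(length <= 0)) {
    stop("length and width must be positive")
  }
  if (any(width > length)) {
    stop("width exceeds length: caliper convention requires length >= width")
  }
  0.5 * length * width^2
}
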