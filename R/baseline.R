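#' Moving minimum
#'
#' Centered moving minimum with window `k` samples (edges use the available
#' part of the window), the drift estimator used by baseline correction.
#'
#' @param x Numeric vector.
#' @param k Window width in samples (coerced to >= 1 integer).
#' @return Numeric vector, same length as `x`.
#' @export
moving_min <- function(x, k) {
  k <- max(1L, as.integer(round(k)))
  n <- length(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  vapply(seq_len(n), function(i) {
    min(x[max(1L, i - half_lo):min(n, i + half_hi)])
  }, 1.0)
}

#' Baseline-drift correction
#'
#' Removes slow baseline wander from a beat-periodic waveform:
#' 1. detect peaks and take the median inter-peak distance `d`;
#' 2. estimate the baseline as the moving minimum with window `d`;
#' 3. fit a polynomial of order `min(round(d), order_cap)` to that estimate
#'    (orthogonal-polynomial basis on a centered abscissa for stability);
#' 4. if fewer than two peaks are found, fall back to fitting the signal
#'    itself with `fallback_order`;
#' 5. subtract the fit, shift so the minimum is exactly 0, and rescale so
#'    the output range equals the input range.
#'
#' A raw beat-spacing polynomial order (~90 for cardiac beats at 125 Hz) is
#' numerically unusable, hence the `order_cap`.
#'
#' @param x Numeric vector, length >= 8.
#' @param fallback_order Polynomial order of the no-peaks fallback branch.
#' @param order_cap Upper bound on the peak-driven polynomial order.
#' @param min_prominence Peak prominence floor passed to [detect_peaks()],
#'   as a fraction of the input range.
#' @return Corrected vector with attributes `branch` (`"peak-driven"` or
#'   `"fallback"`), `poly_order`, and `degenerate` (`TRUE` for a constant
#'   input, which is returned unchanged instead of dividing by zero).
#' @export
correct_baseline <- function(x, fallback_order = 6, order_cap = 8,
                             min_prominence = 0) {
  n <- length(x)
  if (n < 8) abort("correct_baseline needs at least 8 samples")
  x_amp <- max(x) - min(x)
  if (x_amp == 0) {
    attr(x, "degenerate") <- TRUE
    return(x)
  }
  tt <- seq_len(n)
  peaks <- detect_peaks(x, min_prominence * x_amp)
  if (nrow(peaks) >= 2) {
    d <- median(diff(peaks$index))
    baseline <- moving_min(x, d)
    ord <- min(round(d), order_cap)
    branch <- "peak-driven"
  } else {
    baseline <- x
    ord <- fallback_order
    branch <- "fallback"
  }
  ord <- max(1L, min(as.integer(ord), n - 1L))
  fit <- stats::fitted(lm(baseline ~ poly(tt, ord)))
  y <- x - fit
  y <- y - min(y)
  y_amp <- max(y)
  if (y_amp == 0) { # fit reproduced the signal exactly
    y <- x - min(x)
    y_amp <- max(y)
  }
  y <- y * (x_amp / y_amp)
  structure(y, branch = branch, poly_order = ord, degenerate = FALSE)
}

#' Drift-removing baseline correction that preserves absolute level
#'
#' For pressure traces the absolute mmHg level carries the label
#' information, so the full correction (which pins the minimum to 0) is not
#' appropriate. This variant estimates the same moving-minimum polynomial
#' baseline and subtracts only its zero-mean component, removing wander
#' while keeping the mean pressure level.
#'
#' @inheritParams correct_baseline
#' @return Corrected vector (attributes as in [correct_baseline()]).
#' @export
correct_baseline_anchor <- function(x, fallback_order = 6, order_cap = 8,
                                    min_prominence = 0) {
  n <- length(x)
  if (n < 8) abort("correct_baseline_anchor needs at least 8 samples")
  x_amp <- max(x) - min(x)
  if (x_amp == 0) {
    attr(x, "degenerate") <- TRUE
    return(x)
  }
  tt <- seq_len(n)
  peaks <- detect_peaks(x, min_prominence * x_amp)
  if (nrow(peaks) >= 2) {
    d <- median(diff(peaks$index))
    baseline <- moving_min(x, d)
    ord <- min(round(d), order_cap)
    branch <- "peak-driven"
  } else {
    baseline <- x
    ord <- fallback_order
    branch <- "fallback"
  }
  ord <- max(1L, min(as.integer(ord), n - 1L))
  fit <- stats::fitted(lm(baseline ~ poly(tt, ord)))
  y <- x - (fit - mean(fit))
  structure(y, branch = branch, poly_order = ord, degenerate = FALSE)
}
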