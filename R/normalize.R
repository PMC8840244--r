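#' Per-segment unit-range normalization
#'
#' Z-score the segment, then map affinely onto `[0, 1]`. Because the range
#' map is affine-invariant the result equals `(x - min) / (max - min)`; the
#' explicit two-step form mirrors how predictor channels are conditioned.
#'
#' @param x Non-constant numeric vector.
#' @return Vector with `min = 0`, `max = 1`.
#' @export
normalize_unit_range <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot unit-range normalize a constant segment")
  }
  z <- (x - mean(x)) / s
  (z - min(z)) / (max(z) - min(z))
}

#' Global normalization context for pressure waveforms
#'
#' Pressure targets are scaled by a single global divisor (the maximum
#' systolic pressure over the training partition) so segments keep their
#' relative amplitudes — the amplitude *is* the blood-pressure information.
#'
#' @param global_sbp_max Positive scalar divisor in mmHg.
#' @return A `bp_norm_ctx` list.
#' @export
norm_context <- function(global_sbp_max) {
  if (!is.numeric(global_sbp_max) || global_sbp_max <= 0) {
    abort("global_sbp_max must be positive")
  }
  structure(list(global_sbp_max = as.numeric(global_sbp_max)),
            class = "bp_norm_ctx")
}

#' Globally normalize a pressure waveform
#' @param x Numeric vector in mmHg.
#' @param ctx A [norm_context()].
#' @return `x / ctx$global_sbp_max` (dimensionless, amplitude preserved
#'   across segments).
#' @export
normalize_abp <- function(x, ctx) {
  stopifnot(inherits(ctx, "bp_norm_ctx"))
  x / ctx$global_sbp_max
}

#' Invert [normalize_abp()]
#' @inheritParams normalize_abp
#' @export
denormalize_abp_ctx <- function(x, ctx) {
  stopifnot(inherits(ctx, "bp_norm_ctx"))
  x * ctx$global_sbp_max
}
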