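#' Band-pass filter specification
#'
#' Linear-phase FIR band-pass used when deriving velocity/acceleration PPG.
#' Cutoffs bracket the cardiac band: the stop/pass edges kill sub-cardiac
#' drift below and differentiation noise above while passing the pulse
#' fundamentals and their first harmonics. With an odd tap count the group
#' delay is exactly `(order - 1) / 2` samples, which makes delay
#' compensation an integer shift.
#'
#' @param fs Sampling rate (Hz).
#' @param stop_lo,pass_lo,pass_hi,stop_hi Band edges in Hz,
#'   `0 < stop_lo < pass_lo < pass_hi < stop_hi < fs/2`.
#' @param order Number of taps (odd).
#' @return A `bandpass_spec` list with the designed coefficients and
#'   `group_delay`.
#' @export
bandpass_spec <- function(fs = 125, stop_lo = 0.25, pass_lo = 0.5,
                          pass_hi = 10, stop_hi = 15, order = 51) {
  if (!(0 < stop_lo && stop_lo < pass_lo && pass_lo < pass_hi &&
        pass_hi < stop_hi && stop_hi < fs / 2)) {
    abort("band edges must satisfy 0 < stop_lo < pass_lo < pass_hi < stop_hi < fs/2")
  }
  if (order %% 2 == 0) abort("order (tap count) must be odd")
  b <- signal::fir1(order - 1, c(pass_lo, pass_hi) / (fs / 2), type = "pass")
  structure(list(design = "FIR-window", fs = fs, stop_lo = stop_lo,
                 pass_lo = pass_lo, pass_hi = pass_hi, stop_hi = stop_hi,
                 order = as.integer(order), coef = as.numeric(b),
                 group_delay = (order - 1L) %/% 2L),
            class = "bandpass_spec")
}

# causal linear-phase FIR with reflection-padded warm-up
causal_fir <- function(x, b) {
  k <- length(b)
  if (k == 1) return(x * b)
  pad <- 2 * x[1] - x[seq(k, 2)] # reflect around the first sample
  y <- stats::filter(c(pad, x), b, method = "convolution", sides = 1)
  as.numeric(y[(k):(k - 1 + length(x))])
}

#' Derive velocity and acceleration PPG channels
#'
#' From a margin-extended PPG segment, computes the first and second
#' derivative channels: first difference (per-sample `dt`), band-pass
#' filtering to suppress differentiation noise, unit-range normalization,
#' then an integer shift by the filter's group delay (once for VPG, twice
#' for APG) so the three outputs are mutually time-aligned and exactly
#' `out_len` samples long.
#'
#' @param ppg Numeric vector of at least `out_len + 2 * group_delay`
#'   samples; a bare `out_len`-sample segment is accepted when
#'   `margin = "reflect"`, which reflection-pads the tail before filtering.
#' @param spec A [bandpass_spec()].
#' @param out_len Target aligned length (samples).
#' @param margin `"strict"` (require the margin) or `"reflect"`.
#' @return List with `ppg`, `vpg`, `apg` (each `out_len` samples, unit
#'   range) and `degenerate` flag (constant input gives all-zero
#'   derivatives).
#' @export
compute_derivatives <- function(ppg, spec = bandpass_spec(), out_len = 1024,
                                margin = c("strict", "reflect")) {
  margin <- match.arg(margin)
  d <- spec$group_delay
  need <- out_len + 2L * d
  if (length(ppg) < need) {
    if (margin == "reflect" && length(ppg) >= out_len) {
      n <- length(ppg)
      ext <- 2 * ppg[n] - ppg[seq(n - 1, n - (need - n))]
      ppg <- c(ppg, ext)
    } else {
      abort(sprintf(
        "compute_derivatives needs %d samples (out_len + 2*group_delay); got %d",
        need, length(ppg)))
    }
  }
  if (sd(ppg) == 0) {
    z <- rep(0, out_len)
    return(list(ppg = z, vpg = z, apg = z, degenerate = TRUE))
  }
  dt <- 1 # sample-index abscissa
  ppg_n <- normalize_unit_range(ppg)
  v <- diff(ppg_n) / dt
  v <- c(v[1], v) # keep length; edge sample inside the trimmed margin
  vf <- causal_fir(v, spec$coef)
  vpg_full <- if (sd(vf) == 0) rep(0, length(vf)) else normalize_unit_range(vf)
  a <- diff(vpg_full) / dt
  a <- c(a[1], a)
  af <- causal_fir(a, spec$coef)
  apg_full <- if (sd(af) == 0) rep(0, length(af)) else normalize_unit_range(af)
  list(ppg = ppg_n[seq_len(out_len)],
       vpg = vpg_full[(d + 1):(d + out_len)],
       apg = apg_full[(2 * d + 1):(2 * d + out_len)],
       degenerate = FALSE)
}
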