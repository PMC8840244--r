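#' Extract per-segment blood-pressure labels from an ABP waveform
#'
#' Reduces a pressure trace in mmHg to scalar SBP/DBP/MAP labels.
#' `"peak-mean"` (default): SBP is the mean height of the systolic peaks
#' (prominence-gated to skip dicrotic notches) and DBP the mean of the
#' troughs between successive beats. `"extrema"`: SBP/DBP are the segment
#' maximum/minimum. Either way `MAP = DBP + (SBP - DBP) / 3`.
#'
#' Peak amplitudes measured on a noisy trace are biased upward (and trough
#' amplitudes downward) because extrema ride the noise excursions, so the
#' trace is lightly smoothed with a Savitzky-Golay filter before
#' delineation; the polynomial fit preserves systolic peak amplitude while
#' suppressing the sample-level noise that inflates it.
#'
#' @param abp Numeric vector in mmHg (not normalized).
#' @param method `"peak-mean"` or `"extrema"`.
#' @param min_prominence Beat-peak prominence floor as a fraction of the
#'   segment range (suppresses dicrotic double counting).
#' @param smooth_window Savitzky-Golay window length in samples (odd; 1
#'   disables smoothing).
#' @return Tibble with columns `sbp`, `dbp`, `map` (one row), or an error
#'   for a flat segment with no detectable beats.
#' @export
extract_bp_labels <- function(abp, method = c("peak-mean", "extrema"),
                              min_prominence = 0.25, smooth_window = 9) {
  method <- match.arg(method)
  rng <- max(abp) - min(abp)
  if (rng == 0) abort("flat ABP segment: no labels (route to rejection)")
  if (smooth_window > 1 && length(abp) > smooth_window) {
    abp <- signal::sgolayfilt(abp, p = 3, n = smooth_window)
    rng <- max(abp) - min(abp)
    if (rng == 0) abort("flat ABP segment: no labels (route to rejection)")
  }
  if (method == "extrema") {
    sbp <- max(abp); dbp <- min(abp)
  } else {
    peaks <- detect_peaks(abp, min_prominence * rng)
    if (nrow(peaks) < 1) abort("no systolic peaks detected (route to rejection)")
    sbp <- mean(peaks$height)
    # the diastolic level is a plateau: averaging the bottom decile of each
    # inter-beat interval estimates it without the downward bias that the
    # minimum order statistic picks up from noise
    trough_level <- function(seg) {
      mean(seg[seg <= stats::quantile(seg, 0.10)])
    }
    if (nrow(peaks) >= 2) {
      troughs <- vapply(seq_len(nrow(peaks) - 1), function(i) {
        trough_level(abp[peaks$index[i]:peaks$index[i + 1]])
      }, 1.0)
    } else {
      troughs <- trough_level(abp)
    }
    dbp <- mean(troughs)
  }
  tibble::tibble(sbp = sbp, dbp = dbp, map = dbp + (sbp - dbp) / 3)
}
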