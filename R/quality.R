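#' Quality-screening thresholds
#'
#' Acceptance windows for per-segment labels and peak-statistic bounds used
#' by [assess_quality()]. Label windows are inclusive and follow the
#' published cleaning rules: SBP in \[80, 190\], DBP in \[50, 120\], pulse
#' pressure in \[20, 120\] mmHg. The peak-uniformity bounds (never printed
#' in the source study, which tuned them by eye) default to: peak-height
#' standard deviation <= 0.10 on the unit-range-normalized signal,
#' peak-interval standard deviation <= 0.12 after dividing intervals by
#' their median, and 4-25 beats per segment (about 30-180 bpm over 8.192
#' s). The defaults are calibrated so the synthetic generator's clean and
#' distorted records separate cleanly.
#'
#' @param sbp_min,sbp_max,dbp_min,dbp_max,pp_min,pp_max Label windows, mmHg.
#' @param max_peak_height_std Max std of peak heights (unit-range scale).
#' @param max_peak_interval_std Max std of median-normalized intervals.
#' @param peak_count_min,peak_count_max Allowed beat-peak count.
#' @param min_prominence Peak prominence floor (fraction of unit range).
#' @return A `quality_thresholds` list.
#' @export
quality_thresholds <- function(sbp_min = 80, sbp_max = 190,
                               dbp_min = 50, dbp_max = 120,
                               pp_min = 20, pp_max = 120,
                               max_peak_height_std = 0.10,
                               max_peak_interval_std = 0.12,
                               peak_count_min = 4, peak_count_max = 25,
                               min_prominence = 0.1) {
  stopifnot(sbp_min < sbp_max, dbp_min < dbp_max, pp_min < pp_max,
            max_peak_height_std > 0, max_peak_interval_std > 0)
  structure(as.list(environment()), class = "quality_thresholds")
}

peak_stats <- function(x, min_prominence) {
  rng <- max(x) - min(x)
  if (rng == 0) {
    return(list(blank = TRUE, n = 0L, height_std = NA_real_,
                interval_std = NA_real_))
  }
  xn <- (x - min(x)) / rng
  pk <- detect_peaks(xn, min_prominence)
  iv <- peak_intervals(pk)
  list(blank = FALSE, n = nrow(pk),
       height_std = if (nrow(pk) >= 2) sd(pk$height) else 0,
       interval_std = if (length(iv) >= 2) sd(iv / median(iv)) else 0)
}

#' Screen one segment for signal quality
#'
#' Applies, in order: blank-channel check, label-range rules (SBP, DBP,
#' pulse pressure), then peak-uniformity statistics on the unit-range
#' normalized PPG and ABP (height std, interval std, beat count). The
#' decision reports the *first* failed rule.
#'
#' @param ppg,abp Raw sample vectors of the segment.
#' @param labels One-row label tibble from [extract_bp_labels()], or `NULL`
#'   if label extraction failed (treated as a rejection).
#' @param thr A [quality_thresholds()].
#' @return Tibble with `accept` (logical) and `reason` (`NA` when
#'   accepted; otherwise the failed rule name).
#' @export
assess_quality <- function(ppg, abp, labels, thr = quality_thresholds()) {
  fail <- function(reason) tibble::tibble(accept = FALSE, reason = reason)
  sp <- peak_stats(ppg, thr$min_prominence)
  sa <- peak_stats(abp, thr$min_prominence)
  if (sp$blank || sa$blank) return(fail("blank"))
  if (is.null(labels)) return(fail("label_failure"))
  if (labels$sbp < thr$sbp_min || labels$sbp > thr$sbp_max) return(fail("sbp_range"))
  if (labels$dbp < thr$dbp_min || labels$dbp > thr$dbp_max) return(fail("dbp_range"))
  pp <- labels$sbp - labels$dbp
  if (pp < thr$pp_min || pp > thr$pp_max) return(fail("pulse_pressure"))
  if (sp$height_std > thr$max_peak_height_std) return(fail("ppg_peak_height_std"))
  if (sa$height_std > thr$max_peak_height_std) return(fail("abp_peak_height_std"))
  if (sp$interval_std > thr$max_peak_interval_std) return(fail("ppg_peak_interval_std"))
  if (sa$interval_std > thr$max_peak_interval_std) return(fail("abp_peak_interval_std"))
  if (sp$n < thr$peak_count_min || sp$n > thr$peak_count_max) return(fail("ppg_peak_count"))
  if (sa$n < thr$peak_count_min || sa$n > thr$peak_count_max) return(fail("abp_peak_count"))
  tibble::tibble(accept = TRUE, reason = NA_character_)
}
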