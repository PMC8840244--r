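mk_lab <- function(sbp, dbp) tibble::tibble(sbp = sbp, dbp = dbp,
                                            map = dbp + (sbp - dbp) / 3)

test_that("label-range rules reject out-of-window and wide-pulse-pressure segments", {
  g <- clean_cohort(40)
  ppg <- g$segments$ppg[[1]]; abp <- g$segments$abp[[1]]
  expect_equal(assess_quality(ppg, abp, mk_lab(75, 60))$reason, "sbp_range")
  expect_equal(assess_quality(ppg, abp, mk_lab(185, 55))$reason,
               "pulse_pressure") # PP = 130 > 120
  expect_equal(assess_quality(ppg, abp, mk_lab(120, 45))$reason, "dbp_range")
  # label windows are inclusive at both edges (PP = 70 and 30, both inside)
  expect_true(assess_quality(ppg, abp, mk_lab(190, 120))$accept)
  expect_true(assess_quality(ppg, abp, mk_lab(80, 50))$accept)
})

test_that("blank channels and failed labels are rejected with named reasons", {
  g <- clean_cohort(40)
  abp <- g$segments$abp[[1]]
  expect_equal(assess_quality(rep(0, 1074), abp, mk_lab(120, 70))$reason,
               "blank")
  expect_equal(assess_quality(g$segments$ppg[[1]], abp, NULL)$reason,
               "label_failure")
})

test_that("clean generator records pass the default screen", {
  g <- clean_cohort(40)
  acc <- vapply(seq_len(nrow(g$segments)), function(i) {
    lab <- extract_bp_labels(g$segments$abp[[i]])
    assess_quality(g$segments$ppg[[i]], g$segments$abp[[i]], lab)$accept
  }, TRUE)
  expect_gte(mean(acc), 0.9)
})

test_that("injected distortions trip the peak-statistic rules", {
  g <- clean_cohort(40)
  s <- g$segments
  lab1 <- extract_bp_labels(s$abp[[1]])
  # double peaks roughly double the count and break interval uniformity
  d1 <- inject_distortion(s, s$segment_id[1], "double-peak",
                          beat_starts = g$truth$beat_starts[[1]])
  q1 <- assess_quality(d1$ppg[[1]], d1$abp[[1]],
                       extract_bp_labels(d1$abp[[1]]))
  expect_false(q1$accept)
  n_clean <- nrow(detect_peaks(normalize_unit_range(s$ppg[[1]]), 0.1))
  n_dbl <- nrow(detect_peaks(normalize_unit_range(d1$ppg[[1]]), 0.1))
  expect_gte(n_dbl, 1.7 * n_clean)
  # irregular beat heights push the height std over threshold
  d2 <- inject_distortion(s, s$segment_id[2], "irregular-height",
                          beat_starts = g$truth$beat_starts[[2]])
  q2 <- assess_quality(d2$ppg[[2]], d2$abp[[2]],
                       extract_bp_labels(d2$abp[[2]]))
  expect_false(q2$accept)
  # blanking rejects with the blank rule
  d3 <- inject_distortion(s, s$segment_id[3], "blank")
  q3 <- assess_quality(d3$ppg[[3]], d3$abp[[3]], lab1)
  expect_equal(q3$reason, "blank")
  expect_error(inject_distortion(s, s$segment_id[1], "melt"))
})

test_that("enlarging every acceptance window never converts accept into reject", {
  g <- clean_cohort(40)
  thr <- quality_thresholds()
  wide <- quality_thresholds(sbp_min = 0, sbp_max = 1e6, dbp_min = 0,
                             dbp_max = 1e6, pp_min = 0, pp_max = 1e6,
                             max_peak_height_std = 1e6,
                             max_peak_interval_std = 1e6,
                             peak_count_min = 0, peak_count_max = 1e6)
  for (i in seq_len(nrow(g$segments))) {
    lab <- extract_bp_labels(g$segments$abp[[i]])
    a1 <- assess_quality(g$segments$ppg[[i]], g$segments$abp[[i]], lab, thr)
    a2 <- assess_quality(g$segments$ppg[[i]], g$segments$abp[[i]], lab, wide)
    if (a1$accept) expect_true(a2$accept)
  }
  # vacuous thresholds accept everything with computable labels
  expect_true(assess_quality(g$segments$ppg[[5]], g$segments$abp[[5]],
                             mk_lab(300, 10), wide)$accept)
})
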