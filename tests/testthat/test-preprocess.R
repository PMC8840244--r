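prep_cohort <- function() {
  if (is.null(.fixture_env$prep)) {
    g <- generate_segments(synth_config(n_records = 60, seed = 2024,
                                        distortion_fraction = 0.2))
    .fixture_env$prep <- list(g = g, out = preprocess_segments(g$segments))
  }
  .fixture_env$prep
}

test_that("the front end keeps clean records and rejects most distorted ones", {
  p <- prep_cohort()
  g <- p$g; out <- p$out
  rejected <- out$rejections$segment_id
  dist_ids <- g$truth$segment_id[g$truth$distorted]
  clean_ids <- g$truth$segment_id[!g$truth$distorted]
  expect_gte(mean(dist_ids %in% rejected), 0.75)
  expect_lte(mean(clean_ids %in% rejected), 0.10)
  expect_equal(out$report$n_in, 60)
  expect_equal(out$report$n_out + nrow(out$rejections), 60)
})

test_that("preprocessed channels are aligned, unit-length and normalized", {
  out <- prep_cohort()$out
  s <- out$segments
  for (ch in c("ppg", "vpg", "apg", "ecg", "abp")) {
    expect_true(all(lengths(s[[ch]]) == 1024))
  }
  # predictor channels are unit-range normalized before the alignment trim,
  # so trimmed values stay inside [0, 1] and still sweep most of it
  for (ch in c("ppg", "vpg", "apg", "ecg")) {
    vals <- unlist(s[[ch]])
    expect_gte(min(vals), 0)
    expect_lte(max(vals), 1)
  }
  expect_gt(max(s$ppg[[1]]) - min(s$ppg[[1]]), 0.9)
  # normalized pressure lies in (0, 1] with the training max at exactly 1
  abp_max <- max(vapply(s$abp, max, 1.0))
  expect_equal(abp_max, 1)
  expect_true(all(vapply(s$abp, min, 1.0) > 0))
  # history records every stage once
  expect_equal(segment_metadata(s)$history,
               c("baseline_corrected", "labels_extracted", "quality_screened",
                 "derivatives_added", "normalized"))
})

test_that("labels survive preprocessing in mmHg and match the generator truth", {
  p <- prep_cohort()
  lab <- p$out$labels
  truth <- p$g$truth[match(lab$segment_id, p$g$truth$segment_id), ]
  expect_lt(median(abs(lab$sbp - truth$sbp)), 2)
  expect_lt(median(abs(lab$dbp - truth$dbp)), 2)
})

test_that("preprocessing is deterministic and honours a frozen context", {
  p <- prep_cohort()
  again <- preprocess_segments(p$g$segments)
  expect_identical(again$segments$ppg, p$out$segments$ppg)
  expect_identical(again$labels, p$out$labels)
  # frozen context rescales pressure accordingly
  ctx <- norm_context(2 * p$out$ctx$global_sbp_max)
  half <- preprocess_segments(p$g$segments, ctx = ctx)
  expect_equal(max(vapply(half$segments$abp, max, 1.0)), 0.5,
               tolerance = 1e-9)
})

test_that("the training partition alone sets the global pressure divisor", {
  p <- prep_cohort()
  lab <- p$out$labels
  # exclude the segment carrying the global waveform maximum from training
  s0 <- p$out$segments
  top <- s0$segment_id[which.max(vapply(s0$abp, max, 1.0))]
  train_ids <- setdiff(lab$segment_id, top)
  out2 <- preprocess_segments(p$g$segments, train_ids = train_ids)
  expect_lt(out2$ctx$global_sbp_max, p$out$ctx$global_sbp_max)
  i_top <- match(top, out2$segments$segment_id)
  expect_gt(max(out2$segments$abp[[i_top]]), 1) # test-only segment may exceed 1
})

test_that("an input store with no survivors fails with the report attached", {
  g <- generate_segments(synth_config(n_records = 5, seed = 8))
  s <- g$segments
  for (id in s$segment_id) s <- inject_distortion(s, id, "blank")
  expect_error(preprocess_segments(s), "no segments survived")
})

test_that("a missing pressure channel aborts preprocessing", {
  g <- clean_cohort(10)
  s <- g$segments
  s$abp <- vector("list", nrow(s))
  expect_error(preprocess_segments(s), "abp")
})
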