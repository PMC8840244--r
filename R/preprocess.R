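#' Preprocess a raw segment store
#'
#' Runs the full signal-conditioning front end over a segment table, in
#' order: baseline correction per channel, per-segment label extraction
#' from the mmHg pressure trace, quality rejection, derivative-channel
#' computation (VPG/APG), and normalization (unit-range for predictor
#' channels, global systolic-maximum division for the pressure target).
#'
#' Baseline correction applies the full moving-minimum/polynomial scheme to
#' PPG and ECG; for ABP the default `abp_baseline = "anchor"` removes only
#' the zero-mean drift component so the absolute mmHg level (the label
#' information) survives. `"full"` applies the verbatim scheme, `"none"`
#' skips it.
#'
#' The global pressure divisor is the maximum of the trimmed ABP waveforms
#' over the *training* records only (pass `train_ids`), so no test-set
#' information leaks into normalization; omit `train_ids` for the
#' whole-store ("strict") variant, or pass a frozen `ctx` from an earlier
#' run.
#'
#' @param segments Raw `segment_tbl` with at least `ppg` and `abp`.
#' @param thr [quality_thresholds()].
#' @param spec [bandpass_spec()] for derivative filtering.
#' @param label_method Passed to [extract_bp_labels()].
#' @param abp_baseline `"anchor"`, `"full"` or `"none"`.
#' @param out_len Aligned output length (samples).
#' @param margin `"strict"` (input must carry `2 * group_delay` extra
#'   samples) or `"reflect"` (edge-pad exact-length inputs).
#' @param train_ids Segment ids making up the training partition for the
#'   global divisor; `NULL` uses every accepted segment.
#' @param ctx Optional frozen [norm_context()] (overrides `train_ids`).
#' @return A `bp_preprocess` list: `segments` (clean, normalized, aligned),
#'   `labels` (per-segment mmHg scalars), `ctx`, `rejections` (one row per
#'   rejected segment with the first failed rule), and `report` (per-rule
#'   counts and fraction removed).
#' @export
preprocess_segments <- function(segments, thr = quality_thresholds(),
                                spec = bandpass_spec(),
                                label_method = "peak-mean",
                                abp_baseline = c("anchor", "full", "none"),
                                out_len = 1024,
                                margin = c("strict", "reflect"),
                                train_ids = NULL, ctx = NULL) {
  abp_baseline <- match.arg(abp_baseline)
  margin <- match.arg(margin)
  validate_segments(segments, require = c("ppg", "abp"))
  n <- nrow(segments)
  if (n == 0) abort("empty input store")

  has_ecg <- "ecg" %in% names(segments) &&
    !all(vapply(segments$ecg, is.null, TRUE))

  keep <- logical(n)
  reasons <- character(n)
  ppg_out <- vpg_out <- apg_out <- ecg_out <- abp_out <- vector("list", n)
  labs <- vector("list", n)

  for (i in seq_len(n)) {
    ppg <- segments$ppg[[i]]
    abp <- segments$abp[[i]]
    ppg_c <- tryCatch(correct_baseline(ppg), error = function(e) ppg)
    abp_c <- switch(abp_baseline,
                    none = abp,
                    anchor = tryCatch(correct_baseline_anchor(abp),
                                      error = function(e) abp),
                    full = tryCatch(correct_baseline(abp),
                                    error = function(e) abp))
    lab <- tryCatch(extract_bp_labels(abp_c, method = label_method),
                    error = function(e) NULL)
    q <- assess_quality(ppg_c, abp_c, lab, thr)
    if (!q$accept) {
      reasons[i] <- q$reason
      next
    }
    der <- tryCatch(compute_derivatives(ppg_c, spec, out_len, margin),
                    error = function(e) NULL)
    if (is.null(der)) {
      reasons[i] <- "derivative_failure"
      next
    }
    if (der$degenerate) {
      reasons[i] <- "blank"
      next
    }
    keep[i] <- TRUE
    labs[[i]] <- lab
    ppg_out[[i]] <- der$ppg
    vpg_out[[i]] <- der$vpg
    apg_out[[i]] <- der$apg
    abp_out[[i]] <- abp_c[seq_len(out_len)]
    if (has_ecg && !is.null(segments$ecg[[i]])) {
      e <- tryCatch(correct_baseline(segments$ecg[[i]]),
                    error = function(e) segments$ecg[[i]])
      e <- e[seq_len(out_len)]
      ecg_out[[i]] <- if (sd(e) > 0) normalize_unit_range(e) else rep(0, out_len)
    }
  }

  if (!any(keep)) {
    rej <- tibble::tibble(segment_id = segments$segment_id,
                          reason = reasons)
    abort(paste0("no segments survived preprocessing; rejections: ",
                 paste(utils::capture.output(print(table(reasons))),
                       collapse = " ")))
  }

  ids <- which(keep)
  labels <- dplyr::bind_rows(labs[ids])
  labels <- dplyr::bind_cols(
    tibble::tibble(segment_id = segments$segment_id[ids],
                   subject_id = segments$subject_id[ids]),
    labels)

  if (is.null(ctx)) {
    ctx_ids <- if (is.null(train_ids)) {
      seq_along(ids)
    } else {
      which(segments$segment_id[ids] %in% train_ids)
    }
    if (!length(ctx_ids)) abort("no accepted training segments for the global divisor")
    ctx <- norm_context(max(vapply(abp_out[ids[ctx_ids]], max, 1.0)))
  }

  clean <- segment_tbl(
    segment_id = segments$segment_id[ids],
    subject_id = segments$subject_id[ids],
    fs = segments$fs[ids],
    ppg = ppg_out[ids],
    abp = lapply(abp_out[ids], normalize_abp, ctx = ctx),
    ecg = if (has_ecg) ecg_out[ids] else NULL,
    vpg = vpg_out[ids],
    apg = apg_out[ids],
    metadata = segment_metadata(segments))
  for (flag in c("baseline_corrected", "labels_extracted",
                 "quality_screened", "derivatives_added", "normalized")) {
    clean <- add_history(clean, flag)
  }

  rejections <- tibble::tibble(segment_id = segments$segment_id[!keep],
                               reason = reasons[!keep])
  report <- rejections |>
    dplyr::count(.data$reason, name = "n_rejected") |>
    dplyr::arrange(dplyr::desc(.data$n_rejected))
  structure(list(segments = clean, labels = labels, ctx = ctx,
                 rejections = rejections,
                 report = list(per_rule = report,
                               n_in = n, n_out = length(ids),
                               fraction_removed = 1 - length(ids) / n)),
            class = "bp_preprocess")
}

#' @export
print.bp_preprocess <- function(x, ...) {
  cat(sprintf("<bp_preprocess> %d/%d segments kept (%.1f%% removed), global SBP max %.2f mmHg\n",
              x$report$n_out, x$report$n_in,
              100 * x$report$fraction_removed, x$ctx$global_sbp_max))
  if (nrow(x$report$per_rule)) print(x$report$per_rule)
  invisible(x)
}
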