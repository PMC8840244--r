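#' Mean absolute error
#' @param y_true,y_pred Aligned numeric vectors (mmHg).
#' @return Scalar MAE in mmHg.
#' @export
mae <- function(y_true, y_pred) {
  check_error_vector(y_true, y_pred)
  mean(abs(y_pred - y_true))
}

check_error_vector <- function(y_true, y_pred) {
  if (!length(y_true)) abort("empty error vector")
  if (length(y_true) != length(y_pred)) abort("y_true/y_pred length mismatch")
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    abort("non-finite values in error vector")
  }
  invisible(TRUE)
}

# cumulative-percentage thresholds of the BHS protocol (percent of absolute
# errors <= 5 / 10 / 15 mmHg required for each grade; all three must hold)
BHS_TABLE <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' British Hypertension Society grading
#'
#' Cumulative percentages of absolute errors at or below 5, 10 and 15 mmHg
#' (inclusive), graded A/B/C against the protocol table; a device must meet
#' all three thresholds of a grade, otherwise it falls through to D.
#'
#' @param y_true,y_pred Aligned numeric vectors (mmHg).
#' @return Tibble with `pct_le_5`, `pct_le_10`, `pct_le_15`, `grade`.
#' @export
bhs_grade <- function(y_true, y_pred) {
  check_error_vector(y_true, y_pred)
  a <- abs(y_pred - y_true)
  pct <- vapply(c(5, 10, 15), function(thr) 100 * mean(a <= thr), 1.0)
  grade <- "D"
  for (g in c("C", "B", "A")) if (all(pct >= BHS_TABLE[[g]])) grade <- g
  tibble::tibble(pct_le_5 = pct[1], pct_le_10 = pct[2], pct_le_15 = pct[3],
                 grade = grade)
}

#' AAMI compliance check
#'
#' Mean error (prediction minus ground truth) and its sample standard
#' deviation, against the device standard: |ME| <= 5 mmHg, SD <= 8 mmHg,
#' and at least 85 evaluated subjects. All boundaries are inclusive.
#'
#' @param y_true,y_pred Aligned numeric vectors (mmHg).
#' @param n_subjects Number of distinct subjects behind the segments.
#' @return Tibble with `me`, `std`, `n_subjects`, `pass`.
#' @export
aami_check <- function(y_true, y_pred, n_subjects) {
  check_error_vector(y_true, y_pred)
  d <- y_pred - y_true
  me <- mean(d)
  s <- if (length(d) >= 2) sd(d) else 0
  tibble::tibble(me = me, std = s, n_subjects = as.integer(n_subjects),
                 pass = abs(me) <= 5 && s <= 8 && n_subjects >= 85)
}

#' Bland-Altman agreement limits
#'
#' Mean and sample standard deviation of the differences (prediction minus
#' ground truth) with the 95% limits of agreement `mu +/- 1.96 sigma`.
#'
#' @param y_true,y_pred Aligned numeric vectors, length >= 2.
#' @return Tibble with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(y_true, y_pred) {
  check_error_vector(y_true, y_pred)
  if (length(y_true) < 2) abort("Bland-Altman needs at least 2 pairs")
  d <- y_pred - y_true
  bland_altman_limits(mean(d), sd(d))
}

#' Limits of agreement from summary statistics
#' @param mean_diff,sd_diff Mean and standard deviation of the differences.
#' @return Tibble with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`
#'   (`mean_diff -/+ 1.96 * sd_diff`).
#' @export
bland_altman_limits <- function(mean_diff, sd_diff) {
  tibble::tibble(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = mean_diff - 1.96 * sd_diff,
                 loa_high = mean_diff + 1.96 * sd_diff)
}

#' Sample Pearson correlation
#'
#' Sample covariance over the product of sample standard deviations.
#' @param x,y Equal-length numeric vectors (length >= 2), both
#'   non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("pearson_r needs two aligned vectors of length >= 2")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Least-squares linear fit
#' @param x,y As in [pearson_r()].
#' @return Tibble with `intercept` (beta0) and `slope` (beta1).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("linear_fit needs two aligned vectors of length >= 2")
  }
  if (sd(x) == 0) abort("linear fit undefined for constant predictor")
  b1 <- stats::cov(x, y) / stats::var(x)
  tibble::tibble(intercept = mean(y) - b1 * mean(x), slope = b1)
}

#' Full evaluation report
#'
#' Bundles the field's standard metrics for one prediction target: MAE,
#' mean error and its SD, BHS cumulative percentages and grade, AAMI
#' verdict, Bland-Altman limits, Pearson correlation and the linear fit of
#' predictions on ground truths.
#'
#' @param data Data frame with columns `y_true`, `y_pred`, and optionally
#'   `subject_id` (used to count distinct subjects for AAMI).
#' @param target Label carried into the report (e.g. `"sbp"`).
#' @param n_subjects Override for the AAMI subject count.
#' @return A `bp_eval` object; see [tidy.bp_eval()] / [glance.bp_eval()].
#' @export
bp_evaluate <- function(data, target = "bp", n_subjects = NULL) {
  y_true <- data$y_true
  y_pred <- data$y_pred
  check_error_vector(y_true, y_pred)
  n_subjects <- n_subjects %||%
    (if ("subject_id" %in% names(data)) dplyr::n_distinct(data$subject_id)
     else length(y_true))
  out <- list(
    target = target,
    n = length(y_true),
    mae = mae(y_true, y_pred),
    bhs = bhs_grade(y_true, y_pred),
    aami = aami_check(y_true, y_pred, n_subjects),
    bland_altman = if (length(y_true) >= 2) bland_altman(y_true, y_pred) else NULL,
    pearson_r = if (length(y_true) >= 2 && sd(y_true) > 0 && sd(y_pred) > 0) {
      pearson_r(y_true, y_pred)
    } else NA_real_,
    fit = if (length(y_true) >= 2 && sd(y_true) > 0) {
      linear_fit(y_true, y_pred)
    } else NULL,
    data = tibble::as_tibble(data))
  class(out) <- "bp_eval"
  out
}

#' Tidy an evaluation report
#' @param x A `bp_eval`.
#' @param ... Unused.
#' @return One row per metric: `metric`, `value` (numeric), `label`.
#' @method tidy bp_eval
#' @export
tidy.bp_eval <- function(x, ...) {
  ba <- x$bland_altman
  tibble::tribble(
    ~metric, ~value, ~label,
    "mae", x$mae, NA_character_,
    "me", x$aami$me, NA_character_,
    "std", x$aami$std, NA_character_,
    "pct_le_5", x$bhs$pct_le_5, NA_character_,
    "pct_le_10", x$bhs$pct_le_10, NA_character_,
    "pct_le_15", x$bhs$pct_le_15, NA_character_,
    "bhs_grade", NA_real_, x$bhs$grade,
    "aami_pass", as.numeric(x$aami$pass), NA_character_,
    "loa_low", if (is.null(ba)) NA_real_ else ba$loa_low, NA_character_,
    "loa_high", if (is.null(ba)) NA_real_ else ba$loa_high, NA_character_,
    "pearson_r", x$pearson_r, NA_character_,
    "slope", if (is.null(x$fit)) NA_real_ else x$fit$slope, NA_character_,
    "intercept", if (is.null(x$fit)) NA_real_ else x$fit$intercept, NA_character_)
}

#' One-row summary of an evaluation report
#' @param x A `bp_eval`.
#' @param ... Unused.
#' @method glance bp_eval
#' @export
glance.bp_eval <- function(x, ...) {
  tibble::tibble(target = x$target, n = x$n, mae = x$mae,
                 me = x$aami$me, std = x$aami$std,
                 bhs_grade = x$bhs$grade, aami_pass = x$aami$pass,
                 pearson_r = x$pearson_r)
}

#' @export
print.bp_eval <- function(x, ...) {
  cat(sprintf("<bp_eval> %s, n = %d\n", x$target, x$n))
  cat(sprintf("  MAE %.3f mmHg | ME %.3f +/- %.3f\n", x$mae, x$aami$me,
              x$aami$std))
  cat(sprintf("  BHS %.2f%% / %.2f%% / %.2f%% -> grade %s | AAMI %s (n_subjects %d)\n",
              x$bhs$pct_le_5, x$bhs$pct_le_10, x$bhs$pct_le_15, x$bhs$grade,
              if (x$aami$pass) "pass" else "fail", x$aami$n_subjects))
  if (!is.null(x$bland_altman)) {
    cat(sprintf("  Bland-Altman [%.3f, %.3f] | r = %.3f\n",
                x$bland_altman$loa_low, x$bland_altman$loa_high, x$pearson_r))
  }
  invisible(x)
}
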