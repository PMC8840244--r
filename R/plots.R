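#' Plot an evaluation report
#'
#' Two panels in the style of agreement figures for blood-pressure
#' studies: predictions against ground truth with the least-squares line,
#' and a Bland-Altman plot with the mean difference and the 95% limits of
#' agreement.
#'
#' @param object A `bp_eval`.
#' @param which `"regression"`, `"bland-altman"` or `"both"`.
#' @param ... Unused.
#' @return A ggplot object (patchwork-free: `"both"` facets the two views).
#' @method autoplot bp_eval
#' @export
autoplot.bp_eval <- function(object, which = c("both", "regression",
                                               "bland-altman"), ...) {
  which <- match.arg(which)
  d <- object$data
  reg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$y_true, y = .data$y_pred)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "ground truth (mmHg)", y = "prediction (mmHg)",
                  title = sprintf("%s: r = %.3f", object$target,
                                  object$pearson_r))
  if (which == "regression") return(reg)
  ba <- object$bland_altman
  bd <- tibble::tibble(m = (d$y_true + d$y_pred) / 2, diff = d$y_pred - d$y_true)
  bap <- ggplot2::ggplot(bd, ggplot2::aes(x = .data$m, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "mean of pair (mmHg)", y = "prediction - truth (mmHg)",
                  title = sprintf("%s: LoA [%.3f, %.3f]", object$target,
                                  ba$loa_low, ba$loa_high))
  if (which == "bland-altman") return(bap)
  bd$panel <- "Bland-Altman"
  both <- dplyr::bind_rows(
    tibble::tibble(x = d$y_true, y = d$y_pred, panel = "regression"),
    tibble::tibble(x = bd$m, y = bd$diff, panel = "Bland-Altman"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = toupper(object$target))
}

#' Plot autoencoder training history
#' @param object A trained `bp_autoencoder`.
#' @param ... Unused.
#' @return ggplot of train/validation loss and the monitored metric.
#' @method autoplot bp_autoencoder
#' @export
autoplot.bp_autoencoder <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history")
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' Plot the channels of one segment
#' @param segments A `segment_tbl`.
#' @param segment_id Which record to draw (default: first).
#' @return ggplot with one facet per channel.
#' @export
plot_segment <- function(segments, segment_id = segments$segment_id[1]) {
  i <- match(segment_id, segments$segment_id)
  if (is.na(i)) abort(sprintf("unknown segment_id %s", segment_id))
  rows <- list()
  for (ch in present_channels(segments[i, ])) {
    v <- segments[[ch]][[i]]
    rows[[ch]] <- tibble::tibble(
      t = (seq_along(v) - 1) / segments$fs[i],
      value = v, channel = toupper(ch))
  }
  d <- dplyr::bind_rows(rows)
  d$channel <- factor(d$channel, levels = toupper(BP_CHANNELS))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = segment_id)
}
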