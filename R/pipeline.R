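#' Run the two-stage blood-pressure pipeline end to end
#'
#' Orchestrates: train/test split, preprocessing (with the global pressure
#' divisor computed on the training partition only), autoencoder training,
#' feature extraction for both partitions, per-target regressor training,
#' prediction, and evaluation. When `workdir` is given, the artifacts are
#' written there: rejection report, feature tables, predictions,
#' per-epoch training history, evaluation report (JSON), and a manifest
#' with a config digest.
#'
#' @param segments Raw `segment_tbl` (at least `ppg` and `abp`).
#' @param labels_truth Optional ground-truth label table (used only for
#'   reporting; evaluation always uses the extracted labels).
#' @param cfg A [unet_config()].
#' @param tcfg A [train_config()].
#' @param thr [quality_thresholds()].
#' @param spec_bp [bandpass_spec()].
#' @param channels Predictor channels in stacking order.
#' @param regressor `"mlp"` etc.; see [regressor_spec()].
#' @param test_fraction Held-out fraction (record-level seeded split;
#'   subject-level disjointness is enforced when subject ids repeat).
#' @param split_by `"record"` or `"subject"`.
#' @param seed Global seed (split + training + regressors).
#' @param workdir Optional artifact directory.
#' @param verbose Progress messages.
#' @return A `bp_pipeline` list: `model`, `regressors`, `features`,
#'   `predictions`, `eval` (list of `bp_eval` per target), `preprocess`,
#'   `split`, `manifest`.
#' @export
run_bp_pipeline <- function(segments, labels_truth = NULL,
                            cfg = unet_config(depth = 1, width = 32,
                                              kernel = 3, channels = 1,
                                              n_features = 128),
                            tcfg = train_config(max_epochs = 10, patience = 5),
                            thr = quality_thresholds(),
                            spec_bp = bandpass_spec(),
                            channels = c("ppg", "vpg", "apg", "ecg"),
                            regressor = "mlp",
                            test_fraction = 0.25,
                            split_by = c("record", "subject"),
                            seed = 1L, workdir = NULL, verbose = FALSE) {
  split_by <- match.arg(split_by)
  validate_segments(segments, require = c("ppg", "abp"))
  channels <- channels[seq_len(cfg$channels)]

  # seeded train/test split
  ids <- segments$segment_id
  split <- withr::with_seed(seed, {
    if (split_by == "subject") {
      subj <- unique(segments$subject_id)
      test_subj <- sample(subj, max(1, round(test_fraction * length(subj))))
      list(test = ids[segments$subject_id %in% test_subj])
    } else {
      list(test = sample(ids, max(1, round(test_fraction * length(ids)))))
    }
  })
  split$train <- setdiff(ids, split$test)

  if (verbose) message("preprocessing ", length(ids), " segments")
  prep <- preprocess_segments(segments, thr = thr, spec = spec_bp,
                              out_len = cfg$input_length,
                              train_ids = split$train)
  clean <- prep$segments
  is_train <- clean$segment_id %in% split$train
  if (!any(is_train) || !any(!is_train)) {
    abort("train or test partition empty after preprocessing")
  }

  X_train <- stack_channels(clean[is_train, ], channels)
  X_test <- stack_channels(clean[!is_train, ], channels)
  T_train <- stack_target(clean[is_train, ], cfg$target)

  if (verbose) message("training autoencoder on ", sum(is_train), " segments")
  tcfg$seed <- seed
  model <- train_autoencoder(cfg, X_train, T_train, tcfg, verbose = verbose)

  feats_train <- extract_features(model, X_train)
  feats_test <- extract_features(model, X_test)

  labels <- prep$labels
  regs <- list(); preds <- list(); evals <- list()
  for (target in c("sbp", "dbp")) {
    rspec <- if (regressor == "mlp") default_mlp_spec(target, seed = seed)
             else regressor_spec(regressor, target = target, seed = seed)
    regs[[target]] <- train_regressor(feats_train, labels, rspec)
    p <- predict(regs[[target]], feats_test)
    truth <- labels[match(p$segment_id, labels$segment_id), ]
    y_true <- truth[[target]]
    preds[[target]] <- tibble::tibble(segment_id = p$segment_id,
                                      target = target,
                                      y_true = y_true,
                                      y_pred = p$.pred,
                                      subject_id = truth$subject_id)
    evals[[target]] <- bp_evaluate(preds[[target]], target = target)
  }
  predictions <- dplyr::bind_rows(preds)

  manifest <- list(
    n_records = nrow(segments), n_clean = nrow(clean),
    n_train = sum(is_train), n_test = sum(!is_train),
    channels = channels, seed = seed,
    unet = unclass(cfg), train = unclass(model$tcfg),
    regressor = regressor,
    global_sbp_max = prep$ctx$global_sbp_max,
    config_digest = rlang::hash(list(unclass(cfg), unclass(model$tcfg),
                                     regressor, seed)))

  out <- structure(list(model = model, regressors = regs,
                        features = list(train = feats_train,
                                        test = feats_test),
                        predictions = predictions, eval = evals,
                        preprocess = prep, split = split,
                        manifest = manifest),
                   class = "bp_pipeline")
  if (!is.null(workdir)) write_pipeline_artifacts(out, workdir)
  out
}

write_pipeline_artifacts <- function(res, workdir) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$preprocess$rejections,
                   file.path(workdir, "rejections.csv"))
  readr::write_csv(res$features$train, file.path(workdir, "features_train.csv"))
  readr::write_csv(res$features$test, file.path(workdir, "features_test.csv"))
  readr::write_csv(res$predictions, file.path(workdir, "predictions.csv"))
  readr::write_csv(res$model$history, file.path(workdir, "history.csv"))
  report <- lapply(res$eval, function(ev) {
    g <- glance(ev)
    c(as.list(g), as.list(ev$bhs), as.list(ev$bland_altman))
  })
  jsonlite::write_json(report, file.path(workdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(res$model[c("config", "params", "history", "best_epoch")],
          file.path(workdir, "checkpoint.rds"))
  invisible(workdir)
}

#' @export
print.bp_pipeline <- function(x, ...) {
  cat(sprintf("<bp_pipeline> %d records -> %d clean (train %d / test %d)\n",
              x$manifest$n_records, x$manifest$n_clean, x$manifest$n_train,
              x$manifest$n_test))
  for (ev in x$eval) print(ev)
  invisible(x)
}

#' Architecture sweep
#'
#' Runs the pipeline once per grid cell, varying one or more architecture
#' axes (`depth`, `width`, `kernel`, `channels`, `n_features`, `target`),
#' and tabulates held-out SBP/DBP MAE. Infeasible cells (input length not
#' divisible by `2^depth`) are marked skipped and the sweep continues. An
#' empty grid runs the single base configuration.
#'
#' @param segments Raw `segment_tbl`.
#' @param grid Named list, axis -> vector of values.
#' @param cfg Base [unet_config()] supplying the fixed axes.
#' @param ... Passed to [run_bp_pipeline()].
#' @return Tibble: one row per cell with the axis values, `sbp_mae`,
#'   `dbp_mae`, `skipped`.
#' @export
run_sweep <- function(segments, grid = list(), cfg = unet_config(
                        depth = 1, width = 32, kernel = 3, channels = 1,
                        n_features = 128), ...) {
  axes <- names(grid)
  allowed <- c("depth", "width", "kernel", "channels", "n_features", "target")
  if (!all(axes %in% allowed)) {
    abort(sprintf("sweep axes must be among %s",
                  paste(allowed, collapse = ", ")))
  }
  cells <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
           else data.frame(.default = TRUE)
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    cell_cfg <- unclass(cfg)
    for (ax in axes) cell_cfg[[ax]] <- cells[r, ax]
    cell <- tibble::as_tibble(cells[r, , drop = FALSE])
    res <- tryCatch({
      cfg_r <- do.call(unet_config, cell_cfg[c("depth", "width", "kernel",
                                               "channels", "n_features",
                                               "target", "upsample",
                                               "convs_per_block",
                                               "input_length",
                                               "feature_activation")])
      run_bp_pipeline(segments, cfg = cfg_r, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[r]] <- dplyr::bind_cols(cell, tibble::tibble(
        sbp_mae = NA_real_, dbp_mae = NA_real_, skipped = TRUE,
        note = conditionMessage(res)))
    } else {
      rows[[r]] <- dplyr::bind_cols(cell, tibble::tibble(
        sbp_mae = res$eval$sbp$mae, dbp_mae = res$eval$dbp$mae,
        skipped = FALSE, note = NA_character_))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (".default" %in% names(out)) out$.default <- NULL
  if (length(axes)) out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(axes)))
  out
}
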