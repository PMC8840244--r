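#' Autoencoder training configuration
#'
#' Defaults mirror the study setup: batch size 64, up to 100 epochs,
#' early-stopping patience 15, mean-squared-error loss, Adam with standard
#' moment decays, validation mean-absolute-error as the monitored metric,
#' and a random 20% validation split fixed by `seed`.
#'
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping (0 trains exactly one epoch).
#' @param val_fraction Fraction of segments held out for validation.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param seed Integer seed fixing split, initialization and batch order.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64, max_epochs = 100, patience = 15,
                         val_fraction = 0.2, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, patience <= max_epochs)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, seed = as.integer(seed),
                 loss = "mse", monitored = "val_mae"),
            class = "train_config")
}

#' Stack predictor channels of a segment table into a tensor
#'
#' @param segments A preprocessed `segment_tbl`.
#' @param channels Channel names in declared stacking order (subset of
#'   `c("ppg", "vpg", "apg", "ecg")`).
#' @return Numeric array of dim `(n_segments, length, n_channels)` with
#'   `segment_id` rownames-like attribute `"segment_id"`.
#' @export
stack_channels <- function(segments, channels = c("ppg", "vpg", "apg", "ecg")) {
  missing <- channels[vapply(channels, function(ch) {
    !ch %in% names(segments) || any(vapply(segments[[ch]], is.null, TRUE))
  }, TRUE)]
  if (length(missing)) {
    abort(sprintf("channel(s) not present on all segments: %s",
                  paste(missing, collapse = ", ")))
  }
  n <- nrow(segments)
  L <- length(segments[[channels[1]]][[1]])
  X <- array(0, c(n, L, length(channels)))
  for (c_i in seq_along(channels)) {
    for (i in seq_len(n)) X[i, , c_i] <- segments[[channels[c_i]]][[i]]
  }
  attr(X, "segment_id") <- segments$segment_id
  X
}

#' Target waveform matrix for autoencoder training
#' @param segments Preprocessed `segment_tbl`.
#' @param target `"abp"` (normalized pressure) or `"ppg"`.
#' @return `n x length` numeric matrix.
#' @export
stack_target <- function(segments, target = c("abp", "ppg")) {
  target <- match.arg(target)
  do.call(rbind, segments[[target]])
}

#' Train the U-Net autoencoder
#'
#' Mini-batch Adam on mean-squared-error between the network output and the
#' target waveform, with seeded validation split and early stopping on
#' validation mean absolute error; the weights of the best monitored epoch
#' are restored. Reruns with identical data, config and seed are
#' bit-reproducible.
#'
#' @param model A `bp_autoencoder` from [build_autoencoder()], or a
#'   [unet_config()] (a model is then built with `tcfg$seed`).
#' @param inputs Array `(n, input_length, channels)` from
#'   [stack_channels()].
#' @param targets Matrix `(n, input_length)` from [stack_target()].
#' @param tcfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained `bp_autoencoder` with a `history` tibble
#'   (epoch, train_loss, val_loss, val_mae) and `best_epoch`.
#' @export
train_autoencoder <- function(model, inputs, targets,
                              tcfg = train_config(), verbose = FALSE) {
  if (inherits(model, "unet_config")) {
    model <- build_autoencoder(model, seed = tcfg$seed)
  }
  cfg <- model$config
  n <- dim(inputs)[1]
  if (nrow(targets) != n) abort("inputs and targets are not row-aligned")
  if (dim(inputs)[2] != cfg$input_length || dim(inputs)[3] != cfg$channels) {
    abort(sprintf("input tensor is %d x %d, config expects %d x %d",
                  dim(inputs)[2], dim(inputs)[3],
                  cfg$input_length, cfg$channels))
  }
  X <- aperm(inputs, c(2, 1, 3)) # (L, N, C)
  Tm <- t(targets)               # (L, N)

  idx <- withr::with_seed(tcfg$seed, sample.int(n))
  n_val <- max(1L, round(tcfg$val_fraction * n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  batch_size <- tcfg$batch_size
  if (length(tr_idx) < batch_size) {
    warn(sprintf("training set (%d) smaller than batch size; reducing to %d",
                 length(tr_idx), length(tr_idx)))
    batch_size <- length(tr_idx)
  }

  state <- nn_adam_init(model$params)
  best <- list(metric = Inf, params = model$params, epoch = 0L)
  hist <- list()
  stall <- 0L

  val_forward <- function(params) {
    m <- model; m$params <- params
    preds <- matrix(0, cfg$input_length, length(val_idx))
    for (chunk in split(seq_along(val_idx),
                        ceiling(seq_along(val_idx) / batch_size))) {
      fb <- unet_forward(m, X[, val_idx[chunk], , drop = FALSE])
      preds[, chunk] <- fb$out
    }
    err <- preds - Tm[, val_idx, drop = FALSE]
    c(mse = mean(err^2), mae = mean(abs(err)))
  }

  withr::with_seed(tcfg$seed + 1L, {
    for (epoch in seq_len(tcfg$max_epochs)) {
      perm <- sample(tr_idx)
      batches <- split(perm, ceiling(seq_along(perm) / batch_size))
      ep_loss <- 0
      for (b in batches) {
        Xb <- X[, b, , drop = FALSE]
        Tb <- Tm[, b, drop = FALSE]
        fwd <- unet_forward(model, Xb, keep_cache = TRUE)
        err <- fwd$out - Tb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          abort(sprintf("non-finite training loss at epoch %d", epoch))
        }
        ep_loss <- ep_loss + loss * length(b)
        dOut <- 2 * err / length(err)
        grads <- unet_backward(model, fwd, dOut)
        upd <- nn_adam_step(model$params, grads, state, lr = tcfg$lr,
                            beta1 = tcfg$beta1, beta2 = tcfg$beta2,
                            eps = tcfg$eps)
        model$params <- upd$params
        state <- upd$state
      }
      vm <- val_forward(model$params)
      hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                      train_loss = ep_loss / length(perm),
                                      val_loss = vm[["mse"]],
                                      val_mae = vm[["mae"]])
      if (verbose) {
        message(sprintf("epoch %3d  train_mse %.5g  val_mae %.5g",
                        epoch, ep_loss / length(perm), vm[["mae"]]))
      }
      if (vm[["mae"]] < best$metric) {
        best <- list(metric = vm[["mae"]], params = model$params,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (tcfg$patience == 0L || stall >= max(tcfg$patience, 1L)) break
    }
  })

  model$params <- best$params
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model$tcfg <- tcfg
  model
}

#' Extract bottleneck features
#'
#' Activations of the in-line dense feature layer for each input segment
#' (post-activation by default, per the config's `feature_activation`).
#'
#' @param model Trained `bp_autoencoder`.
#' @param inputs Array `(n, input_length, channels)`.
#' @param batch_size Inference chunk size.
#' @return Tibble: `segment_id` (from the tensor attribute, or row number)
#'   plus `n_features` numeric columns `f0001`, `f0002`, ...
#' @export
extract_features <- function(model, inputs, batch_size = 64) {
  cfg <- model$config
  if (dim(inputs)[3] != cfg$channels) {
    abort(sprintf("channel mismatch: tensor has %d, config expects %d",
                  dim(inputs)[3], cfg$channels))
  }
  n <- dim(inputs)[1]
  X <- aperm(inputs, c(2, 1, 3))
  Fm <- matrix(0, n, cfg$n_features)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fb <- unet_forward(model, X[, chunk, , drop = FALSE], upto = "features")
    Fm[chunk, ] <- fb$features
  }
  ids <- attr(inputs, "segment_id") %||% as.character(seq_len(n))
  colnames(Fm) <- sprintf("f%04d", seq_len(cfg$n_features))
  dplyr::bind_cols(tibble::tibble(segment_id = ids),
                   tibble::as_tibble(Fm))
}

#' Reconstruct target waveforms
#' @param model Trained `bp_autoencoder`.
#' @param inputs Array `(n, input_length, channels)`.
#' @param batch_size Inference chunk size.
#' @return `n x input_length` matrix of predicted target waveforms.
#' @export
reconstruct <- function(model, inputs, batch_size = 64) {
  cfg <- model$config
  if (dim(inputs)[3] != cfg$channels) {
    abort(sprintf("channel mismatch: tensor has %d, config expects %d",
                  dim(inputs)[3], cfg$channels))
  }
  n <- dim(inputs)[1]
  X <- aperm(inputs, c(2, 1, 3))
  out <- matrix(0, n, cfg$input_length)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fb <- unet_forward(model, X[, chunk, , drop = FALSE])
    out[chunk, ] <- t(fb$out)
  }
  out
}

#' @export
print.bp_autoencoder <- function(x, ...) {
  pc <- count_parameters(x$config)
  cat(sprintf(
    "<bp_autoencoder> depth %d, width %d, kernel %d, %d channel(s), %d features (%s)\n",
    x$config$depth, x$config$width, x$config$kernel, x$config$channels,
    x$config$n_features, if (x$trained) "trained" else "untrained"))
  cat(sprintf("  backbone %s + dense %s weights; bottleneck map %d x %d\n",
              format(pc$backbone_weights, big.mark = ","),
              format(pc$feature_dense_weights, big.mark = ","),
              pc$bottleneck[["length"]], pc$bottleneck[["channels"]]))
  if (!is.null(x$history)) {
    cat(sprintf("  %d epoch(s), best val MAE %.5g at epoch %d\n",
                nrow(x$history), min(x$history$val_mae), x$best_epoch))
  }
  invisible(x)
}
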