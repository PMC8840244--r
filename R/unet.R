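#' Shallow 1-D U-Net autoencoder configuration
#'
#' Architecture grid of the feature-extraction network: an encoder of
#' `depth` levels (each level: `convs_per_block` same-padded convolutions
#' with ReLU, channel count doubling per level starting at `width`, then
#' factor-2 max pooling), a flattened dense bottleneck of `n_features`
#' units (the feature layer) with a dense back-projection to the pooled map
#' shape, a bottom convolution block, and a mirrored decoder (upsample,
#' skip concatenation, convolution block) closed by a linear 1x1
#' convolution to one output channel.
#'
#' @param depth Encoder levels, 1-4.
#' @param width Filters at the first level (32-256 in the study grid).
#' @param kernel Odd convolution kernel size, 1-11.
#' @param channels Input channel count, 1-4.
#' @param n_features Dense bottleneck size.
#' @param target Training target selector, `"abp"` (pressure waveform) or
#'   `"ppg"` (self-reconstruction ablation).
#' @param upsample `"transpose-conv"` (kernel 2, stride 2) or
#'   `"nearest+conv"`.
#' @param convs_per_block Convolutions per encoder/decoder block.
#' @param input_length Segment length; must be divisible by `2^depth`.
#' @param feature_activation `"linear"` (default: an identity bottleneck
#'   whose pre-activation values are the extracted features) or `"relu"`
#'   (rectified bottleneck, post-activation features). With heavy skip
#'   connections a rectified bottleneck can die at small training scale
#'   while the skip path carries the loss; the linear bottleneck cannot.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 1, width = 128, kernel = 3, channels = 4,
                        n_features = 1024, target = c("abp", "ppg"),
                        upsample = c("transpose-conv", "nearest+conv"),
                        convs_per_block = 2, input_length = 1024,
                        feature_activation = c("linear", "relu")) {
  target <- match.arg(target)
  upsample <- match.arg(upsample)
  feature_activation <- match.arg(feature_activation)
  if (kernel %% 2 == 0) abort("kernel size must be odd")
  if (depth < 1 || depth > 8) abort("depth must be a small positive integer")
  if (input_length %% 2^depth != 0) {
    abort(sprintf("input_length %d is not divisible by 2^depth = %d",
                  input_length, 2^depth))
  }
  if (width < 1 || n_features < 1 || channels < 1) {
    abort("width, n_features and channels must be >= 1")
  }
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 kernel = as.integer(kernel), channels = as.integer(channels),
                 n_features = as.integer(n_features), target = target,
                 upsample = upsample,
                 convs_per_block = as.integer(convs_per_block),
                 input_length = as.integer(input_length),
                 feature_activation = feature_activation),
            class = "unet_config")
}

# per-layer shapes implied by a config (single source of truth for both the
# builder and the closed-form parameter count)
unet_layout <- function(cfg) {
  d <- cfg$depth; w <- cfg$width; K <- cfg$kernel
  layers <- list()
  add <- function(layers, name, type, cin, cout, k) {
    layers[[name]] <- list(type = type, cin = cin, cout = cout, k = k)
    layers
  }
  for (i in seq_len(d)) {
    cin <- if (i == 1) cfg$channels else w * 2^(i - 2)
    cout <- w * 2^(i - 1)
    for (j in seq_len(cfg$convs_per_block)) {
      layers <- add(layers, sprintf("enc%d_conv%d", i, j), "conv",
                    if (j == 1) cin else cout, cout, K)
    }
  }
  Lb <- cfg$input_length / 2^d
  Cb <- w * 2^(d - 1)
  layers <- add(layers, "dense_in", "dense", Lb * Cb, cfg$n_features, 1)
  layers <- add(layers, "dense_out", "dense", cfg$n_features, Lb * Cb, 1)
  for (j in seq_len(cfg$convs_per_block)) {
    layers <- add(layers, sprintf("bot_conv%d", j), "conv",
                  if (j == 1) Cb else 2 * Cb, 2 * Cb, K)
  }
  for (i in rev(seq_len(d))) {
    cup_in <- w * 2^i
    cup_out <- w * 2^(i - 1)
    layers <- add(layers, sprintf("dec%d_up", i), "up", cup_in, cup_out, 2)
    for (j in seq_len(cfg$convs_per_block)) {
      layers <- add(layers, sprintf("dec%d_conv%d", i, j), "conv",
                    if (j == 1) 2 * cup_out else cup_out, cup_out, K)
    }
  }
  layers <- add(layers, "head", "conv", w, 1, 1)
  attr(layers, "bottleneck") <- c(length = Lb, channels = Cb)
  layers
}

layer_param_count <- function(ly) {
  n_w <- switch(ly$type,
                conv = ly$k * ly$cin * ly$cout,
                up = 2 * ly$cin * ly$cout,
                dense = ly$cin * ly$cout)
  c(weights = n_w, bias = ly$cout)
}

#' Closed-form parameter counts for a U-Net configuration
#'
#' Returns the convolutional backbone size (all convolution, upsampling and
#' output-head parameters), the feature dense layer's weight count (weights
#' only, bias excluded — the figure quoted for the bottleneck is
#' `pooled_length x pooled_channels x n_features`), and the total trainable
#' parameter count including both dense layers and all biases. The counts
#' are exact for the built model.
#'
#' @param cfg A [unet_config()].
#' @return Named list: `backbone_weights`, `feature_dense_weights`,
#'   `total`, `bottleneck` (pooled map shape).
#' @export
count_parameters <- function(cfg) {
  layout <- unet_layout(cfg)
  backbone <- 0; total <- 0; feature_dense <- 0
  for (nm in names(layout)) {
    pc <- layer_param_count(layout[[nm]])
    total <- total + sum(pc)
    if (layout[[nm]]$type != "dense") backbone <- backbone + sum(pc)
    if (nm == "dense_in") feature_dense <- pc[["weights"]]
  }
  list(backbone_weights = backbone, feature_dense_weights = feature_dense,
       total = total, bottleneck = attr(layout, "bottleneck"))
}

#' Build an (untrained) U-Net autoencoder
#'
#' Allocates He-initialized parameters for every layer in the layout implied
#' by `cfg`. The returned handle carries the parameters, the config, and an
#' empty training history.
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed fixing the weight initialization.
#' @return A `bp_autoencoder` handle.
#' @export
build_autoencoder <- function(cfg, seed = 1L) {
  layout <- unet_layout(cfg)
  params <- withr::with_seed(seed, {
    out <- list()
    for (nm in names(layout)) {
      ly <- layout[[nm]]
      fan_in <- switch(ly$type, conv = ly$k * ly$cin, up = ly$cin,
                       dense = ly$cin)
      nrow_w <- switch(ly$type, conv = ly$k * ly$cin, up = 2 * ly$cin,
                       dense = ly$cin)
      out[[paste0(nm, "_W")]] <- nn_he_init(nrow_w, ly$cout, fan_in)
      out[[paste0(nm, "_b")]] <- rep(0, ly$cout)
    }
    out
  })
  structure(list(config = cfg, params = params, layout = layout,
                 history = NULL, trained = FALSE, seed = seed),
            class = "bp_autoencoder")
}

# forward pass; upto = "features" stops after the dense feature layer
unet_forward <- function(model, X, upto = c("all", "features"),
                         keep_cache = FALSE) {
  upto <- match.arg(upto)
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  caches <- list()
  skips <- list()
  H <- X
  for (i in seq_len(d)) {
    for (j in seq_len(cfg$convs_per_block)) {
      nm <- sprintf("enc%d_conv%d", i, j)
      cv <- nn_conv_fwd(H, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                        cfg$kernel)
      rl <- nn_relu_fwd(cv$Y)
      H <- rl$Y
      if (keep_cache) caches[[nm]] <- list(conv = cv, relu = rl)
      else cv <- rl <- NULL
    }
    skips[[i]] <- H
    pl <- nn_pool_fwd(H)
    H <- pl$Y
    if (keep_cache) caches[[sprintf("pool%d", i)]] <- pl
  }
  bshape <- dim(H) # (Lb, N, Cb)
  Hm <- nn_flatten(H)
  di <- nn_dense_fwd(Hm, p$dense_in_W, p$dense_in_b)
  feat_pre <- di$Y
  if (cfg$feature_activation == "relu") {
    frl <- nn_relu_fwd(feat_pre)
    features <- frl$Y
  } else {
    frl <- NULL
    features <- feat_pre
  }
  if (upto == "features") {
    return(list(features = features))
  }
  if (keep_cache) caches$dense_in <- list(dense = di, relu = frl,
                                          bshape = bshape)
  do <- nn_dense_fwd(features, p$dense_out_W, p$dense_out_b)
  drl <- nn_relu_fwd(do$Y)
  H <- nn_unflatten(drl$Y, bshape[1], bshape[3])
  if (keep_cache) caches$dense_out <- list(dense = do, relu = drl)
  for (j in seq_len(cfg$convs_per_block)) {
    nm <- sprintf("bot_conv%d", j)
    cv <- nn_conv_fwd(H, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                      cfg$kernel)
    rl <- nn_relu_fwd(cv$Y)
    H <- rl$Y
    if (keep_cache) caches[[nm]] <- list(conv = cv, relu = rl)
  }
  for (i in rev(seq_len(d))) {
    nm <- sprintf("dec%d_up", i)
    up <- if (cfg$upsample == "transpose-conv") {
      nn_up_fwd(H, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    } else {
      nn_upnn_fwd(H, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    }
    if (keep_cache) caches[[nm]] <- up
    cs <- dim(skips[[i]])[3]
    H <- array(0, dim(up$Y) + c(0, 0, cs))
    H[, , seq_len(cs)] <- skips[[i]]
    H[, , cs + seq_len(dim(up$Y)[3])] <- up$Y
    if (keep_cache) caches[[sprintf("concat%d", i)]] <- cs
    for (j in seq_len(cfg$convs_per_block)) {
      nm <- sprintf("dec%d_conv%d", i, j)
      cv <- nn_conv_fwd(H, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                        cfg$kernel)
      rl <- nn_relu_fwd(cv$Y)
      H <- rl$Y
      if (keep_cache) caches[[nm]] <- list(conv = cv, relu = rl)
    }
  }
  hd <- nn_conv_fwd(H, p$head_W, p$head_b, 1L) # linear output
  if (keep_cache) caches$head <- hd
  list(out = hd$Y[, , 1], features = features, caches = caches,
       skip_dims = lapply(skips, dim))
}

# backward pass for mean-squared-error on the full output
unet_backward <- function(model, fwd, dOut) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  caches <- fwd$caches
  grads <- list()
  dH <- array(dOut, c(dim(dOut)[1], dim(dOut)[2], 1L))
  bw <- nn_conv_bwd(caches$head, p$head_W, 1L, dH)
  grads$head_W <- bw$dW; grads$head_b <- bw$db
  dH <- bw$dX
  dSkips <- list()
  for (i in seq_len(d)) {
    for (j in rev(seq_len(cfg$convs_per_block))) {
      nm <- sprintf("dec%d_conv%d", i, j)
      dH <- nn_relu_bwd(caches[[nm]]$relu, dH)
      bw <- nn_conv_bwd(caches[[nm]]$conv, p[[paste0(nm, "_W")]],
                        cfg$kernel, dH)
      grads[[paste0(nm, "_W")]] <- bw$dW
      grads[[paste0(nm, "_b")]] <- bw$db
      dH <- bw$dX
    }
    cs <- caches[[sprintf("concat%d", i)]]
    dSkips[[i]] <- dH[, , seq_len(cs), drop = FALSE]
    dUp <- dH[, , cs + seq_len(dim(dH)[3] - cs), drop = FALSE]
    nm <- sprintf("dec%d_up", i)
    bw <- if (cfg$upsample == "transpose-conv") {
      nn_up_bwd(caches[[nm]], p[[paste0(nm, "_W")]], dUp)
    } else {
      nn_upnn_bwd(caches[[nm]], p[[paste0(nm, "_W")]], dUp)
    }
    grads[[paste0(nm, "_W")]] <- bw$dW
    grads[[paste0(nm, "_b")]] <- bw$db
    dH <- bw$dX
  }
  for (j in rev(seq_len(cfg$convs_per_block))) {
    nm <- sprintf("bot_conv%d", j)
    dH <- nn_relu_bwd(caches[[nm]]$relu, dH)
    bw <- nn_conv_bwd(caches[[nm]]$conv, p[[paste0(nm, "_W")]],
                      cfg$kernel, dH)
    grads[[paste0(nm, "_W")]] <- bw$dW
    grads[[paste0(nm, "_b")]] <- bw$db
    dH <- bw$dX
  }
  dHm <- nn_flatten(dH)
  dHm <- nn_relu_bwd(caches$dense_out$relu, dHm)
  bw <- nn_dense_bwd(caches$dense_out$dense, p$dense_out_W, dHm)
  grads$dense_out_W <- bw$dW; grads$dense_out_b <- bw$db
  dF <- bw$dX
  if (cfg$feature_activation == "relu") {
    dF <- nn_relu_bwd(caches$dense_in$relu, dF)
  }
  bw <- nn_dense_bwd(caches$dense_in$dense, p$dense_in_W, dF)
  grads$dense_in_W <- bw$dW; grads$dense_in_b <- bw$db
  bshape <- caches$dense_in$bshape
  dH <- nn_unflatten(bw$dX, bshape[1], bshape[3])
  for (i in rev(seq_len(d))) {
    dH <- nn_pool_bwd(caches[[sprintf("pool%d", i)]], dH)
    dH <- dH + dSkips[[i]]
    for (j in rev(seq_len(cfg$convs_per_block))) {
      nm <- sprintf("enc%d_conv%d", i, j)
      dH <- nn_relu_bwd(caches[[nm]]$relu, dH)
      bw <- nn_conv_bwd(caches[[nm]]$conv, p[[paste0(nm, "_W")]],
                        cfg$kernel, dH)
      grads[[paste0(nm, "_W")]] <- bw$dW
      grads[[paste0(nm, "_b")]] <- bw$db
      dH <- bw$dX
    }
  }
  grads
}
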