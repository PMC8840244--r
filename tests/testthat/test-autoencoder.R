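test_that("the pinned architecture reproduces the printed layer sizes", {
  cfg <- unet_config(depth = 1, width = 128, kernel = 3, channels = 4,
                     n_features = 1024)
  pc <- count_parameters(cfg)
  expect_equal(unname(pc$bottleneck), c(512, 128)) # pooled map 512 x 128
  expect_equal(pc$feature_dense_weights, 512 * 128 * 1024) # 67,108,864
  expect_equal(pc$backbone_weights, 559873)
  # within 10% of the quoted "around 0.55 million"
  expect_lt(abs(pc$backbone_weights - 550000) / 550000, 0.1)
  # degenerate corner: 512 x 1 x 1
  tiny <- unet_config(depth = 1, width = 1, kernel = 1, channels = 1,
                      n_features = 1)
  expect_equal(count_parameters(tiny)$feature_dense_weights, 512)
})

test_that("closed-form parameter counts equal the built model exactly on the grid", {
  for (depth in c(1, 4)) {
    for (width in c(4, 12)) { # scaled-down widths, same structural formula
      for (kernel in c(3, 11)) {
        for (channels in c(1, 4)) {
          cfg <- unet_config(depth, width, kernel, channels, n_features = 16)
          m <- build_autoencoder(cfg, seed = 1)
          built <- sum(vapply(m$params, length, 1L))
          expect_equal(count_parameters(cfg)$total, built,
                       info = sprintf("d%d w%d k%d c%d", depth, width,
                                      kernel, channels))
        }
      }
    }
  }
  # full-width corner checked once without allocating the weights twice
  cfg <- unet_config(1, 256, 11, 4, n_features = 32)
  m <- build_autoencoder(cfg, seed = 1)
  expect_equal(count_parameters(cfg)$total, sum(vapply(m$params, length, 1L)))
})

test_that("configuration invariants are enforced", {
  expect_error(unet_config(depth = 3, input_length = 1024 + 4), "divisible")
  expect_error(unet_config(kernel = 4), "odd")
  expect_error(unet_config(width = 0), ">= 1")
  expect_equal(unet_config(depth = 1)$depth, 1L)
})

test_that("an untrained network produces finite, input-dependent output", {
  cfg <- unet_config(depth = 1, width = 8, kernel = 3, channels = 1,
                     n_features = 16, input_length = 256)
  m <- build_autoencoder(cfg, seed = 4)
  X <- array(rnorm(6 * 256), c(6, 256, 1))
  out <- reconstruct(m, X)
  expect_equal(dim(out), c(6, 256))
  expect_true(all(is.finite(out)))
  expect_gt(sd(out[1, ] - out[2, ]), 0) # no collapsed constant head
  Xz <- array(0, c(2, 256, 1))
  expect_true(all(is.finite(reconstruct(m, Xz))))
})

test_that("training memorizes a tiny identity task and restores the best epoch", {
  withr::with_seed(8, {
    X <- array(0, c(8, 256, 1))
    for (i in 1:8) X[i, , 1] <- normalize_unit_range(
      sin(2 * pi * (2 + i / 4) * (0:255) / 125 + i))
  })
  targets <- X[, , 1]
  cfg <- unet_config(depth = 1, width = 16, kernel = 3, channels = 1,
                     n_features = 64, input_length = 256, target = "ppg")
  tcfg <- train_config(batch_size = 8, max_epochs = 200, patience = 200,
                       val_fraction = 0.25, seed = 5)
  expect_warning(m <- train_autoencoder(cfg, X, targets, tcfg),
                 "smaller than batch")
  expect_lt(min(m$history$train_loss), 1e-3)
  expect_true(all(is.finite(m$history$val_mae)))
  # restored weights reproduce the minimum recorded monitored metric
  expect_equal(min(m$history$val_mae), m$history$val_mae[m$best_epoch])
})

test_that("patience zero trains exactly one epoch", {
  X <- array(rnorm(6 * 128), c(6, 128, 1))
  cfg <- unet_config(depth = 1, width = 4, kernel = 3, channels = 1,
                     n_features = 8, input_length = 128)
  m <- train_autoencoder(cfg, X, X[, , 1],
                         train_config(batch_size = 4, max_epochs = 50,
                                      patience = 0, seed = 2))
  expect_equal(nrow(m$history), 1)
})

test_that("identical seeds give identical histories and features", {
  X <- array(rnorm(10 * 128), c(10, 128, 1))
  Tm <- X[, , 1]
  cfg <- unet_config(depth = 1, width = 4, kernel = 3, channels = 1,
                     n_features = 8, input_length = 128)
  tcfg <- train_config(batch_size = 5, max_epochs = 3, patience = 3, seed = 9)
  m1 <- train_autoencoder(cfg, X, Tm, tcfg)
  m2 <- train_autoencoder(cfg, X, Tm, tcfg)
  expect_identical(m1$history, m2$history)
  expect_identical(extract_features(m1, X), extract_features(m2, X))
})

test_that("feature extraction is shape-correct, deterministic and channel-checked", {
  cfg <- unet_config(depth = 1, width = 4, kernel = 3, channels = 1,
                     n_features = 24, input_length = 128)
  m <- build_autoencoder(cfg, seed = 3)
  X <- array(rnorm(10 * 128), c(10, 128, 1))
  X[2, , ] <- X[1, , ] # duplicate rows
  f <- extract_features(m, X)
  expect_equal(dim(f), c(10, 25)) # segment_id + 24 features
  expect_equal(unlist(f[1, -1]), unlist(f[2, -1]))
  X2 <- array(rnorm(10 * 128 * 2), c(10, 128, 2))
  expect_error(extract_features(m, X2), "channel mismatch")
  expect_error(reconstruct(m, X2), "channel mismatch")
})

test_that("the self-reconstruction target option runs the same pipeline end to end", {
  g <- clean_cohort(40)
  prep <- preprocess_segments(g$segments)
  X <- stack_channels(prep$segments, "ppg")
  Tm <- stack_target(prep$segments, "ppg")
  cfg <- unet_config(depth = 1, width = 4, kernel = 3, channels = 1,
                     n_features = 16, target = "ppg")
  m <- train_autoencoder(cfg, X, Tm,
                         train_config(batch_size = 16, max_epochs = 2,
                                      patience = 2, seed = 4))
  expect_equal(m$config$target, "ppg")
  expect_true(all(is.finite(m$history$val_mae)))
})

test_that("non-row-aligned inputs and targets are refused", {
  cfg <- unet_config(depth = 1, width = 4, kernel = 3, channels = 1,
                     n_features = 8, input_length = 128)
  X <- array(rnorm(6 * 128), c(6, 128, 1))
  expect_error(train_autoencoder(cfg, X, X[1:5, , 1], train_config(seed = 1)),
               "row-aligned")
})

test_that("trained features separate low- and high-pressure segments", {
  lo <- generate_segments(synth_config(n_records = 30, seed = 61,
                                       sbp_mean = 100, sbp_sd = 2,
                                       dbp_mean = 62, dbp_sd = 2))
  hi <- generate_segments(synth_config(n_records = 30, seed = 62,
                                       sbp_mean = 160, sbp_sd = 2,
                                       dbp_mean = 66, dbp_sd = 2))
  hi$segments$segment_id <- sub("^syn", "hyp", hi$segments$segment_id)
  segs <- dplyr::bind_rows(lo$segments, hi$segments)
  attr(segs, "bp_metadata") <- segment_metadata(lo$segments)
  prep <- preprocess_segments(segs)
  X <- stack_channels(prep$segments, "ppg")
  Tm <- stack_target(prep$segments, "abp")
  cfg <- unet_config(depth = 1, width = 16, kernel = 3, channels = 1,
                     n_features = 32)
  m <- train_autoencoder(cfg, X, Tm,
                         train_config(batch_size = 16, max_epochs = 30,
                                      patience = 30, seed = 8))
  f <- as.matrix(extract_features(m, X)[-1])
  grp <- prep$segments$segment_id %in% lo$segments$segment_id
  D <- as.matrix(dist(scale(f)))
  within <- mean(D[grp, grp][upper.tri(D[grp, grp])]) / 2 +
    mean(D[!grp, !grp][upper.tri(D[!grp, !grp])]) / 2
  across <- mean(D[grp, !grp])
  expect_gt(across, within)
  # reconstructions beat the training-mean-waveform baseline on held-out data
  rec <- reconstruct(m, X)
  mean_wave <- colMeans(Tm)
  mse_model <- mean((rec - Tm)^2)
  mse_base <- mean(sweep(Tm, 2, mean_wave)^2)
  expect_lt(mse_model, mse_base)
})
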