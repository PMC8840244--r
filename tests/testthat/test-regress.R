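fake_features <- function(n = 120, d = 6, seed = 55) {
  withr::with_seed(seed, {
    sbp <- runif(n, 90, 180)
    dbp <- runif(n, 55, 100)
    x <- cbind(sbp + rnorm(n, 0, 0.1), matrix(rnorm(n * (d - 1)), n))
    colnames(x) <- sprintf("f%02d", seq_len(d))
    list(features = dplyr::bind_cols(
           tibble::tibble(segment_id = sprintf("s%03d", seq_len(n))),
           tibble::as_tibble(x)),
         labels = tibble::tibble(segment_id = sprintf("s%03d", seq_len(n)),
                                 subject_id = "x", sbp = sbp, dbp = dbp))
  })
}

test_that("the default MLP spec carries the printed hyperparameters", {
  s <- default_mlp_spec()
  expect_equal(s$hyperparameters$alpha, 1e-4)
  expect_equal(s$hyperparameters$max_iter, 500)
  expect_equal(s$hyperparameters$hidden_layer_sizes, 100)
  expect_equal(s$hyperparameters$solver, "adam")
  expect_equal(s$hyperparameters$activation, "relu")
  expect_equal(s$hyperparameters$learning_rate, "invscaling")
  expect_equal(s$hyperparameters$batch_size, "auto")
  expect_identical(default_mlp_spec(), default_mlp_spec())
})

test_that("the MLP recovers a label hidden in one feature column", {
  fx <- fake_features(n = 300)
  spec <- default_mlp_spec("sbp", seed = 3)
  spec$hyperparameters$batch_size <- 32 # more Adam steps on a small fixture
  m <- train_regressor(fx$features, fx$labels, spec)
  expect_lt(m$train_mae, 1)
  p <- predict(m, fx$features)
  expect_equal(nrow(p), 300)
  expect_true(all(is.finite(p$.pred)))
  # internal consistency: train_mae reproduces from the scorer
  expect_equal(mae(fx$labels$sbp, p$.pred), m$train_mae)
})

test_that("constant labels yield near-constant predictions", {
  fx <- fake_features()
  lab <- fx$labels
  lab$sbp <- rep(120, nrow(lab))
  for (alg in c("mlp", "knn", "random-forest")) {
    m <- train_regressor(fx$features, lab,
                         regressor_spec(alg, "sbp", seed = 2))
    p <- predict(m, fx$features)
    expect_lt(max(abs(p$.pred - 120)), 2, label = alg)
  }
})

test_that("same seed and data give identical MLP predictions", {
  fx <- fake_features()
  m1 <- train_regressor(fx$features, fx$labels, default_mlp_spec("sbp", seed = 7))
  m2 <- train_regressor(fx$features, fx$labels, default_mlp_spec("sbp", seed = 7))
  expect_identical(predict(m1, fx$features), predict(m2, fx$features))
})

test_that("all eight algorithms fit a synthetic benchmark and score finitely", {
  withr::with_seed(77, {
    n <- 200
    x <- matrix(rnorm(n * 64), n)
    colnames(x) <- sprintf("f%03d", 1:64)
    sbp <- 130 + 15 * x[, 1] - 8 * x[, 2] + rnorm(n, 0, 3)
    features <- dplyr::bind_cols(
      tibble::tibble(segment_id = sprintf("s%03d", 1:n)), tibble::as_tibble(x))
    labels <- tibble::tibble(segment_id = sprintf("s%03d", 1:n),
                             sbp = sbp, dbp = sbp - 50)
  })
  for (alg in c("mlp", "knn", "svr", "sgd", "adaboost", "gradboost",
                "xgboost", "random-forest")) {
    m <- train_regressor(features, labels, regressor_spec(alg, "sbp", seed = 1))
    expect_true(is.finite(m$train_mae), label = alg)
    p <- predict(m, features)
    expect_true(all(is.finite(p$.pred)), label = alg)
    # every algorithm must beat predicting the mean on its own training set
    expect_lt(m$train_mae, mean(abs(sbp - mean(sbp))), label = alg)
  }
})

test_that("SBP and DBP models are independent: shuffling DBP labels leaves SBP alone", {
  fx <- fake_features()
  m_ref <- train_regressor(fx$features, fx$labels, default_mlp_spec("sbp", seed = 5))
  shuffled <- fx$labels
  withr::with_seed(1, shuffled$dbp <- sample(shuffled$dbp))
  m_shuf <- train_regressor(fx$features, shuffled, default_mlp_spec("sbp", seed = 5))
  expect_identical(predict(m_ref, fx$features), predict(m_shuf, fx$features))
})

test_that("misaligned rows, degenerate features and bad dimensions error", {
  fx <- fake_features()
  expect_error(train_regressor(fx$features[1:50, ], fx$labels[51:100, ],
                               default_mlp_spec()), "aligned")
  flat <- fx$features
  for (cn in setdiff(names(flat), "segment_id")) flat[[cn]] <- 0
  expect_error(train_regressor(flat, fx$labels, default_mlp_spec()),
               "degenerate")
  m <- train_regressor(fx$features, fx$labels, default_mlp_spec("sbp"))
  expect_error(predict(m, fx$features[, 1:4]), "dimension")
})

test_that("tidy and glance summarize fitted regressors", {
  fx <- fake_features()
  m <- train_regressor(fx$features, fx$labels, default_mlp_spec("dbp", seed = 2))
  td <- tidy(m)
  expect_true("alpha" %in% td$term)
  gl <- glance(m)
  expect_equal(gl$algorithm, "mlp")
  expect_equal(gl$target, "dbp")
  expect_true(is.finite(gl$train_mae))
})
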