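#' Regressor specification
#'
#' Second-stage model choice: one regressor per blood-pressure target,
#' trained on the autoencoder's bottleneck features.
#'
#' @param algorithm One of `"mlp"`, `"knn"`, `"svr"`, `"sgd"`,
#'   `"adaboost"`, `"gradboost"`, `"xgboost"`, `"random-forest"`.
#' @param target `"sbp"` or `"dbp"`.
#' @param hyperparameters Named list overriding algorithm defaults.
#' @param seed Integer seed for the stochastic algorithms.
#' @return A `regressor_spec` list.
#' @export
regressor_spec <- function(algorithm = c("mlp", "knn", "svr", "sgd",
                                         "adaboost", "gradboost", "xgboost",
                                         "random-forest"),
                           target = c("sbp", "dbp"),
                           hyperparameters = list(), seed = 1L) {
  structure(list(algorithm = match.arg(algorithm),
                 target = match.arg(target),
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Default multilayer-perceptron spec
#'
#' The published MLP setup, verbatim: Adam solver, ReLU activation,
#' inverse-scaling learning-rate schedule label, alpha (L2) 0.0001, batch
#' size `"auto"`, 500 iterations, one hidden layer of 100 units.
#'
#' @param target `"sbp"` or `"dbp"`.
#' @param seed Integer seed.
#' @return A `regressor_spec`.
#' @export
default_mlp_spec <- function(target = "sbp", seed = 1L) {
  regressor_spec("mlp", target = target, seed = seed,
                 hyperparameters = list(solver = "adam",
                                        activation = "relu",
                                        learning_rate = "invscaling",
                                        alpha = 1e-4,
                                        batch_size = "auto",
                                        max_iter = 500,
                                        hidden_layer_sizes = 100))
}

feature_matrix <- function(features) {
  x <- as.matrix(features[setdiff(names(features), "segment_id")])
  storage.mode(x) <- "double"
  x
}

# one-hidden-layer ReLU network trained with Adam on centred targets;
# n_iter_no_change/tol stopping as in the common sklearn-style setup
fit_mlp <- function(x, y, hp, seed) {
  hidden <- hp$hidden_layer_sizes %||% 100
  alpha <- hp$alpha %||% 1e-4
  max_iter <- hp$max_iter %||% 500
  batch <- hp$batch_size %||% "auto"
  if (identical(batch, "auto")) batch <- min(200L, nrow(x))
  tol <- hp$tol %||% 1e-4
  no_change <- hp$n_iter_no_change %||% 10
  lr <- hp$learning_rate_init %||% 1e-3
  d <- ncol(x); n <- nrow(x)
  withr::with_seed(seed, {
    params <- list(W1 = nn_he_init(d, hidden, d), b1 = rep(0, hidden),
                   W2 = nn_he_init(hidden, 1, hidden), b2 = 0)
    state <- nn_adam_init(params)
    best_loss <- Inf; stall <- 0
    for (it in seq_len(max_iter)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (b in split(perm, ceiling(seq_along(perm) / batch))) {
        xb <- x[b, , drop = FALSE]
        yb <- y[b]
        h_pre <- nn_addbias(xb %*% params$W1, params$b1)
        h <- h_pre * (h_pre > 0)
        pred <- drop(h %*% params$W2) + params$b2
        err <- pred - yb
        ep_loss <- ep_loss + sum(err^2) / 2
        g <- err / length(b)
        dW2 <- crossprod(h, g) + alpha * params$W2
        db2 <- sum(g)
        dh <- (matrix(g, ncol = 1) %*% t(params$W2)) * (h_pre > 0)
        dW1 <- crossprod(xb, dh) + alpha * params$W1
        db1 <- colSums(dh)
        upd <- nn_adam_step(params,
                            list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
                            state, lr = lr)
        params <- upd$params; state <- upd$state
      }
      ep_loss <- ep_loss / n
      if (ep_loss > best_loss - tol) stall <- stall + 1 else stall <- 0
      best_loss <- min(best_loss, ep_loss)
      if (stall >= no_change) break
    }
    params
  })
}

predict_mlp <- function(fit, x) {
  h <- nn_addbias(x %*% fit$W1, fit$b1)
  h <- h * (h > 0)
  drop(h %*% fit$W2) + fit$b2
}

# mini-batch stochastic gradient descent, squared loss, L2 penalty,
# inverse-scaling step size
fit_sgd <- function(x, y, hp, seed) {
  alpha <- hp$alpha %||% 1e-4
  eta0 <- hp$eta0 %||% 0.01
  power_t <- hp$power_t %||% 0.25
  max_iter <- hp$max_iter %||% 200
  batch <- hp$batch_size %||% 32
  withr::with_seed(seed, {
    w <- rep(0, ncol(x)); b <- 0; t <- 0
    for (it in seq_len(max_iter)) {
      perm <- sample.int(nrow(x))
      for (bi in split(perm, ceiling(seq_along(perm) / batch))) {
        t <- t + 1
        eta <- eta0 / t^power_t
        xb <- x[bi, , drop = FALSE]
        err <- drop(xb %*% w) + b - y[bi]
        w <- w - eta * (drop(crossprod(xb, err)) / length(bi) + alpha * w)
        b <- b - eta * mean(err)
      }
    }
    list(w = w, b = b)
  })
}

# AdaBoost.R2 with shallow regression trees
fit_adaboost <- function(x, y, hp, seed) {
  m_max <- hp$n_estimators %||% 50
  depth <- hp$max_depth %||% 3
  df <- data.frame(x)
  withr::with_seed(seed, {
    w <- rep(1 / nrow(x), nrow(x))
    trees <- list(); betas <- numeric(0)
    for (m in seq_len(m_max)) {
      idx <- sample.int(nrow(x), replace = TRUE, prob = w)
      fit <- rpart::rpart(y ~ ., data = cbind(df, y = y)[idx, ],
                          control = rpart::rpart.control(maxdepth = depth,
                                                         cp = 0, xval = 0))
      pred <- predict(fit, df)
      ae <- abs(pred - y)
      denom <- max(ae)
      if (denom == 0) { trees[[m]] <- fit; betas[m] <- 1e-10; break }
      lossv <- ae / denom
      lbar <- sum(w * lossv)
      if (lbar >= 0.5) break
      beta <- lbar / (1 - lbar)
      trees[[m]] <- fit
      betas[m] <- beta
      w <- w * beta^(1 - lossv)
      w <- w / sum(w)
    }
    if (!length(trees)) {
      fit <- rpart::rpart(y ~ ., data = cbind(df, y = y),
                          control = rpart::rpart.control(maxdepth = depth,
                                                         cp = 0, xval = 0))
      trees <- list(fit); betas <- 1
    }
    list(trees = trees, betas = betas)
  })
}

predict_adaboost <- function(fit, x) {
  df <- data.frame(x)
  preds <- vapply(fit$trees, function(tr) predict(tr, df),
                  numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  lw <- log(1 / pmax(fit$betas, 1e-12))
  # weighted-median combination
  apply(preds, 1, function(p) {
    o <- order(p)
    cw <- cumsum(lw[o])
    p[o][which(cw >= 0.5 * sum(lw))[1]]
  })
}

# least-squares gradient boosting with shallow trees
fit_gradboost <- function(x, y, hp, seed) {
  m_max <- hp$n_estimators %||% 100
  depth <- hp$max_depth %||% 3
  nu <- hp$learning_rate %||% 0.1
  df <- data.frame(x)
  withr::with_seed(seed, {
    f0 <- mean(y)
    resid <- y - f0
    trees <- vector("list", m_max)
    for (m in seq_len(m_max)) {
      fit <- rpart::rpart(r ~ ., data = cbind(df, r = resid),
                          control = rpart::rpart.control(maxdepth = depth,
                                                         cp = 0, xval = 0))
      trees[[m]] <- fit
      resid <- resid - nu * predict(fit, df)
    }
    list(f0 = f0, trees = trees, nu = nu)
  })
}

predict_gradboost <- function(fit, x) {
  df <- data.frame(x)
  pred <- rep(fit$f0, nrow(df))
  for (tr in fit$trees) pred <- pred + fit$nu * predict(tr, df)
  pred
}

#' Train a blood-pressure regressor on bottleneck features
#'
#' Joins features and labels on `segment_id`, standardizes the feature
#' columns with training-set statistics, and fits the algorithm named in
#' the spec. SBP and DBP models are always trained separately (one target
#' per model).
#'
#' @param features Tibble from [extract_features()] (`segment_id` +
#'   feature columns).
#' @param labels Label tibble with `segment_id` and the target column.
#' @param spec A [regressor_spec()].
#' @return A `bp_regressor` (spec, scaler, fitted state, `train_mae`).
#' @export
train_regressor <- function(features, labels, spec = default_mlp_spec()) {
  stopifnot(inherits(spec, "regressor_spec"))
  if (!spec$target %in% names(labels)) {
    abort(sprintf("labels have no '%s' column", spec$target))
  }
  joined <- dplyr::inner_join(features, labels[c("segment_id", spec$target)],
                              by = "segment_id")
  if (nrow(joined) != nrow(features)) {
    abort("features and labels are not aligned on segment_id")
  }
  y <- joined[[spec$target]]
  x <- feature_matrix(joined[setdiff(names(joined), spec$target)])
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) abort("degenerate features: zero variance everywhere")
  ctr <- colMeans(x)
  scl <- ifelse(sds == 0, 1, sds)
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  y_center <- mean(y)
  yc <- y - y_center
  hp <- spec$hyperparameters
  fit <- switch(
    spec$algorithm,
    mlp = fit_mlp(xs, yc, hp, spec$seed),
    sgd = fit_sgd(xs, yc, hp, spec$seed),
    knn = caret::knnreg(xs, yc, k = hp$k %||% 5),
    svr = e1071::svm(xs, yc, type = "eps-regression",
                     kernel = hp$kernel %||% "radial"),
    adaboost = fit_adaboost(xs, yc, hp, spec$seed),
    gradboost = fit_gradboost(xs, yc, hp, spec$seed),
    xgboost = withr::with_seed(spec$seed, xgboost::xgboost(
      x = xs, y = yc,
      nrounds = hp$nrounds %||% 100, max_depth = hp$max_depth %||% 6,
      learning_rate = hp$eta %||% 0.3, nthreads = 1, verbosity = 0)),
    `random-forest` = ranger::ranger(
      x = xs, y = yc, num.trees = hp$num_trees %||% 100,
      seed = spec$seed, num.threads = 1))
  model <- structure(list(spec = spec, center = ctr, scale = scl,
                          y_center = y_center, fit = fit,
                          n_features = ncol(x)),
                     class = "bp_regressor")
  model$train_mae <- mae(y, predict(model, features)$.pred)
  model
}

#' Predict blood pressure from features
#' @param object A `bp_regressor`.
#' @param features Feature tibble (`segment_id` + the training feature
#'   columns).
#' @param ... Unused.
#' @return Tibble with `segment_id`, `.pred` (mmHg).
#' @export
predict.bp_regressor <- function(object, features, ...) {
  x <- feature_matrix(features)
  if (ncol(x) != object$n_features) {
    abort(sprintf("feature dimension %d does not match training (%d)",
                  ncol(x), object$n_features))
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  pred <- switch(
    object$spec$algorithm,
    mlp = predict_mlp(object$fit, xs),
    sgd = drop(xs %*% object$fit$w) + object$fit$b,
    knn = predict(object$fit, xs),
    svr = as.numeric(predict(object$fit, xs)),
    adaboost = predict_adaboost(object$fit, xs),
    gradboost = predict_gradboost(object$fit, xs),
    xgboost = predict(object$fit, xs),
    `random-forest` = predict(object$fit, data = xs,
                              num.threads = 1)$predictions)
  tibble::tibble(segment_id = features$segment_id,
                 .pred = as.numeric(pred) + object$y_center)
}

#' @method tidy bp_regressor
#' @export
tidy.bp_regressor <- function(x, ...) {
  hp <- x$spec$hyperparameters
  if (!length(hp)) {
    return(tibble::tibble(term = character(), value = character()))
  }
  tibble::tibble(term = names(hp),
                 value = vapply(hp, function(v) paste(format(v), collapse = ","),
                                ""))
}

#' @method glance bp_regressor
#' @export
glance.bp_regressor <- function(x, ...) {
  tibble::tibble(algorithm = x$spec$algorithm, target = x$spec$target,
                 n_features = x$n_features, train_mae = x$train_mae,
                 seed = x$spec$seed)
}

#' @export
print.bp_regressor <- function(x, ...) {
  cat(sprintf("<bp_regressor> %s -> %s (train MAE %.3f mmHg, %d features)\n",
              x$spec$algorithm, toupper(x$spec$target), x$train_mae,
              x$n_features))
  invisible(x)
}
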