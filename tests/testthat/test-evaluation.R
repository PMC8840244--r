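test_that("mean absolute error matches hand computation and is symmetric", {
  expect_equal(mae(c(120, 130), c(122, 127)), 2.5) # (2 + 3) / 2
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- rnorm(50, 120, 10); y <- x + rnorm(50)
  expect_equal(mae(x, y), mae(y, x))
  expect_error(mae(numeric(), numeric()), "empty")
})

test_that("BHS grading reproduces worked examples", {
  z <- rep(120, 10)
  expect_equal(bhs_grade(z, z)$grade, "A")
  expect_equal(bhs_grade(z, z)$pct_le_5, 100)
  # 100 errors: 55 x 3, 35 x 8, 8 x 12, 2 x 20 -> (55, 90, 98), grade B
  err <- c(rep(3, 55), rep(8, 35), rep(12, 8), rep(20, 2))
  g <- bhs_grade(rep(0, 100), err)
  expect_equal(c(g$pct_le_5, g$pct_le_10, g$pct_le_15), c(55, 90, 98))
  expect_equal(g$grade, "B")
  # published cumulative percentages imply grade A
  expect_true(all(c(92.02, 99.18, 99.85) >= c(60, 85, 95)))
})

test_that("BHS grading agrees with brute-force counting on random error vectors", {
  withr::with_seed(42, {
    for (rep in 1:300) {
      err <- rnorm(sample(20:60, 1), mean = runif(1, -4, 4),
                   sd = runif(1, 1, 12))
      got <- bhs_grade(rep(0, length(err)), err)
      ref <- brute_bhs(err)
      expect_equal(c(got$pct_le_5, got$pct_le_10, got$pct_le_15), ref$pct)
      expect_equal(got$grade, ref$grade)
    }
  })
})

test_that("appending zero-error samples never lowers the BHS grade", {
  grades <- c(D = 0, C = 1, B = 2, A = 3)
  withr::with_seed(11, {
    for (rep in 1:50) {
      err <- rnorm(30, 0, runif(1, 2, 15))
      g1 <- bhs_grade(rep(0, 30), err)$grade
      g2 <- bhs_grade(rep(0, 40), c(err, rep(0, 10)))$grade
      expect_gte(grades[g2], grades[g1])
    }
  })
})

test_that("AAMI verdicts use inclusive boundaries and the subject floor", {
  # errors constructed to have exactly ME 0.09 and SD 0.94 over 942 subjects
  withr::with_seed(1, {
    d <- rnorm(942)
    d <- (d - mean(d)) / sd(d) * 0.94 + 0.09
  })
  r <- aami_check(rep(0, 942), d, n_subjects = 942)
  expect_equal(r$me, 0.09)
  expect_equal(r$std, 0.94)
  expect_true(r$pass)
  expect_false(aami_check(rep(0, 100), rep(6, 100), 942)$pass) # ME bound
  # boundary case: exactly 4.9 / 8.0 / 85 passes
  withr::with_seed(2, {
    d <- rnorm(400)
    d <- (d - mean(d)) / sd(d) * 8.0 + 4.9
    r2 <- aami_check(rep(0, 400), d, 85)
    expect_equal(r2$me, 4.9)
    expect_equal(r2$std, 8.0)
    expect_true(r2$pass)
  })
  expect_false(aami_check(rep(0, 10), rep(0, 10), 84)$pass)
})

test_that("Bland-Altman limits match the closed form", {
  withr::with_seed(9, {
    y <- rnorm(200, 120, 15)
    p <- y + rnorm(200, 2, 4)
    ba <- bland_altman(y, p)
    d <- p - y
    expect_equal(ba$mean_diff, mean(d))
    expect_equal(ba$sd_diff, sd(d))
    expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d), tolerance = 1e-9)
  })
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ident), c(mean_diff = 0, sd_diff = 0,
                                loa_low = 0, loa_high = 0))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Pearson correlation matches the sample-sum formula and affine invariance", {
  expect_equal(round(pearson_r(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  expect_equal(pearson_r(1:10, 2 * (1:10) + 3), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  withr::with_seed(5, {
    for (rep in 1:50) {
      x <- rnorm(30); y <- rnorm(30)
      expect_equal(pearson_r(x, y), brute_pearson(x, y), tolerance = 1e-12)
      a <- runif(1, 0.1, 5); b <- rnorm(1)
      expect_equal(pearson_r(a * x + b, y), pearson_r(x, y),
                   tolerance = 1e-9)
    }
  })
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("the least-squares fit matches the normal equations", {
  f <- linear_fit(1:10, 3 + 2 * (1:10))
  expect_equal(f$intercept, 3)
  expect_equal(f$slope, 2)
  f2 <- linear_fit(c(0, 1, 2), c(0, 0, 3))
  expect_equal(f2$slope, 1.5)
  expect_equal(f2$intercept, -0.5)
  withr::with_seed(6, {
    x <- rnorm(40); y <- rnorm(40)
    expect_equal(sign(linear_fit(x, y)$slope), sign(pearson_r(x, y)))
    ref <- unname(coef(lm(y ~ x)))
    f3 <- linear_fit(x, y)
    expect_equal(c(f3$intercept, f3$slope), ref, tolerance = 1e-9)
  })
})

test_that("the bundled report is complete and internally consistent", {
  withr::with_seed(12, {
    d <- tibble::tibble(y_true = rnorm(300, 130, 20),
                        subject_id = rep(sprintf("s%d", 1:100), 3))
    d$y_pred <- d$y_true + rnorm(300, 1, 3)
    ev <- bp_evaluate(d, target = "sbp")
    expect_s3_class(ev, "bp_eval")
    expect_equal(ev$aami$n_subjects, 100L)
    # limits recomputable from mu and sigma
    expect_equal(ev$bland_altman$loa_low,
                 ev$aami$me - 1.96 * ev$aami$std, tolerance = 1e-12)
    td <- tidy(ev)
    expect_true(all(c("mae", "pct_le_5", "loa_high", "slope") %in% td$metric))
    expect_false(any(is.na(td$value[td$metric != "bhs_grade"])))
    gl <- glance(ev)
    expect_equal(gl$n, 300L)
    # perfect predictions: zero error, grade A, AAMI pass
    pd <- tibble::tibble(y_true = rnorm(100, 120, 10),
                         subject_id = sprintf("s%d", 1:100))
    pd$y_pred <- pd$y_true
    pev <- bp_evaluate(pd, "sbp")
    expect_equal(pev$mae, 0)
    expect_equal(pev$bhs$grade, "A")
    expect_true(pev$aami$pass)
  })
})
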