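test_that("univariate regression is recovered exactly", {
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  y <- 2 * x[, 1]
  m <- fit_pls(x, y, 1)
  expect_equal(unname(m$coef), 2, tolerance = 1e-12)
  expect_equal(predict(m, x), y, tolerance = 1e-12)
})

test_that("noiseless mixture data are fit exactly at the true rank", {
  sim <- noiseless_fixture(seed = 5, grid = wavelength_grid(step_nm = 10))
  y <- sim$reference$naringin
  m <- fit_pls(sim$spectra, y, 3)
  expect_lt(rmse <- sqrt(mean((y - predict(m, sim$spectra))^2)), 1e-8)
  # requesting factors beyond the rank errors
  expect_error(fit_pls(sim$spectra, y, 10), "rank")
})

test_that("predictions agree with an independent established PLS oracle", {
  for (rep in 1:10) {
    set.seed(200 + rep)
    x <- matrix(rnorm(30 * 50), 30, 50)
    colnames(x) <- paste0("v", 1:50)
    y <- rnorm(30)
    a <- sample(1:5, 1)
    xn <- matrix(rnorm(8 * 50), 8, 50)
    colnames(xn) <- colnames(x)
    m <- fit_pls(x, y, a)
    oracle <- mixOmics::pls(x, y, ncomp = a, mode = "regression",
                            scale = FALSE)
    expect_equal(predict(m, xn),
                 unname(predict(oracle, xn)$predict[, 1, a]),
                 tolerance = 1e-8)
  }
})

test_that("predict applies stored centering and is stateless", {
  set.seed(12)
  x <- smooth_random_matrix(20, 30, 13)
  y <- rowSums(x[, 5:8]) + rnorm(20, sd = 0.01)
  m <- fit_pls(x, y, 3)
  # the mean spectrum predicts the mean response
  expect_equal(unname(predict(m, matrix(m$x_mean, 1))), m$y_mean,
               tolerance = 1e-10)
  # batch predict equals row-wise predicts
  rowwise <- vapply(1:5, function(i) predict(m, x[i, , drop = FALSE]),
                    numeric(1))
  expect_equal(unname(predict(m, x[1:5, ])), rowwise, tolerance = 1e-12)
  expect_error(predict(m, x[, 1:10]), "expects")
})

test_that("training RMSE is nonincreasing in the factor count", {
  set.seed(14)
  x <- smooth_random_matrix(25, 40, 15)
  y <- rowSums(x[, 10:12]) + rnorm(25, sd = 0.05)
  m <- fit_pls(x, y, 8)
  rmses <- vapply(1:8, function(a) sqrt(mean((y - predict(m, x, a))^2)),
                  numeric(1))
  expect_true(all(diff(rmses) <= 1e-10))
})

test_that("a mask covering all variables equals the full-spectrum model", {
  set.seed(15)
  x <- smooth_random_matrix(20, 25, 16)
  y <- x[, 7] + rnorm(20, sd = 0.01)
  m1 <- fit_pls(x, y, 3)
  m2 <- fit_pls(x, y, 3, mask = seq_len(ncol(x)))
  expect_identical(m1$coef, m2$coef)
  expect_identical(m1$weights, m2$weights)
})

test_that("leave-one-out PRESS selects the true rank on noiseless data", {
  sim <- noiseless_fixture(seed = 6, grid = wavelength_grid(step_nm = 10))
  y <- sim$reference$hesperidin
  cv <- loo_press(sim$spectra, y, a_max = 6)
  expect_equal(cv$selected, 3L)
  expect_lt(cv$rmsecv[3], 1e-8)
  # definitional consistency of RMSECV
  expect_equal(cv$rmsecv, sqrt(cv$press / nrow(sim$spectra$x)))
})

test_that("PRESS on pure-noise responses does not beat the null model", {
  set.seed(17)
  x <- matrix(rnorm(20 * 10), 20, 10)
  not_better <- 0L
  for (rep in 1:50) {
    y <- rnorm(20)
    cv <- loo_press(x, y, a_max = 1)
    null_press <- sum(vapply(1:20, function(i) {
      (y[i] - mean(y[-i]))^2
    }, numeric(1)))
    not_better <- not_better + (cv$press[1] >= null_press)
  }
  expect_gte(not_better, 25L)
})

test_that("a_max is capped with a warning near the sample count", {
  set.seed(18)
  x <- matrix(rnorm(8 * 20), 8, 20)
  y <- rnorm(8)
  expect_warning(cv <- loo_press(x, y, a_max = 10), "capped")
  expect_equal(cv$a_max, 6L)
  expect_error(loo_press(x[1:2, ], y[1:2]), "at least 3")
})

test_that("pipeline metrics behave: exact fit, R2 definition, optimism", {
  grid <- wavelength_grid(step_nm = 10)
  sim <- noiseless_fixture(seed = 7, grid = grid)
  split <- kennard_stone(sim$spectra, 50)
  ev <- evaluate_pipeline(sim$spectra, sim$reference, "naringin", split,
                          a_max = 5)
  expect_equal(ev$metrics$ncomp, 3)
  expect_lt(ev$metrics$rmsec, 1e-8)
  expect_lt(ev$metrics$rmsecv, 1e-8)
  expect_lt(ev$metrics$rmsep, 1e-8)
  expect_gt(ev$metrics$r2_pre, 0.999999)

  # a constant-prediction model has nonpositive prediction R2
  yp <- sim$reference$naringin[split$prediction]
  const <- mean(sim$reference$naringin[split$calibration])
  expect_lte(1 - sum((yp - const)^2) / sum((yp - mean(yp))^2), 0)
  # calibration fit is optimistic relative to cross-validation
  opt <- 0L
  for (seed in 1:20) {
    s2 <- default_fixture(seed = seed, grid = wavelength_grid(step_nm = 20))
    sp2 <- kennard_stone(s2$spectra, 50)
    e2 <- evaluate_pipeline(s2$spectra, s2$reference, "naringin", sp2,
                            a_max = 8)
    opt <- opt + (e2$metrics$r2_cal > e2$metrics$r2_cv)
  }
  expect_gte(opt, 19L)
})

test_that("empty prediction sets report absent RMSEP", {
  grid <- wavelength_grid(step_nm = 50)
  sim <- default_fixture(seed = 9, grid = grid)
  split <- structure(list(calibration = 1:75, prediction = integer(0),
                          sample_ids = rownames(sim$spectra$x),
                          n_calibration = 75L), class = "split_result")
  ev <- evaluate_pipeline(sim$spectra, sim$reference, "naringin", split,
                          a_max = 4)
  expect_true(is.na(ev$metrics$rmsep))
  expect_true(is.na(ev$metrics$r2_pre))
  expect_false(is.na(ev$metrics$rmsecv))
})

test_that("zero-variance responses are rejected", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(fit_pls(x, rep(1, 10), 1), "zero variance")
})
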