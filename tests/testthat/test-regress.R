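test_that("simple linear regression reproduces the five-point calibration", {
  m <- fit_simple_lr(ecd_calibration_points(), alpha_per, ecd_percent)
  expect_equal(m$slope, 1.878, tolerance = 0.001 / 1.878)
  expect_equal(m$intercept, -67.84, tolerance = 0.01 / 67.84)
  expect_equal(m$r_squared, 0.917, tolerance = 0.001 / 0.917)
})

test_that("simple linear regression is exact on a line and matches the
           normal-equations oracle", {
  f <- c(1, 2, 3, 4)
  m <- fit_simple_lr(f, 2 * f + 1)
  expect_equal(c(m$slope, m$intercept, m$r_squared), c(2, 1, 1))

  set.seed(10)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    f <- rnorm(n); y <- rnorm(n)
    m <- fit_simple_lr(f, y)
    o <- oracle_lm(f, y)
    expect_equal(m$intercept, o[["intercept"]], tolerance = 1e-10)
    expect_equal(m$slope, o[["slope"]], tolerance = 1e-10)
    expect_equal(m$r_squared, o[["r_squared"]], tolerance = 1e-10)
  }
  expect_error(fit_simple_lr(rep(1, 5), rnorm(5)), "constant")
  expect_error(fit_simple_lr(1, 2), "at least 2")
})

test_that("simple-LR fit reproduces the mean relation and R^2 is scale
           invariant", {
  set.seed(12)
  f <- runif(10, 20, 90); y <- runif(10)
  m <- fit_simple_lr(f, y)
  expect_equal(mean(y), m$intercept + m$slope * mean(f), tolerance = 1e-9)
  m2 <- fit_simple_lr(3 * f - 40, y)
  expect_equal(m2$r_squared, m$r_squared, tolerance = 1e-12)
})

test_that("SVR keeps noise-free linear data inside the epsilon tube", {
  f <- c(20, 35, 50, 65, 80, 90)
  y <- (f - 20) / 70
  m <- fit_svr(f, y, kernel = "linear", cost = 100, epsilon = 0.01)
  expect_lte(max(abs(svr_predict(m, f, clip = FALSE) - y)), 0.01 + 1e-6)
})

test_that("SVR matches the exhaustive active-set dual oracle on tiny sets", {
  # data already spanning [0, 1] so the internal min-max scaling is identity
  x <- c(0, 0.2, 0.45, 0.6, 0.85, 1)
  y <- c(0, 0.1, 0.5, 0.4, 0.9, 1)
  for (C in c(1, 10)) {
    m <- fit_svr(x, y, kernel = "linear", cost = C, epsilon = 0.05)
    want <- oracle_svr_predict(x, y, C = C, eps = 0.05)
    expect_false(is.null(want))
    expect_equal(svr_predict(m, x, clip = FALSE), want, tolerance = 1e-4)
  }
  m_rbf <- fit_svr(x, y, kernel = "rbf", cost = 5, epsilon = 0.05, gamma = 2)
  want_rbf <- oracle_svr_predict(x, y, C = 5, eps = 0.05, kernel = "rbf",
                                 gamma = 2)
  expect_equal(svr_predict(m_rbf, x, clip = FALSE), want_rbf,
               tolerance = 1e-4)
})

test_that("degree-1 polynomial kernel equals the linear kernel", {
  set.seed(14)
  f <- runif(12, 20, 90)
  y <- pmin(pmax((f - 20) / 70 + rnorm(12, sd = 0.05), 0), 1)
  lin <- fit_svr(f, y, kernel = "linear", cost = 16.59, epsilon = 0.01)
  pol <- fit_svr(f, y, kernel = "poly", cost = 16.59, epsilon = 0.01,
                 gamma = 1, degree = 1, coef0 = 0)
  probe <- seq(20, 90, length.out = 30)
  expect_equal(svr_predict(pol, probe), svr_predict(lin, probe),
               tolerance = 1e-6)
})

test_that("linear-kernel prediction equals the explicit dot-product weights", {
  f <- c(10, 30, 50, 70, 95)
  y <- c(0.05, 0.3, 0.45, 0.7, 0.95)
  m <- fit_svr(f, y, kernel = "linear", cost = 50, epsilon = 0.01)
  xs <- (f - m$x_min) / (m$x_max - m$x_min)
  w <- sum(m$coefs * m$sv[, 1])
  manual_scaled <- w * xs - m$rho
  manual <- m$y_min + manual_scaled * (m$y_max - m$y_min)
  expect_equal(svr_predict(m, f, clip = FALSE), manual, tolerance = 1e-10)
})

test_that("predictions are clipped to [0, 1] when requested", {
  f <- c(20, 40, 60, 80, 100)
  y <- c(0, 0.25, 0.5, 0.75, 1)
  m <- fit_svr(f, y, kernel = "linear", cost = 100, epsilon = 0.001)
  expect_equal(svr_predict(m, 140), 1)
  expect_gt(svr_predict(m, 140, clip = FALSE), 1)
  expect_equal(svr_predict(m, -20), 0)
})

test_that("SVR with small epsilon and large cost approaches least squares
           on noise-free linear data", {
  f <- seq(20, 90, length.out = 15)
  y <- (f - 20) / 70
  m <- fit_svr(f, y, kernel = "linear", cost = 1000, epsilon = 1e-4)
  ls <- fit_simple_lr(f, y)
  expect_lt(max(abs(svr_predict(m, f, clip = FALSE) - predict(ls, f))), 1e-3)
})

test_that("grid search returns the exhaustive-minimum candidate,
           deterministically", {
  cfg <- synth_config(seed = 15)
  coh <- gen_cohort_features(8, cfg)
  gs <- grid_search_svr(coh, alpha_per, observed_ecd, subject,
                        kernel = "linear", cost_grid = c(0.1, 1, 16.59, 100))
  expect_equal(nrow(gs$results), 4)
  expect_equal(gs$best$cv_mse, min(gs$results$cv_mse))
  # exhaustive re-evaluation of every grid point
  manual <- vapply(c(0.1, 1, 16.59, 100), function(C) {
    errs <- vapply(unique(coh$subject), function(s) {
      tr <- coh[coh$subject != s, ]; te <- coh[coh$subject == s, ]
      m <- fit_svr(tr$alpha_per, tr$observed_ecd, kernel = "linear",
                   cost = C, epsilon = 0.01)
      mean((svr_predict(m, te$alpha_per, clip = FALSE) - te$observed_ecd)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_equal(gs$results$cv_mse, manual, tolerance = 1e-12)
  gs2 <- grid_search_svr(coh, alpha_per, observed_ecd, subject,
                         kernel = "linear",
                         cost_grid = c(0.1, 1, 16.59, 100))
  expect_identical(gs$best, gs2$best)
  # single-candidate grid returns that candidate
  gs1 <- grid_search_svr(coh, alpha_per, observed_ecd, subject,
                         kernel = "linear", cost_grid = 2)
  expect_equal(gs1$best$cost, 2)
})
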