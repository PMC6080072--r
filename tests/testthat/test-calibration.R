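test_that("PLS matches an independent SIMPLS implementation", {
  set.seed(11)
  for (i in 1:5) {
    n <- 20L; p <- 8L; A <- sample(1:5, 1L)
    X <- matrix(stats::rnorm(n * p), n)
    y <- as.numeric(X %*% stats::rnorm(p) + stats::rnorm(n))
    fit <- pls_fit(X, y, A)
    orc <- simpls_oracle(X, y, A)
    Xn <- matrix(stats::rnorm(10 * p), 10)
    expect_equal(predict(fit, Xn),
                 as.numeric(Xn %*% orc$beta + orc$intercept),
                 tolerance = 1e-6)
  }
})

test_that("PLS exact-fit, nesting, and centering properties", {
  ## y linear in one predictor, orthogonal design -> one factor is exact
  X <- orthogonal_X(30, 5, seed = 2)
  y <- 2 * X[, 3] + 1
  expect_lt(pls_fit(X, y, 1)$train_rmse, 1e-8)
  ## training residual non-increasing in A
  set.seed(4)
  X <- matrix(stats::rnorm(15 * 6), 15)
  y <- stats::rnorm(15)
  rmse <- vapply(1:6, function(A) pls_fit(X, y, A)$train_rmse, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
  ## predicting the training mean row gives the training response mean
  fit <- pls_fit(X, y, 3)
  expect_equal(predict(fit, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-10)
  expect_equal(predict(fit, X), fit$fitted, tolerance = 1e-10)
  ## duplicated prediction row duplicates the prediction
  Xn <- X[c(1, 1, 2), ]
  pr <- predict(fit, Xn)
  expect_identical(pr[1], pr[2])
})

test_that("PLS guards: factor range, degenerate input, dimensions", {
  X <- matrix(stats::rnorm(10 * 4), 10)
  y <- stats::rnorm(10)
  expect_error(pls_fit(X, y, 0), "A must")
  expect_error(pls_fit(X, y, 5), "A must")
  expect_error(pls_fit(matrix(1, 10, 3), y, 1), "degenerate")
  expect_error(pls_fit(X, rep(1, 10), 1), "constant response")
  fit <- pls_fit(X, y, 2)
  expect_error(predict(fit, matrix(0, 2, 5)), "columns")
})

test_that("cross-validation scores strictly out of fold", {
  ro <- rank_one_data(20, 4, seed = 3)   # exact one-factor fit in any fold
  cv <- cross_validate(ro$X, ro$y, 1, "loo")
  expect_lt(as.numeric(cv), 1e-6)
  expect_length(unique(attr(cv, "folds")), 20L)   # one fold per sample
  ## leakage check: out-of-fold predictions differ from resubstitution fit
  set.seed(8)
  Xn <- matrix(stats::rnorm(15 * 5), 15)
  yn <- stats::rnorm(15)
  cvn <- cross_validate(Xn, yn, 2, "loo")
  fitted_all <- pls_fit(Xn, yn, 2)$fitted
  expect_gt(max(abs(attr(cvn, "predictions") - fitted_all)), 1e-6)
  ## duplicating a sample changes the loo score measurably
  cvdup <- cross_validate(rbind(Xn, Xn[1, ]), c(yn, yn[1]), 2, "loo")
  expect_gt(abs(as.numeric(cvdup) - as.numeric(cvn)), 1e-8)
  ## k-fold is deterministic given the seed and close to loo on easy data
  Xe <- orthogonal_X(30, 4, seed = 5)
  ye <- Xe[, 1] + with_seed_local(55, stats::rnorm(30, 0, 0.05))
  k1 <- cross_validate(Xe, ye, 1, "kfold", k = 5, seed = 2)
  k2 <- cross_validate(Xe, ye, 1, "kfold", k = 5, seed = 2)
  expect_identical(as.numeric(k1), as.numeric(k2))
  l <- cross_validate(Xe, ye, 1, "loo")
  expect_lt(abs(as.numeric(k1) - as.numeric(l)) / as.numeric(l), 0.5)
})

test_that("the fast factor scan reproduces direct cross-validation", {
  set.seed(6)
  X <- matrix(stats::rnorm(25 * 12), 25)
  y <- as.numeric(X[, 1:3] %*% c(1, -1, 2)) + stats::rnorm(25, 0, 0.3)
  ch <- choose_factors(X, y, A_max = 6, scheme = "loo")
  for (A in c(1L, 3L, 6L))
    expect_equal(ch$rmsecv[A],
                 as.numeric(cross_validate(X, y, A, "loo")),
                 tolerance = 1e-12)
  expect_equal(ch$A, which.min(ch$rmsecv))
})

test_that("error metrics follow the printed formulas exactly", {
  expect_equal(rmsecv(c(1, 2, 3), c(0, 3, 3)), 1)        # residuals 1,-1,0
  expect_equal(rmsecv(1:5, 1:5), 0)
  m <- 7; cst <- 0.3                                      # constant residual
  expect_equal(rmsecv(rep(0, m), rep(-cst, m)),
               cst * sqrt(m / (m - 1)))
  expect_error(rmsecv(1, 1), "m >= 2")
  expect_identical(rmsep, rmsecv)

  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(r_squared(1:4, 1:4), 1)
  expect_equal(r_squared(1:4, rep(2.5, 4)), 0)
  expect_lt(r_squared(1:4, c(9, 9, 9, 9)), 0)             # can be negative
  expect_error(r_squared(rep(1, 3), 1:3), "variance")

  expect_equal(lod(0, 2), 0)
  expect_equal(lod(1, 3.3), 1)
  expect_equal(lod(0.5, 5), 0.33)
  expect_equal(lod(1, -2), lod(1, 2))                     # |slope|
  expect_error(lod(1, 0), "zero")
})

test_that("baseline standard deviation estimates and guards", {
  wl <- seq(751.9, 774.86, length.out = 512)
  flat <- rep(3, 512)
  expect_equal(baseline_sd(wl, flat, c(755, 760)), 0)
  noisy <- with_seed_local(10, stats::rnorm(512))
  est <- baseline_sd(wl, noisy, c(752, 761))   # ~200 grid points
  expect_gt(est, 0.85); expect_lt(est, 1.15)
  expect_error(baseline_sd(wl, noisy, c(766.2, 766.9),
                           peak_windows = list(c(766.07, 767.07))),
               "overlaps")
  expect_error(baseline_sd(wl, noisy, c(900, 901)), "grid point")
})

test_that("peak height reads the windowed maximum robustly", {
  wl <- seq(751.9, 774.86, length.out = 512)
  amp <- 40
  lor <- function(center) amp * line_profile(wl - center, 0.25)
  expect_equal(peak_height(wl, lor(766.57), 766.57), amp, tolerance = 0.04)
  ## small shift: the windowed max moves only by profile curvature
  h0 <- peak_height(wl, lor(766.57), 766.57)
  h1 <- peak_height(wl, lor(766.62), 766.57)
  expect_lt(abs(h1 - h0) / h0, 0.05)
  expect_equal(peak_height(wl, numeric(512), 766.57), 0)
  expect_error(peak_height(wl, lor(766.57), 900), "no grid points")
})

test_that("peak area integrates with optional baseline subtraction", {
  wl <- seq(0, 10, by = 0.01)
  rect <- as.numeric(wl >= 4.5 & wl <= 5.5)
  expect_equal(peak_area(wl, rect, 5, half_width = 0.5), 1,
               tolerance = 0.02)
  expect_equal(peak_area(wl, numeric(length(wl)), 5, 0.5), 0)
  ## Lorentzian over +/- 5 FWHM against the closed-form partial integral
  w <- 0.4; A <- 3
  lor <- A * line_profile(wl - 5, w)
  got <- peak_area(wl, lor, 5, half_width = 5 * w)
  want <- A * w * atan(10)            # int of A/(1+(2x/w)^2) over +/-5w
  expect_equal(got, want, tolerance = 0.02)
  ## linear-endpoint baseline removes an added ramp; the chord also sits on
  ## the Lorentzian tails, so the expected value is the area above the chord
  ramp <- 2 + 0.3 * wl
  got2 <- peak_area(wl, lor + ramp, 5, half_width = 5 * w,
                    baseline = "linear_endpoints")
  want2 <- want - 10 * w * A * line_profile(5 * w, w)
  expect_equal(got2, want2, tolerance = 0.02)
  ## overlapping windows merge instead of double-counting
  both <- peak_area(wl, rect, c(4.9, 5.1), half_width = 0.5)
  expect_equal(both, 1, tolerance = 0.03)
})

test_that("univariate calibration line and its guards", {
  u <- univariate_fit(c(1, 2, 3), c(1, 2, 2))
  expect_equal(u$slope, 0.5)
  expect_equal(u$r_squared, 0.75)
  expect_equal(univariate_fit(1:5, 2 * (1:5) + 3)$r_squared, 1)
  expect_lt(abs(univariate_fit(1:5, rep(2, 5))$slope), 1e-12)
  expect_error(univariate_fit(rep(1, 4), 1:4), "degenerate")
  expect_error(univariate_fit(1:2, 1:2), ">= 3")
  expect_equal(predict(u, 2), u$intercept + 2 * u$slope)
})

test_that("peak shift degrades univariate calibration at equal noise", {
  ## a tight reading window makes the fixed-position height reading
  ## sensitive to uncontrolled shift, as with a raw fixed-pixel readout
  r2_at_shift <- function(shift_sd) {
    mean(vapply(1:10, function(s) {
      cfg <- sim_config(shift_sd = shift_sd, broadening_sd = 0,
                        energy_sd = 0, noise_sd = 2, n_matrix_lines = 0)
      ds <- simulate_dataset(40, cfg, seed = 100 + s)
      f <- apply(ds$intensities, 1, function(v)
        peak_height(ds$wavelengths, v, 766.57, half_width = 0.1))
      univariate_fit(f, ds$concentrations)$r_squared
    }, numeric(1)))
  }
  expect_lt(r2_at_shift(0.1), r2_at_shift(0))
})
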