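test_that("line profiles have unit amplitude and half-maximum geometry", {
  for (kind in c("lorentzian", "gaussian")) {
    expect_equal(line_profile(0, 0.3, kind), 1)
    expect_equal(line_profile(0.15, 0.3, kind), 0.5)
    expect_equal(line_profile(-0.15, 0.3, kind), 0.5)
  }
  ## closed-form Lorentzian integral: pi * fwhm / 2
  x <- seq(-50 * 0.3, 50 * 0.3, by = 0.001)
  got <- sum(line_profile(x, 0.3)) * 0.001
  expect_equal(got, pi * 0.3 / 2, tolerance = 0.02)
  expect_error(line_profile(0, -1), "fwhm")
})

test_that("degenerate configurations produce exact spectra", {
  cfg <- easy_config(baseline = 0, baseline_slope = 0,
                     interferents = data.frame(center = numeric(0),
                                               amplitude = numeric(0),
                                               fwhm = numeric(0)))
  sp <- with_seed_local(1, simulate_spectrum(0, cfg))
  expect_equal(max(abs(sp$intensities)), 0)
  ## no randomness, no saturation: windowed height exactly proportional to c
  h <- function(conc) {
    s <- with_seed_local(1, simulate_spectrum(conc, cfg))
    peak_height(s$wavelengths, s$intensities[1, ], 766.57)
  }
  expect_equal(h(0.8) / h(0.4), 2, tolerance = 1e-9)
  ## with self-absorption the response is concave
  cfg_sat <- easy_config(baseline = 0, self_absorption = 0.8)
  hs <- function(conc) {
    s <- with_seed_local(1, simulate_spectrum(conc, cfg_sat))
    peak_height(s$wavelengths, s$intensities[1, ], 766.57)
  }
  expect_lt(hs(0.8) / hs(0.4), 2)
})

test_that("datasets have the study's shape and are seed-reproducible", {
  ds <- simulate_dataset(90, sim_config(), seed = 42)
  expect_equal(dim(ds), c(90L, 512L))
  expect_true(all(ds$concentrations >= 0.415 & ds$concentrations <= 0.815))
  expect_equal(range(ds$wavelengths), c(751.90, 774.86))
  ds2 <- simulate_dataset(90, sim_config(), seed = 42)
  expect_identical(ds$intensities, ds2$intensities)
  expect_identical(ds$concentrations, ds2$concentrations)
  expect_false(identical(
    ds$intensities, simulate_dataset(90, sim_config(), seed = 43)$intensities))
  ## minor matrix lines respect the guard zone around the analyte doublet
  ml <- attr(ds, "matrix_lines")
  expect_equal(nrow(ml), 120L)
  expect_true(all(abs(ml$center - 766.57) > 2.0))
  expect_true(all(abs(ml$center - 769.95) > 2.0))
})

test_that("noiseless linear regime recovers concentration univariately", {
  cfg <- easy_config()
  ds <- simulate_dataset(30, cfg, seed = 7)
  f <- apply(ds$intensities, 1, function(v)
    peak_height(ds$wavelengths, v, 766.57))
  expect_gt(univariate_fit(f, ds$concentrations)$r_squared, 0.999)
})

test_that("univariate quality degrades monotonically with peak shift", {
  r2_at <- function(shift_sd) {
    mean(vapply(1:10, function(s) {
      cfg <- sim_config(shift_sd = shift_sd, broadening_sd = 0,
                        energy_sd = 0, noise_sd = 2, n_matrix_lines = 0)
      ds <- simulate_dataset(40, cfg, seed = 700 + s)
      f <- apply(ds$intensities, 1, function(v)
        peak_height(ds$wavelengths, v, 766.57, half_width = 0.1))
      univariate_fit(f, ds$concentrations)$r_squared
    }, numeric(1)))
  }
  r2 <- vapply(c(0, 0.02, 0.05, 0.1), r2_at, numeric(1))
  expect_true(all(diff(r2) <= 1e-6))
})

test_that("the stressed regime favors the wavelet pipeline over univariate", {
  ds <- simulate_dataset(90, sim_config(), seed = 314)
  sp <- split_dataset(ds, 65, seed = 315)
  cfg <- ddlibs_config(B = 8L, rfa = test_rfa(800), seed = 316)
  model <- ddlibs_train(sp$first, cfg)
  pred <- ddlibs_predict(model, sp$second)
  r2_dd <- r_squared(sp$second$concentrations, pred)
  ncal <- normalize_spectra(sp$first, "mean")
  nval <- normalize_spectra(sp$second, "mean")
  f <- function(d) apply(d$intensities, 1, function(v)
    peak_height(d$wavelengths, v, 766.57))
  uni <- univariate_fit(f(ncal), ncal$concentrations)
  r2_uni <- r_squared(nval$concentrations, predict(uni, f(nval)))
  expect_gt(r2_dd, r2_uni)
})
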