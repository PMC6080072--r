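test_that("filter banks load, verify, and reject unknown names", {
  for (K in 1:4) {
    fb <- load_filterbank(paste0("bi", K))
    expect_s3_class(fb, "hdwt_filterbank")
    expect_equal(fb$vanishing_moments, K)
    rep <- verify_filterbank(fb)
    expect_true(rep$pass)
    expect_lt(rep$pr_residual, 1e-8)
    expect_lt(max(abs(rep$moment_sums)), 1e-8)
  }
  expect_error(load_filterbank("bi9"), "unknown filter bank")
  ## a perturbed tap must be caught numerically
  bad <- load_filterbank("bi4")
  bad$h0[3] <- bad$h0[3] + 0.1
  expect_false(verify_filterbank(bad)$pass)
  expect_gt(verify_filterbank(bad)$pr_residual, 1e-4)
})

test_that("perfect reconstruction holds across banks, scales and boundaries", {
  set.seed(42)
  for (K in 1:4) {
    fb <- load_filterbank(paste0("bi", K))
    for (bd in c("zero", "periodic", "symmetric")) {
      for (n in c(160, 320)) {
        J <- if (bd == "periodic") 4L else sample(2:4, 1L)
        x <- stats::rnorm(n); x <- x / max(abs(x))
        cf <- hdwt_forward(x, fb, J, bd)
        expect_lt(max(abs(hdwt_inverse(cf, fb) - x)), 1e-8)
      }
    }
  }
})

test_that("the coefficient count law holds", {
  fb <- load_filterbank("bi4")
  x <- with_seed_local(1, stats::rnorm(512))
  expect_equal(length(hdwt_forward(x, fb, 4L, "zero")), 1520L)
  expect_equal(length(hdwt_forward(x, fb, 4L, "periodic")), 1472L)
  ## approximately 3x oversampling for deep decompositions
  for (K in c(1L, 4L)) {
    fbk <- load_filterbank(paste0("bi", K))
    tot <- length(hdwt_forward(stats::rnorm(1024), fbk, 4L, "periodic"))
    expect_equal(tot / 1024, 2.875, tolerance = 1e-9)  # 3(1-2^-J)+2^-J
  }
})

test_that("the transform is linear and maps zero to zero", {
  fb <- load_filterbank("bi3")
  set.seed(3)
  x <- stats::rnorm(200); y <- stats::rnorm(200)
  fx <- hdwt_flatten(hdwt_forward(x, fb, 3))$values
  fy <- hdwt_flatten(hdwt_forward(y, fb, 3))$values
  fxy <- hdwt_flatten(hdwt_forward(2 * x - 5 * y, fb, 3))$values
  expect_equal(fxy, 2 * fx - 5 * fy, tolerance = 1e-10)
  z <- hdwt_forward(numeric(200), fb, 3)
  expect_equal(max(abs(hdwt_flatten(z)$values)), 0)
  expect_equal(max(abs(hdwt_inverse(z, fb))), 0)
})

test_that("flatten/unflatten is a bijection with the frozen ordering", {
  fb <- load_filterbank("bi4")
  cf <- hdwt_forward(with_seed_local(2, stats::rnorm(256)), fb, 3)
  fl <- hdwt_flatten(cf)
  expect_equal(nrow(fl$index_map), length(fl$values))
  expect_identical(fl$index_map$flat, seq_along(fl$values))
  ## flat index 1 is (scale 1, decimated detail, offset 1)
  expect_equal(fl$index_map$scale[1], 1)
  expect_equal(fl$index_map$band[1], "detail_dec")
  expect_equal(fl$index_map$offset[1], 1)
  ## scale 1 decimated, then scale 1 undecimated, ..., approximation last
  expect_identical(unique(fl$index_map$band[fl$index_map$scale == 1]),
                   c("detail_dec", "detail_undec"))
  expect_equal(fl$index_map$band[nrow(fl$index_map)], "approx")
  back <- hdwt_unflatten(fl$values, cf)
  expect_equal(back$subbands, cf$subbands)
  expect_error(hdwt_unflatten(fl$values[-1], cf), "expected")
})

test_that("partial reconstruction behaves at its extremes", {
  fb <- load_filterbank("bi4")
  x <- with_seed_local(4, stats::rnorm(256))
  cf <- hdwt_forward(x, fb, 3)
  expect_lt(max(abs(reconstruct_from_selected(cf, seq_len(length(cf))) - x)),
            1e-8)
  expect_equal(max(abs(reconstruct_from_selected(cf, integer(0)))), 0)
  expect_error(reconstruct_from_selected(cf, length(cf) + 1L), "1\\.\\.")
  ## one selected coefficient reconstructs a single synthesis atom,
  ## localized near that coefficient's position
  one <- reconstruct_from_selected(cf, 500L)
  expect_equal(length(one), 256L)
  expect_gt(max(abs(one)), 0)
})

test_that("guards: short signals, bad lengths, wrong bank", {
  fb <- load_filterbank("bi4")
  expect_error(hdwt_forward(stats::rnorm(64), fb, 4), "too short")
  expect_error(hdwt_forward(c(1, NA, 3, rep(1, 200)), fb, 1),
               "non-finite")
  expect_error(hdwt_forward(stats::rnorm(300), fb, 3, "periodic"),
               "divisible")
  cf <- hdwt_forward(stats::rnorm(256), fb, 2)
  expect_error(hdwt_inverse(cf, load_filterbank("bi2")), "produced with")
})

test_that("HDWT is nearer shift-invariance than the critically sampled reference", {
  fb <- load_filterbank("bi4")
  set.seed(9)
  wins <- 0L
  for (i in 1:20) {
    n <- 256
    x <- stats::rnorm(n, 0, 0.05)
    for (p in 1:3) {
      c0 <- stats::runif(1, 30, n - 30); w <- stats::runif(1, 2, 8)
      x <- x + stats::runif(1, 0.5, 2) / (1 + ((seq_len(n) - c0) / w)^2)
    }
    xs <- c(x[n], x[-n])
    dh <- magnitude_profile_change(hdwt_forward(x, fb, 3, "periodic"),
                                   hdwt_forward(xs, fb, 3, "periodic"))
    dd <- magnitude_profile_change(dwt_forward(x, 4, 3),
                                   dwt_forward(xs, 4, 3))
    wins <- wins + (dh < dd)
  }
  expect_gte(wins, 18L)
})

test_that("the reference transform is orthonormal (energy-preserving)", {
  x <- with_seed_local(5, stats::rnorm(256))
  d <- dwt_forward(x, 4, 3)
  expect_equal(sum(subband_energies(d)), sum(x^2), tolerance = 1e-10)
  f <- orthonormal_filters(4)
  expect_equal(sum(f$h0^2), 1, tolerance = 1e-10)
  expect_equal(sum(f$h0 * f$h1), 0, tolerance = 1e-10)
  expect_equal(sum(f$h0), sqrt(2), tolerance = 1e-10)
})

test_that("coefficient matrix and table views are consistent", {
  ds <- simulate_dataset(5, easy_config(), seed = 2)
  fb <- load_filterbank("bi4")
  cm <- hdwt_coef_matrix(ds, fb, 4)
  expect_equal(dim(cm$X), c(5L, 1520L))
  expect_equal(cm$X[1, ],
               hdwt_flatten(hdwt_forward(ds$intensities[1, ], fb, 4))$values)
  tab <- hdwt_as_table(cm$template)
  expect_named(tab, c("flat", "scale", "band", "offset", "value"))
  expect_equal(nrow(tab), 1520L)
})
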