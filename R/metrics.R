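## Figures of merit and univariate peak calibration.

#' Root mean square error, m - 1 denominator
#'
#' `sqrt(sum((actual - predicted)^2) / (m - 1))`.  The source convention this
#' package reproduces divides by `m - 1` rather than `m`, for both
#' cross-validation (RMSECV) and external prediction (RMSEP); [rmsep()] is
#' the same computation applied to a prediction set.
#'
#' @param actual,predicted numeric vectors of equal length `m >= 2`.
#' @return non-negative scalar.
#' @export
rmsecv <- function(actual, predicted) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  m <- length(actual)
  if (length(predicted) != m) stop("length mismatch")
  if (m < 2L) stop("need m >= 2 (the m - 1 denominator)")
  sqrt(sum((actual - predicted)^2) / (m - 1))
}

#' @rdname rmsecv
#' @export
rmsep <- rmsecv

#' Coefficient of determination
#'
#' `1 - SSE/SST` about the mean of `actual`; can be negative for models worse
#' than the mean predictor.
#'
#' @param actual,predicted numeric vectors of equal length.
#' @return scalar `<= 1`.
#' @export
r_squared <- function(actual, predicted) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  if (length(actual) != length(predicted)) stop("length mismatch")
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("zero variance in actual values")
  1 - sum((actual - predicted)^2) / sst
}

#' Limit of detection
#'
#' `3.3 * sd_blank / |slope|`: the baseline standard deviation near the
#' analyte peaks over the calibration-curve slope.
#'
#' @param sd_blank non-negative baseline standard deviation.
#' @param slope nonzero calibration slope.
#' @return limit of detection in concentration units.
#' @export
lod <- function(sd_blank, slope) {
  if (sd_blank < 0) stop("sd_blank must be >= 0")
  if (slope == 0) stop("zero calibration slope")
  3.3 * sd_blank / abs(slope)
}

#' Baseline standard deviation
#'
#' Sample standard deviation of the intensities in a peak-free wavelength
#' window; the `SD_blank` input of [lod()].
#'
#' @param wavelengths,intensities the spectrum.
#' @param window `c(lo, hi)` in nm; must contain at least two grid points.
#' @param peak_windows optional list of `c(lo, hi)` windows that the baseline
#'   window must not overlap (guard against including an analyte peak).
#' @return the standard deviation.
#' @export
baseline_sd <- function(wavelengths, intensities, window,
                        peak_windows = NULL) {
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("window must be c(lo, hi) with lo < hi")
  for (pw in peak_windows)
    if (window[1L] <= pw[2L] && pw[1L] <= window[2L])
      stop(sprintf("baseline window [%g, %g] overlaps peak window [%g, %g]",
                   window[1L], window[2L], pw[1L], pw[2L]))
  sel <- wavelengths >= window[1L] & wavelengths <= window[2L]
  if (sum(sel) < 2L)
    stop(sprintf("baseline window [%g, %g] contains %d grid point(s), need >= 2",
                 window[1L], window[2L], sum(sel)))
  stats::sd(intensities[sel])
}

#' Peak height
#'
#' Maximum intensity within `center +/- half_width` nm.  The windowed
#' maximum (rather than the value at the nominal center pixel) is robust to
#' the small uncontrolled peak shifts typical of LIBS.
#'
#' @param wavelengths,intensities the spectrum.
#' @param center nominal line position, nm.
#' @param half_width window half-width, nm (default 0.5).
#' @return the peak height.
#' @export
peak_height <- function(wavelengths, intensities, center, half_width = 0.5) {
  sel <- wavelengths >= center - half_width & wavelengths <= center + half_width
  if (!any(sel))
    stop(sprintf("window %.3f +/- %.3f nm contains no grid points",
                 center, half_width))
  max(intensities[sel])
}

#' Peak area
#'
#' Trapezoidal integral of the intensity over one or more peak windows
#' (overlapping windows are merged), optionally above a baseline linearly
#' interpolated between each window's endpoints.
#'
#' @param wavelengths,intensities the spectrum.
#' @param centers numeric vector of line positions, nm.
#' @param half_width window half-width, nm.
#' @param baseline `"none"` (default) or `"linear_endpoints"`.
#' @return total area (intensity x nm).
#' @export
peak_area <- function(wavelengths, intensities, centers, half_width = 0.5,
                      baseline = c("none", "linear_endpoints")) {
  baseline <- match.arg(baseline)
  win <- cbind(centers - half_width, centers + half_width)
  win <- win[order(win[, 1L]), , drop = FALSE]
  merged <- list(win[1L, ])
  for (i in seq_len(nrow(win))[-1L]) {
    last <- merged[[length(merged)]]
    if (win[i, 1L] <= last[2L])
      merged[[length(merged)]] <- c(last[1L], max(last[2L], win[i, 2L]))
    else merged[[length(merged) + 1L]] <- win[i, ]
  }
  total <- 0
  for (w in merged) {
    sel <- which(wavelengths >= w[1L] & wavelengths <= w[2L])
    if (length(sel) < 2L)
      stop(sprintf("window [%g, %g] nm contains fewer than 2 grid points",
                   w[1L], w[2L]))
    x <- wavelengths[sel]; y <- intensities[sel]
    if (baseline == "linear_endpoints") {
      y <- y - (y[1L] + (y[length(y)] - y[1L]) *
                  (x - x[1L]) / (x[length(x)] - x[1L]))
    }
    total <- total + trapz(x, y)
  }
  total
}

#' Univariate calibration line
#'
#' Ordinary least-squares line `y ~ feature` with slope, intercept and the
#' coefficient of determination of the fit.  In the calibration harness the
#' response is the analyte concentration and the feature a peak height or
#' area, so the fitted line predicts concentration directly.
#'
#' @param features numeric vector (peak heights or areas), not all equal.
#' @param y numeric response (concentrations), `length >= 3`.
#' @return object of class `univariate_model` with `slope`, `intercept`,
#'   `r_squared`.
#' @export
univariate_fit <- function(features, y) {
  features <- as.numeric(features); y <- as.numeric(y)
  n <- length(features)
  if (n < 3L || length(y) != n) stop("need >= 3 paired points")
  if (diff(range(features)) == 0) stop("degenerate features (all equal)")
  sxx <- sum((features - mean(features))^2)
  slope <- sum((features - mean(features)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(features)
  fitted <- intercept + slope * features
  structure(list(slope = slope, intercept = intercept,
                 r_squared = if (diff(range(y)) == 0) 0
                             else r_squared(y, fitted),
                 fitted = fitted, n = n),
            class = "univariate_model")
}

#' @export
print.univariate_model <- function(x, ...) {
  cat(sprintf("<univariate_model> slope %.4g, intercept %.4g, R^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
predict.univariate_model <- function(object, features, ...)
  object$intercept + object$slope * as.numeric(features)
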