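## End-to-end calibration pipeline and the method-comparison harness.
##
## Pipeline order (frozen): normalize -> wavelet transform -> bagged
## random-frog selection -> PLS on the selected coefficient(s).
## Normalization precedes region extraction and the transform, since
## reference-line normalization may need spectral range outside the analysis
## window.

default_pipeline_config <- function() {
  list(normalization = "mean",
       reference_wavelength = 247.86,
       filter = "bi4",
       J = 4L,
       boundary = "zero",
       k_select = 1L,
       A_select = 2L,          # factors inside the random-frog search
       A_max = 15L,            # cap for factor choice of plain PLS
       B = 1000L,
       train_fraction = 0.7,
       rfa = rfa_params(),
       seed = 1L)
}

#' Assemble a pipeline configuration
#'
#' Starts from the package defaults (mean normalization, `bi4` bank, scale 4,
#' zero boundary, single selected coefficient, 1,000 bagged runs) and
#' overrides the named fields.
#'
#' @param ... named overrides of the default fields.
#' @return a configuration list.
#' @export
ddlibs_config <- function(...) {
  cfg <- default_pipeline_config()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Choose the decomposition scale by minimum RMSECV
#'
#' For each candidate scale, transforms all calibration spectra, fits PLS on
#' the full coefficient matrix, and scores leave-one-out RMSECV; returns the
#' scale with the smallest value (ties to the smaller scale).
#'
#' @param cal calibration [spectra_dataset()] with concentrations.
#' @param fb filter bank.
#' @param scales candidate scale vector.
#' @param A PLS factors used for the scan.
#' @param boundary boundary mode.
#' @return list with `scale` and the per-candidate `rmsecv`.
#' @export
choose_scale <- function(cal, fb, scales = 1:6, A = 5L, boundary = "zero") {
  stopifnot(inherits(cal, "spectra_dataset"))
  if (!length(scales)) stop("empty candidate scale list")
  if (is.null(cal$concentrations)) stop("calibration set needs concentrations")
  errs <- vapply(scales, function(J) {
    cm <- hdwt_coef_matrix(cal, fb, J, boundary)
    Af <- min(A, nrow(cm$X) - 2L, ncol(cm$X))
    as.numeric(cross_validate(cm$X, cal$concentrations, Af, "loo"))
  }, numeric(1L))
  list(scale = scales[which.min(errs)],
       rmsecv = stats::setNames(errs, paste0("J", scales)))
}

#' Train the full data-driven calibration model
#'
#' Normalizes the calibration spectra, transforms each to wavelet
#' coefficients, runs the bagged random-frog selection over the coefficient
#' matrix, keeps the top `k_select` coefficients (default 1), and fits a PLS
#' model on them with `A = min(k_select, ...)` factors (one factor when a
#' single coefficient is selected).  Fully reproducible from `config$seed`.
#'
#' @param cal calibration [spectra_dataset()] with concentrations.
#' @param config a [ddlibs_config()] list.
#' @return object of class `ddlibs_model`.
#' @export
ddlibs_train <- function(cal, config = ddlibs_config()) {
  stopifnot(inherits(cal, "spectra_dataset"))
  if (is.null(cal$concentrations))
    stop("calibration set needs concentrations")
  norm <- normalize_spectra(cal, config$normalization,
                            config$reference_wavelength)
  fb <- load_filterbank(config$filter)
  cm <- hdwt_coef_matrix(norm, fb, config$J, config$boundary)
  sel <- mrfa(cm$X, norm$concentrations, A = config$A_select,
              B = config$B, train_fraction = config$train_fraction,
              params = config$rfa, seed = child_seed(config$seed, 101L))
  keep <- select_top(sel, config$k_select)
  A_fit <- min(length(keep), nrow(cm$X) - 1L)
  fit <- pls_fit(cm$X[, keep, drop = FALSE], norm$concentrations, A_fit)
  train_r2 <- r_squared(norm$concentrations, fit$fitted)
  structure(list(config = config,
                 wavelengths = cal$wavelengths,
                 selected = keep,
                 selection = sel,
                 index_map = cm$index_map,
                 pls = fit,
                 n_factors = fit$n_factors,
                 train_r2 = train_r2,
                 train_rmse = fit$train_rmse),
            class = "ddlibs_model")
}

#' @export
print.ddlibs_model <- function(x, ...) {
  im <- x$index_map[match(x$selected, x$index_map$flat), ]
  cat(sprintf("<ddlibs_model> %s J=%d, %d coefficient(s) selected (scale %s, %s), %d PLS factor(s); training R^2 %.3f\n",
              x$config$filter, x$config$J, length(x$selected),
              paste(im$scale, collapse = ","),
              paste(im$band, collapse = ","),
              x$n_factors, x$train_r2))
  invisible(x)
}

#' Predict concentrations with a trained model
#'
#' Applies the stored normalization, transform and coefficient selection,
#' then the PLS map.  The new dataset must share the training wavelength
#' grid (within 1e-9 nm).
#'
#' @param model a `ddlibs_model`.
#' @param ds a [spectra_dataset()].
#' @return numeric vector of predicted concentrations (g/100 g).
#' @export
ddlibs_predict <- function(model, ds) {
  stopifnot(inherits(model, "ddlibs_model"), inherits(ds, "spectra_dataset"))
  if (length(ds$wavelengths) != length(model$wavelengths) ||
      max(abs(ds$wavelengths - model$wavelengths)) > 1e-9)
    stop("wavelength grid differs from the training grid")
  cfg <- model$config
  norm <- normalize_spectra(ds, cfg$normalization, cfg$reference_wavelength)
  fb <- load_filterbank(cfg$filter)
  cm <- hdwt_coef_matrix(norm, fb, cfg$J, cfg$boundary)
  predict(model$pls, cm$X[, model$selected, drop = FALSE])
}

## ---------------------------------------------------------------- methods

rfa_threshold_vars <- function(freq) {
  ## retention rule for single-run frog + PLS: keep above-mean frequency
  keep <- which(freq > mean(freq))
  if (!length(keep)) keep <- which.max(freq)
  keep
}

#' Compare calibration methods on a common validation set
#'
#' Runs the seven-method harness: three univariate calibrations (height of
#' each potassium line, area of both), plain PLS on the raw variables, a
#' single random-frog selection on raw variables followed by PLS, the same
#' on wavelet coefficients, and the full bagged pipeline.  All methods see
#' the same normalization and are scored on the same validation set
#' (`r_squared` and `rmsep`).  Child seeds fan out from `config$seed` by a
#' fixed counter scheme, so adding a method does not perturb the others.
#'
#' @param cal,val calibration and validation [spectra_dataset()]s on one
#'   grid; `cal` needs concentrations.
#' @param config a [ddlibs_config()] list.
#' @param methods subset of the seven method names to run.
#' @return a `data.frame` (class `comparison_report`): one row per method
#'   with `method, n_factors, r_squared, rmsep`.
#' @export
compare_methods <- function(cal, val, config = ddlibs_config(),
                            methods = c("univariate_peak1", "univariate_peak2",
                                        "univariate_area", "pls_raw",
                                        "rfa_pls", "hdwt_rfa_pls", "ddlibs")) {
  stopifnot(inherits(cal, "spectra_dataset"), inherits(val, "spectra_dataset"))
  if (max(abs(cal$wavelengths - val$wavelengths)) > 1e-9)
    stop("calibration and validation sets must share one grid")
  if (is.null(cal$concentrations)) stop("calibration set needs concentrations")
  if (is.null(val$concentrations)) stop("validation set needs concentrations")
  methods <- match.arg(methods, several.ok = TRUE)
  ncal <- normalize_spectra(cal, config$normalization,
                            config$reference_wavelength)
  nval <- normalize_spectra(val, config$normalization,
                            config$reference_wavelength)
  ycal <- ncal$concentrations; yval <- nval$concentrations
  peaks <- c(766.57, 769.95)
  rows <- list()
  add_row <- function(method, n_factors, pred) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method,
      n_factors = if (is.null(n_factors)) NA_integer_ else
        as.integer(n_factors),
      r_squared = r_squared(yval, pred),
      rmsep = rmsep(yval, pred))
  }
  uni_feature <- function(ds, mode) {
    apply(ds$intensities, 1L, function(v) switch(mode,
      peak1 = peak_height(ds$wavelengths, v, peaks[1L]),
      peak2 = peak_height(ds$wavelengths, v, peaks[2L]),
      area = peak_area(ds$wavelengths, v, peaks)))
  }
  for (m in methods) {
    if (m %in% c("univariate_peak1", "univariate_peak2", "univariate_area")) {
      mode <- sub("univariate_", "", m)
      mode <- if (mode == "area") "area" else mode
      fit <- univariate_fit(uni_feature(ncal, mode), ycal)
      add_row(m, NULL, predict(fit, uni_feature(nval, mode)))
    } else if (m == "pls_raw") {
      ch <- choose_factors(ncal$intensities, ycal, config$A_max, "loo")
      fit <- pls_fit(ncal$intensities, ycal, ch$A)
      add_row(m, ch$A, predict(fit, nval$intensities))
    } else if (m == "rfa_pls") {
      freq <- rfa_run(ncal$intensities, ycal, A = config$A_select,
                      params = config$rfa,
                      seed = child_seed(config$seed, 201L))
      keep <- rfa_threshold_vars(freq)
      ch <- choose_factors(ncal$intensities[, keep, drop = FALSE], ycal,
                           config$A_max, "loo")
      fit <- pls_fit(ncal$intensities[, keep, drop = FALSE], ycal, ch$A)
      add_row(m, ch$A, predict(fit, nval$intensities[, keep, drop = FALSE]))
    } else if (m == "hdwt_rfa_pls") {
      fb <- load_filterbank(config$filter)
      cmc <- hdwt_coef_matrix(ncal, fb, config$J, config$boundary)
      cmv <- hdwt_coef_matrix(nval, fb, config$J, config$boundary)
      freq <- rfa_run(cmc$X, ycal, A = config$A_select, params = config$rfa,
                      seed = child_seed(config$seed, 301L))
      keep <- rfa_threshold_vars(freq)
      ch <- choose_factors(cmc$X[, keep, drop = FALSE], ycal,
                           config$A_max, "loo")
      fit <- pls_fit(cmc$X[, keep, drop = FALSE], ycal, ch$A)
      add_row(m, ch$A, predict(fit, cmv$X[, keep, drop = FALSE]))
    } else if (m == "ddlibs") {
      model <- ddlibs_train(cal, config)
      add_row(m, model$n_factors, ddlibs_predict(model, val))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", class(out))
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("method comparison (validation set):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare normalization schemes
#'
#' Fits one PLS model per normalization method on the calibration set
#' (factors by leave-one-out RMSECV) and scores RMSEP on the validation set.
#' Duplicate requested methods are deduplicated with a warning.
#'
#' @param cal,val datasets as in [compare_methods()].
#' @param methods normalization names; default all five.
#' @param reference_wavelength line for `reference_line` normalization, nm.
#' @param A_max factor-search cap.
#' @return data frame `method, n_factors, rmsep`, plus attribute `best`
#'   (argmin method).
#' @export
compare_normalizations <- function(cal, val,
                                   methods = c("mean", "vector_norm", "area",
                                               "height", "reference_line"),
                                   reference_wavelength = 247.86,
                                   A_max = 15L) {
  if (anyDuplicated(methods)) {
    warning("duplicate normalization method(s) requested; deduplicated")
    methods <- unique(methods)
  }
  rows <- lapply(methods, function(m) {
    ncal <- normalize_spectra(cal, m, reference_wavelength)
    nval <- normalize_spectra(val, m, reference_wavelength)
    ch <- choose_factors(ncal$intensities, ncal$concentrations, A_max, "loo")
    fit <- pls_fit(ncal$intensities, ncal$concentrations, ch$A)
    data.frame(method = m, n_factors = ch$A,
               rmsep = rmsep(nval$concentrations,
                             predict(fit, nval$intensities)))
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$method[which.min(out$rmsep)]
  out
}

## ------------------------------------------------------------ persistence

#' Save / load a trained model
#'
#' JSON persistence (full double precision); a reloaded model produces
#' bit-identical predictions.
#'
#' @param model a `ddlibs_model`.
#' @param path file path.
#' @return `save_ddlibs_model` returns the path invisibly;
#'   `load_ddlibs_model` returns the model.
#' @export
save_ddlibs_model <- function(model, path) {
  stopifnot(inherits(model, "ddlibs_model"))
  cfg <- model$config
  cfg$rfa <- unclass(cfg$rfa)
  payload <- list(format = "ddlibs_model", format_version = 1L,
                  config = cfg,
                  wavelengths = model$wavelengths,
                  selected = model$selected,
                  index_map = model$index_map,
                  P = model$selection$P,
                  B = model$selection$B,
                  pls = list(n_factors = model$pls$n_factors,
                             ## hex float strings round-trip bit-exactly,
                             ## which decimal JSON numbers do not
                             coefficients_hex = sprintf("%a",
                                                        model$pls$coefficients),
                             intercept_hex = sprintf("%a",
                                                     model$pls$intercept)),
                  n_factors = model$n_factors,
                  train_r2 = model$train_r2,
                  train_rmse = model$train_rmse)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_ddlibs_model
#' @export
load_ddlibs_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ddlibs_model"))
    stop("not a ddlibs model file")
  cfg <- p$config
  cfg$rfa <- do.call(rfa_params, cfg$rfa)
  cfg$J <- as.integer(cfg$J)
  pls <- structure(list(n_factors = p$pls$n_factors,
                        coefficients = as.numeric(p$pls$coefficients_hex),
                        intercept = as.numeric(p$pls$intercept_hex)),
                   class = "pls_model")
  structure(list(config = cfg,
                 wavelengths = p$wavelengths,
                 selected = as.integer(p$selected),
                 selection = structure(list(P = p$P, B = p$B,
                                            selected = as.integer(p$selected)[1L]),
                                       class = "selection_result"),
                 index_map = as.data.frame(p$index_map),
                 pls = pls,
                 n_factors = p$n_factors,
                 train_r2 = p$train_r2,
                 train_rmse = p$train_rmse),
            class = "ddlibs_model")
}
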