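#' Spectral dataset container
#'
#' A `spectra_dataset` holds a set of emission spectra sharing one wavelength
#' axis: an `n_samples x n_wavelengths` intensity matrix, the axis in nm, the
#' sample identifiers, and (optionally) reference analyte concentrations in
#' g/100 g.  Concentrations are stored in g/100 g throughout the package; no
#' unit conversion is performed anywhere.
#'
#' @param wavelengths strictly increasing numeric vector (nm).
#' @param intensities numeric matrix, one row per sample, `length(wavelengths)`
#'   columns.  A single spectrum may be given as a plain vector.
#' @param concentrations optional numeric vector of reference concentrations
#'   (g/100 g), one per sample, all non-negative.  `NULL` for prediction-only
#'   sets.
#' @param sample_ids character labels; defaults to `s1, s2, ...`.
#' @return an object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(wavelengths, intensities,
                            concentrations = NULL, sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite and non-missing")
  if (is.null(dim(intensities)))
    intensities <- matrix(as.numeric(intensities), nrow = 1L)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(wavelengths))
    stop(sprintf("intensity matrix has %d columns but axis has %d wavelengths",
                 ncol(intensities), length(wavelengths)))
  if (anyNA(intensities))
    stop("intensities contain missing values")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    bad <- which(diff(wavelengths) <= 0)[1L]
    stop(sprintf("wavelength axis not strictly increasing at position %d (%g nm)",
                 bad + 1L, wavelengths[bad + 1L]))
  }
  n <- nrow(intensities)
  if (is.null(sample_ids))
    sample_ids <- if (n > 0L) paste0("s", seq_len(n)) else character(0)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("sample_ids length does not match number of spectra")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.null(concentrations)) {
    concentrations <- as.numeric(concentrations)
    if (length(concentrations) != n)
      stop("concentrations length does not match number of spectra")
    if (anyNA(concentrations) || any(concentrations < 0))
      stop("concentrations must be non-negative and non-missing")
  }
  structure(list(wavelengths = wavelengths,
                 intensities = intensities,
                 concentrations = concentrations,
                 sample_ids = sample_ids),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d sample(s) x %d wavelengths [%.2f, %.2f] nm\n",
              nrow(x$intensities), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$concentrations))
    cat(sprintf("  concentrations: %.3f-%.3f g/100 g\n",
                min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$intensities)

## row subset preserving order
subset_samples <- function(ds, idx) {
  spectra_dataset(ds$wavelengths,
                  ds$intensities[idx, , drop = FALSE],
                  if (!is.null(ds$concentrations)) ds$concentrations[idx],
                  ds$sample_ids[idx])
}

#' Extract a wavelength window
#'
#' Keeps exactly the columns whose wavelength lies in the closed interval
#' `[lo, hi]`.  Closed bounds reproduce the 512-variable analysis window
#' 751.90-774.86 nm when the grid endpoints equal the bounds.
#'
#' @param ds a [spectra_dataset()].
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return a `spectra_dataset` restricted to the window; concentrations are
#'   unchanged.
#' @export
extract_region <- function(ds, lo, hi) {
  stopifnot(inherits(ds, "spectra_dataset"))
  stop_if_not_scalar_number(lo, "lo"); stop_if_not_scalar_number(hi, "hi")
  if (!(lo < hi)) stop("lo must be < hi")
  keep <- ds$wavelengths >= lo & ds$wavelengths <= hi
  if (!any(keep))
    stop(sprintf("window [%g, %g] nm selects no wavelengths (axis spans [%g, %g] nm)",
                 lo, hi, min(ds$wavelengths), max(ds$wavelengths)))
  spectra_dataset(ds$wavelengths[keep],
                  ds$intensities[, keep, drop = FALSE],
                  ds$concentrations, ds$sample_ids)
}

#' Random calibration/validation split
#'
#' Randomly partitions the samples into a first set of `n_first` samples and a
#' second set with the remainder (e.g. the 65/25 calibration/validation split
#' used for a 90-sample study).  Sample order within each split follows the
#' parent dataset, so downstream cross-validation folds are reproducible.
#'
#' @param ds a [spectra_dataset()].
#' @param n_first number of samples in the first set, `0 < n_first < n`.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list with elements `first` and `second`.
#' @export
split_dataset <- function(ds, n_first, seed) {
  stopifnot(inherits(ds, "spectra_dataset"))
  n <- nrow(ds$intensities)
  if (!(n_first > 0 && n_first < n))
    stop(sprintf("n_first must be in (0, %d)", n))
  pick <- with_seed(seed, sort(sample.int(n, n_first)))
  list(first = subset_samples(ds, pick),
       second = subset_samples(ds, setdiff(seq_len(n), pick)))
}
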