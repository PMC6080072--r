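## Replicate averaging and per-spectrum normalization.

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate spectra acquired on identical
#' wavelength axes (e.g. 10 spots x 10 shots averaged into one spectrum per
#' sample).
#'
#' @param spectra list of `spectra_dataset` objects (each with one or more
#'   rows) or numeric vectors on a shared axis.
#' @param wavelengths required when `spectra` are plain vectors.
#' @return a single-row [spectra_dataset()].
#' @export
average_replicates <- function(spectra, wavelengths = NULL) {
  if (length(spectra) < 1L) stop("need at least one spectrum")
  if (inherits(spectra[[1L]], "spectra_dataset")) {
    wl <- spectra[[1L]]$wavelengths
    mats <- lapply(spectra, function(s) {
      if (!isTRUE(all.equal(s$wavelengths, wl, tolerance = 0)))
        stop("replicate wavelength axes differ")
      s$intensities
    })
    m <- do.call(rbind, mats)
  } else {
    if (is.null(wavelengths)) stop("wavelengths required for plain vectors")
    wl <- wavelengths
    lens <- lengths(spectra)
    if (any(lens != length(wl))) stop("replicate wavelength axes differ")
    m <- do.call(rbind, spectra)
  }
  spectra_dataset(wl, matrix(colMeans(m), nrow = 1L), sample_ids = "mean")
}

#' Spectrum normalization
#'
#' Divides each spectrum by a per-spectrum scalar.  The five schemes compared
#' for LIBS matrix-effect compensation:
#' \describe{
#'   \item{mean}{the spectrum's mean intensity ("average" normalization).}
#'   \item{vector_norm}{its Euclidean norm.}
#'   \item{area}{its trapezoidal integral over the wavelength axis (axes need
#'     not be uniform).}
#'   \item{height}{its maximum intensity.}
#'   \item{reference_line}{its intensity at a reference emission line
#'     (default: the C I line at 247.86 nm, so this scheme needs the
#'     full-range spectrum, not an extracted window).  The line is looked up
#'     at the nearest grid point within half the local grid step.}
#' }
#' All schemes are scale-invariant (degree-0 homogeneous) and, except
#' `reference_line` on pathological input, idempotent.
#'
#' @param ds a [spectra_dataset()].
#' @param method one of `"mean"`, `"vector_norm"`, `"area"`, `"height"`,
#'   `"reference_line"`.
#' @param reference_wavelength reference line position in nm (used only for
#'   `method = "reference_line"`).
#' @return normalized `spectra_dataset`; concentrations unchanged.
#' @export
normalize_spectra <- function(ds,
                              method = c("mean", "vector_norm", "area",
                                         "height", "reference_line"),
                              reference_wavelength = 247.86) {
  stopifnot(inherits(ds, "spectra_dataset"))
  method <- match.arg(method)
  wl <- ds$wavelengths
  if (any(!is.finite(ds$intensities))) stop("non-finite intensities")
  divisor <- switch(method,
    mean        = rowMeans(ds$intensities),
    vector_norm = sqrt(rowSums(ds$intensities^2)),
    area        = apply(ds$intensities, 1L, function(v) trapz(wl, v)),
    height      = apply(ds$intensities, 1L, max),
    reference_line = {
      j <- which.min(abs(wl - reference_wavelength))
      step <- if (length(wl) > 1L)
        min(diff(wl)[max(1L, j - 1L):min(length(wl) - 1L, j)]) else Inf
      if (abs(wl[j] - reference_wavelength) > step / 2)
        stop(sprintf("reference line %.3f nm is off-axis (nearest grid point %.3f nm)",
                     reference_wavelength, wl[j]))
      ds$intensities[, j]
    })
  bad <- which(!(divisor > 0))
  if (length(bad))
    stop(sprintf("non-positive normalization divisor for sample '%s' (method %s)",
                 ds$sample_ids[bad[1L]], method))
  spectra_dataset(wl, ds$intensities / divisor,
                  ds$concentrations, ds$sample_ids)
}

## trapezoidal integral over a (possibly non-uniform) axis
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2 * diff(x))
}
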