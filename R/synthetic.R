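## Synthetic LIBS spectrum generator.
##
## Emulates the statistical structure the calibration method targets: a
## concentration-dependent potassium doublet (766.57 / 769.95 nm) with
## per-sample uncontrolled peak shift, peak broadening, multiplicative
## laser-energy fluctuation, a mild self-absorption saturation, a sloped
## baseline, additive noise, and concentration-independent interfering
## matrix lines.  It does not model plasma physics (no Saha-Boltzmann, no
## Stark-width calculation).

#' Line-shape primitive
#'
#' Unit-amplitude Lorentzian `1 / (1 + (2 x / fwhm)^2)` or Gaussian
#' `exp(-4 ln 2 (x / fwhm)^2)`; both reach 0.5 at `|x| = fwhm / 2`.
#'
#' @param x offset from line center, nm.
#' @param fwhm full width at half maximum, nm, `> 0`.
#' @param kind `"lorentzian"` (default; the usual Stark-broadened LIBS
#'   profile) or `"gaussian"`.
#' @return profile values.
#' @export
line_profile <- function(x, fwhm, kind = c("lorentzian", "gaussian")) {
  kind <- match.arg(kind)
  if (!is.numeric(fwhm) || fwhm <= 0) stop("fwhm must be > 0")
  switch(kind,
         lorentzian = 1 / (1 + (2 * x / fwhm)^2),
         gaussian = exp(-4 * log(2) * (x / fwhm)^2))
}

#' Simulation configuration
#'
#' Defaults state the emulated study: a 512-point grid over
#' 751.90-774.86 nm; potassium lines at 766.57 and 769.95 nm (amplitude
#' ratio 2:1, the statistical-weight ratio of the doublet); concentrations
#' spanning 0.415-0.815 g/100 g; and the stochastic degradations at the
#' stressed-regime levels (shift sd 0.05 nm, broadening sd 0.05 nm, 10%
#' laser-energy fluctuation).  The wavelength shift is shared by both
#' potassium lines within a spectrum (instrument/plasma shifts move nearby
#' lines together); set `shared_shift = FALSE` for independent line shifts.
#'
#' @param n_points grid size.
#' @param lo,hi grid limits, nm.
#' @param centers potassium line positions, nm.
#' @param fwhm base line widths, nm.
#' @param amplitude peak amplitude per unit concentration
#'   (counts per g/100 g).
#' @param self_absorption saturation constant `s >= 0`; emitted line
#'   strength is proportional to `c / (1 + s c)`.
#' @param shift_sd sd of the per-spectrum wavelength shift, nm.
#' @param broadening_sd sd of per-spectrum extra width, nm (truncated so
#'   widths stay positive).  Broadening conserves the line's integrated
#'   intensity (Stark-type redistribution): the height scales as
#'   `fwhm / w`, so broadened lines are lower and wider.
#' @param energy_sd relative sd of the multiplicative laser-energy factor
#'   (truncated positive).
#' @param baseline,baseline_slope continuum level (counts) and slope
#'   (counts/nm, about the grid center).
#' @param noise_sd additive detector-noise sd, counts (added after the
#'   energy scaling).
#' @param interferents data frame `center, amplitude, fwhm` of fixed
#'   concentration-independent matrix lines.
#' @param n_matrix_lines number of additional minor matrix lines emulating
#'   brand-to-brand sample composition differences.  Their positions,
#'   widths and mean strengths are drawn once per dataset (from the dataset
#'   seed), outside a `matrix_line_guard` window around the analyte lines;
#'   their strengths then vary per sample (lognormal,
#'   sd `matrix_line_sd` on the log scale).  This is the high-rank matrix
#'   effect a low-factor linear model cannot cancel.
#' @param matrix_line_amplitude median line strength (counts) of the minor
#'   lines; per-line medians are log-uniform within one e-fold of this.
#' @param matrix_line_sd per-sample lognormal sd of each minor line.
#' @param matrix_line_guard half-width (nm) of the exclusion zone around
#'   each analyte line (the analysis lines are chosen to be free of direct
#'   spectral interference, as in line selection from an atomic database).
#' @param matrix_lines optional explicit data frame
#'   `center, amplitude, fwhm, amplitude_sd` overriding the random draw.
#' @param conc_range concentration range for [simulate_dataset()], g/100 g.
#' @param profile line shape, `"lorentzian"` or `"gaussian"`.
#' @param shared_shift logical, see above.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_points = 512L, lo = 751.90, hi = 774.86,
                       centers = c(766.57, 769.95),
                       fwhm = c(0.25, 0.25),
                       amplitude = c(2000, 1000),
                       self_absorption = 0.8,
                       shift_sd = 0.05, broadening_sd = 0.05,
                       energy_sd = 0.10,
                       baseline = 150, baseline_slope = 0.5,
                       noise_sd = 5,
                       interferents = data.frame(
                         center = c(752.8, 772.5),
                         amplitude = c(300, 150),
                         fwhm = c(0.25, 0.25)),
                       n_matrix_lines = 120L,
                       matrix_line_amplitude = 30,
                       matrix_line_sd = 0.6,
                       matrix_line_guard = 2.0,
                       matrix_lines = NULL,
                       conc_range = c(0.415, 0.815),
                       profile = c("lorentzian", "gaussian"),
                       shared_shift = TRUE) {
  profile <- match.arg(profile)
  stopifnot(n_points >= 2, lo < hi,
            length(centers) == length(fwhm),
            length(centers) == length(amplitude),
            all(fwhm > 0), self_absorption >= 0,
            shift_sd >= 0, broadening_sd >= 0, energy_sd >= 0,
            noise_sd >= 0, n_matrix_lines >= 0, matrix_line_sd >= 0,
            conc_range[1L] <= conc_range[2L])
  structure(list(wavelengths = seq(lo, hi, length.out = n_points),
                 centers = centers, fwhm = fwhm, amplitude = amplitude,
                 self_absorption = self_absorption,
                 shift_sd = shift_sd, broadening_sd = broadening_sd,
                 energy_sd = energy_sd,
                 baseline = baseline, baseline_slope = baseline_slope,
                 noise_sd = noise_sd, interferents = interferents,
                 n_matrix_lines = as.integer(n_matrix_lines),
                 matrix_line_amplitude = matrix_line_amplitude,
                 matrix_line_sd = matrix_line_sd,
                 matrix_line_guard = matrix_line_guard,
                 matrix_lines = matrix_lines,
                 conc_range = conc_range, profile = profile,
                 shared_shift = shared_shift),
            class = "sim_config")
}

## draw the per-dataset minor matrix-line table from the current RNG state
draw_matrix_lines <- function(cfg) {
  n <- cfg$n_matrix_lines
  if (n == 0L)
    return(data.frame(center = numeric(0), amplitude = numeric(0),
                      fwhm = numeric(0), amplitude_sd = numeric(0)))
  wl <- cfg$wavelengths
  lo <- min(wl) + 0.3; hi <- max(wl) - 0.3
  centers <- numeric(0)
  while (length(centers) < n) {
    cand <- stats::runif(n, lo, hi)
    ok <- vapply(cand, function(x)
      all(abs(x - cfg$centers) > cfg$matrix_line_guard), logical(1L))
    centers <- c(centers, cand[ok])[seq_len(min(n, length(centers) +
                                                  sum(ok)))]
  }
  data.frame(center = centers,
             amplitude = cfg$matrix_line_amplitude *
               exp(stats::runif(n, -1, 1)),
             fwhm = stats::runif(n, 0.12, 0.30),
             amplitude_sd = cfg$matrix_line_sd)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d points [%.2f, %.2f] nm; lines at %s nm; shift/broaden/energy sd %.3g/%.3g/%.3g\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              paste(x$centers, collapse = ", "),
              x$shift_sd, x$broadening_sd, x$energy_sd))
  invisible(x)
}

## truncated normal draws (resample until positive / widths positive)
rnorm_trunc_pos <- function(mean, sd, floor = 0) {
  if (sd == 0) return(mean)
  v <- stats::rnorm(1L, mean, sd)
  while (v <= floor) v <- stats::rnorm(1L, mean, sd)
  v
}

#' Simulate one LIBS spectrum
#'
#' `intensity(lambda) = E * [ sum_k A_k c / (1 + s c) * (w0_k / w_k) *
#' profile(lambda - (mu_k + delta); w_k) + matrix lines + baseline ] +
#' noise`, with the random terms drawn from the current RNG state (set a
#' seed upstream, or use [simulate_dataset()]).  Two modelling points
#' mirror plasma physics: the laser-energy factor `E` multiplies the whole
#' emission spectrum (analyte lines, matrix lines and the continuum), which
#' is what makes per-spectrum normalization able to compensate energy
#' fluctuation; and broadening conserves each line's integrated intensity
#' (`w0/w` height rescaling), so peak-height readings degrade under
#' uncontrolled broadening while integrated (area-like) features stay
#' stable.  Detector noise is added after the energy scaling.
#'
#' @param conc analyte concentration, g/100 g, `>= 0`.
#' @param cfg a [sim_config()].
#' @return single-row [spectra_dataset()] with the concentration attached.
#' @export
simulate_spectrum <- function(conc, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"), conc >= 0)
  wl <- cfg$wavelengths
  E <- rnorm_trunc_pos(1, cfg$energy_sd)
  delta_shared <- if (cfg$shift_sd > 0) stats::rnorm(1L, 0, cfg$shift_sd) else 0
  sat <- conc / (1 + cfg$self_absorption * conc)
  y <- numeric(length(wl))
  for (k in seq_along(cfg$centers)) {
    delta <- if (cfg$shared_shift) delta_shared else
      if (cfg$shift_sd > 0) stats::rnorm(1L, 0, cfg$shift_sd) else 0
    w <- if (cfg$broadening_sd > 0)
      rnorm_trunc_pos(cfg$fwhm[k], cfg$broadening_sd,
                      floor = cfg$fwhm[k] * 0.05) else cfg$fwhm[k]
    y <- y + cfg$amplitude[k] * sat * (cfg$fwhm[k] / w) *
      line_profile(wl - (cfg$centers[k] + delta), w, cfg$profile)
  }
  ## non-analyte lines are other elements: each takes its own shift draw
  line_shift <- function() if (cfg$shift_sd > 0)
    stats::rnorm(1L, 0, cfg$shift_sd) else 0
  if (nrow(cfg$interferents) > 0)
    for (i in seq_len(nrow(cfg$interferents)))
      y <- y + cfg$interferents$amplitude[i] *
        line_profile(wl - (cfg$interferents$center[i] + line_shift()),
                     cfg$interferents$fwhm[i], cfg$profile)
  ml <- cfg$matrix_lines
  if (!is.null(ml) && nrow(ml) > 0)
    for (i in seq_len(nrow(ml))) {
      a <- ml$amplitude[i] *
        if (ml$amplitude_sd[i] > 0)
          exp(stats::rnorm(1L, 0, ml$amplitude_sd[i])) else 1
      y <- y + a * line_profile(wl - (ml$center[i] + line_shift()),
                                ml$fwhm[i], cfg$profile)
    }
  y <- y + cfg$baseline + cfg$baseline_slope * (wl - mean(wl))
  y <- E * y
  if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(wl), 0, cfg$noise_sd)
  spectra_dataset(wl, matrix(y, nrow = 1L), concentrations = conc)
}

#' Simulate a spectral dataset
#'
#' Draws `n` concentrations uniformly over `cfg$conc_range` and one spectrum
#' per sample; bit-identical for a fixed seed.  The minor matrix-line table
#' (positions, widths, mean strengths) is materialized once per dataset
#' from the seed — line positions are shared by all samples, as element
#' lines are — and their strengths then vary per sample.
#'
#' @param n number of samples (the emulated study used 90).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a [spectra_dataset()] with reference concentrations; the
#'   materialized matrix-line table is attached as attribute
#'   `"matrix_lines"`.
#' @export
simulate_dataset <- function(n, cfg = sim_config(), seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    if (is.null(cfg$matrix_lines))
      cfg$matrix_lines <- draw_matrix_lines(cfg)
    conc <- stats::runif(n, cfg$conc_range[1L], cfg$conc_range[2L])
    m <- matrix(0, n, length(cfg$wavelengths))
    for (i in seq_len(n))
      m[i, ] <- simulate_spectrum(conc[i], cfg)$intensities[1L, ]
    ds <- spectra_dataset(cfg$wavelengths, m, conc)
    attr(ds, "matrix_lines") <- cfg$matrix_lines
    ds
  })
}
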