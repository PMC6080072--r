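## Three-channel filter banks for the higher-density wavelet transform.
##
## Structure: analysis lowpass h0 and band filter h1 are decimated by two;
## band filter h2 is undecimated.  Perfect reconstruction (PR) holds through
## the synthesis triple (g0, g1, g2).  Writing filters as z-transforms and
## P(z) = G0(z) H0(z), the bank is built so that
##
##     (1/2) [P(z) + P(-z)] + G2(z) H2(z) = z^-d        (no-distortion)
##     G0(z) H0(-z) + G1(z) H1(-z)       = 0            (alias cancellation)
##
## with H1(z) = z^-1 G0(-z) and G1(z) = z H0(-z), which cancels aliasing for
## any (H0, G0) pair.  The product filter is
##
##     P(z) = 2 c^K [ sum_{k < ceil(K/2)} C(K-1+k, k) s^k + T s^ceil(K/2) ]
##
## in the half-band variables s = sin^2(w/2), c = cos^2(w/2).  The bracket is
## the truncated binomial series of (1-s)^-K, so the even part of P equals
## 1 - D with a deficit D that (a) is nonzero because the series is truncated
## before the half-band identity completes (T != the binomial continuation)
## and (b) has a factor s^ceil(K/2), i.e. >= K zeros at z = 1.  The deficit
## is carried by the undecimated channel: H2(z) = gamma (1 - z^-1)^K and
## G2 = D / H2 (an exact polynomial division).  Both analysis band filters
## therefore annihilate polynomials up to degree K - 1 ("K vanishing
## moments"); H0 is the B-spline lowpass (1 + z^-1)^K.
##
## The exact tap values behind the published "bi1".."bi4" names are not
## available offline; these banks are synthetic stand-ins satisfying the same
## structural contract (three channels, PR, K = 1..4 vanishing moments) and
## are guarded numerically by verify_filterbank() rather than by trusted
## transcription.

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}
polypow <- function(a, k) {
  r <- 1
  for (i in seq_len(k)) r <- polymul(r, a)
  r
}

## B(s(z)) as a causal polynomial in z^-1 (shifted by z^-m), m = ceil(K/2)
truncated_series_poly <- function(K, T_extra = -2) {
  m <- ceiling(K / 2)
  co <- c(choose(K - 1 + 0:(m - 1), 0:(m - 1)), T_extra)
  s_pow <- function(k) if (k == 0L) 1 else polypow(c(-1, 2, -1) / 4, k)
  out <- numeric(2L * m + 1L)
  for (k in 0:m) {
    pk <- s_pow(k)                      # Laurent support -k..k
    idx <- (m - k) + seq_along(pk)      # shift by z^-m -> causal
    out[idx] <- out[idx] + co[k + 1L] * pk
  }
  out
}

build_filterbank <- function(K, T_extra = -2) {
  h0 <- polypow(c(1, 1), K)
  h0 <- h0 * sqrt(2) / sum(h0)                       # H0(1) = sqrt(2)
  g0 <- polymul(polypow(c(1, 1), K), truncated_series_poly(K, T_extra))
  g0 <- g0 * sqrt(2) / sum(g0)                       # G0(1) = sqrt(2)
  P <- polymul(h0, g0)
  d <- (length(P) - 1L) %/% 2L                       # overall stage delay
  if ((length(P) - 1L) %% 2L != 0L)
    stop("internal: product-filter degree must be even")
  ## the decimated channels pass the lag-parity-of-d part of P; the deficit
  ## D = delta_d - that part is carried by the undecimated channel
  S <- numeric(length(P))
  ii <- which(((seq_along(P) - 1L) %% 2L) == (d %% 2L))
  S[ii] <- P[ii]
  D <- -S
  D[d + 1L] <- D[d + 1L] + 1
  h2 <- polypow(c(1, -1), K)
  gamma <- sqrt(sqrt(sum(D^2)) / sum(h2^2))          # balance channel scales
  h2 <- h2 * gamma
  ## exact deconvolution g2 = D / h2
  nd <- length(D) - length(h2) + 1L
  g2 <- numeric(nd)
  r <- D
  for (i in seq_len(nd)) {
    g2[i] <- r[i] / h2[1L]
    r[i:(i + length(h2) - 1L)] <- r[i:(i + length(h2) - 1L)] - g2[i] * h2
  }
  if (max(abs(r)) > 1e-10) stop("internal: deficit division not exact")
  sgn <- (-1)^(seq_along(g0) - 1L)
  sgn0 <- (-1)^(seq_along(h0) - 1L)
  if (d %% 2L == 0L) {
    h1 <- g0 * sgn; o_h1 <- 1L                       # H1(z) = z^-1 G0(-z)
    g1 <- h0 * sgn0; o_g1 <- -1L                     # G1(z) = z H0(-z)
  } else {
    h1 <- g0 * sgn; o_h1 <- 0L                       # H1(z) = G0(-z)
    g1 <- -h0 * sgn0; o_g1 <- 0L                     # G1(z) = -H0(-z)
  }
  structure(list(name = paste0("bi", K), vanishing_moments = K,
                 h0 = h0, h1 = h1, h2 = h2,
                 g0 = g0, g1 = g1, g2 = g2,
                 ## support origins (lag of first tap)
                 o_h0 = 0L, o_h1 = o_h1, o_h2 = 0L,
                 o_g0 = 0L, o_g1 = o_g1, o_g2 = 0L,
                 delay = as.integer(d)),
            class = "hdwt_filterbank")
}

#' Load a three-channel wavelet filter bank
#'
#' Returns the analysis/synthesis filter triple of the higher-density
#' transform.  Four banks are available, `"bi1"` to `"bi4"`, with 1 to 4
#' vanishing moments on the analysis band filters; `"bi4"` is the bank used
#' for potassium calibration.  Every returned bank passes
#' [verify_filterbank()].
#'
#' @param name one of `"bi1"`, `"bi2"`, `"bi3"`, `"bi4"`.
#' @return an object of class `hdwt_filterbank` with analysis filters
#'   `h0, h1, h2`, synthesis filters `g0, g1, g2`, their support origins, the
#'   stage delay, and `vanishing_moments`.
#' @export
load_filterbank <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% paste0("bi", 1:4))
    stop(sprintf("unknown filter bank '%s' (available: bi1, bi2, bi3, bi4)",
                 paste(format(name), collapse = ",")))
  build_filterbank(as.integer(substring(name, 3L)))
}

#' @export
print.hdwt_filterbank <- function(x, ...) {
  cat(sprintf("<hdwt_filterbank> %s: %d vanishing moment(s); taps h0/h1/h2 = %d/%d/%d, stage delay %d\n",
              x$name, x$vanishing_moments,
              length(x$h0), length(x$h1), length(x$h2), x$delay))
  invisible(x)
}

#' Verify a filter bank numerically
#'
#' Checks the two properties the transform relies on, rather than trusting
#' the tap tables: (1) perfect reconstruction, as the maximum residual of
#' forward-then-inverse over random signals; (2) vanishing moments, as the
#' moment sums `sum_n n^k h(n)` of each analysis band filter for
#' `k = 0 .. vanishing_moments - 1`.
#'
#' @param fb an `hdwt_filterbank`.
#' @param n_signals number of random probe signals.
#' @param signal_length probe length.
#' @param tol pass/fail tolerance.
#' @param seed RNG seed for the probes.
#' @return a list with `pr_residual`, `moment_sums` (matrix, rows = band
#'   filters, columns = moment orders), and logical `pass`.
#' @export
verify_filterbank <- function(fb, n_signals = 10L, signal_length = 128L,
                              tol = 1e-8, seed = 42L) {
  stopifnot(inherits(fb, "hdwt_filterbank"))
  pr <- with_seed(seed, {
    max(vapply(seq_len(n_signals), function(i) {
      x <- stats::rnorm(signal_length)
      x <- x / max(abs(x))
      cf <- hdwt_forward(x, fb, J = 2L, boundary = "zero")
      max(abs(hdwt_inverse(cf, fb) - x))
    }, numeric(1L)))
  })
  K <- fb$vanishing_moments
  moment <- function(h, origin, k) {
    lags <- origin + seq_along(h) - 1L
    sum(h * lags^k)
  }
  ms <- rbind(
    h1 = vapply(0:(K - 1L), function(k) moment(fb$h1, fb$o_h1, k), numeric(1L)),
    h2 = vapply(0:(K - 1L), function(k) moment(fb$h2, fb$o_h2, k), numeric(1L)))
  colnames(ms) <- paste0("k", 0:(K - 1L))
  list(pr_residual = pr, moment_sums = ms,
       pass = pr < tol && max(abs(ms)) < tol)
}

#' Orthonormal two-channel filters with K vanishing moments
#'
#' Minimum-phase (Daubechies-type) orthonormal lowpass/highpass pair computed
#' by spectral factorization of the maxflat half-band filter.  Used as the
#' critically-sampled reference transform against which the near
#' shift-invariance of the higher-density transform is judged; see
#' [dwt_forward()].
#'
#' @param K vanishing moments (filter length `2K`).
#' @return list with `h0` (lowpass) and `h1` (highpass) taps.
#' @export
orthonormal_filters <- function(K) {
  stopifnot(K >= 1, K == round(K))
  ## B(s) = sum_{k<K} C(K-1+k,k) s^k ; roots in s -> z-quadratics
  bcoef <- choose(K - 1 + 0:(K - 1), 0:(K - 1))
  h <- polypow(c(1, 1), K)
  if (K > 1) {
    sroots <- polyroot(bcoef)
    for (s0 in sroots) {
      zr <- polyroot(c(1, -(2 - 4 * s0), 1))
      r <- zr[which.min(Mod(zr))]            # minimum-phase root
      h <- polymul(h, c(1, -r))
    }
    h <- Re(h)
  }
  h <- h * sqrt(2) / sum(h)   # H0(1) = sqrt(2); unit 2-norm then follows
                              # from the half-band factorization
  L <- length(h)
  list(h0 = h, h1 = rev(h) * (-1)^(seq_len(L) - 1L))
}
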