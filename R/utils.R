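## Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage / per-run seeds,
#' so that adding a consumer does not perturb the randomness of the others.
#' Uses a Lehmer-style step entirely in exact double arithmetic; results stay
#' below 2^31.
#'
#' @param master integer master seed.
#' @param k non-negative integer counter.
#' @return an integer seed in [1, 2147483646].
#' @export
child_seed <- function(master, k) {
  m <- 2147483647
  s <- (abs(as.double(master)) %% m) + 1
  s <- (s * 48271 + as.double(k) * 16807 + 1) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(s %% 2147483646 + 1)
}

## with_seed: run expr under a fixed seed without clobbering caller RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

## full (zero-extension) convolution of a signal with short filter taps
conv_full <- function(x, h) {
  n <- length(x)
  out <- numeric(n + length(h) - 1L)
  for (k in seq_along(h)) {
    if (h[k] != 0) {
      idx <- k:(k + n - 1L)
      out[idx] <- out[idx] + h[k] * x
    }
  }
  out
}

## circular convolution; tap k (1-based) acts at lag (k - 1 + origin)
conv_circ <- function(x, h, origin = 0L) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_along(h)) {
    if (h[k] != 0) {
      lag <- (k - 1L + origin) %% n
      out <- out + h[k] * x[((seq_len(n) - 1L - lag) %% n) + 1L]
    }
  }
  out
}
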