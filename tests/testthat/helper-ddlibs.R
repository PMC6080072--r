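## Shared fixtures and independent oracles.

## small deterministic dataset on an arbitrary axis
tiny_dataset <- function(n = 4, k = 6, seed = 1, conc = TRUE) {
  with_seed_local(seed, {
    wl <- sort(stats::runif(k, 500, 600))
    m <- matrix(stats::rexp(n * k, rate = 0.1), n, k)
    spectra_dataset(wl, m,
                    concentrations = if (conc) stats::runif(n, 0.4, 0.8),
                    sample_ids = paste0("t", seq_len(n)))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

## independent PLS oracle: SIMPLS (de Jong 1993), coded separately from the
## package's NIPALS implementation
simpls_oracle <- function(X, y, A) {
  X <- as.matrix(X); y <- as.numeric(y)
  mx <- colMeans(X); my <- mean(y)
  X0 <- sweep(X, 2, mx); y0 <- y - my
  s <- crossprod(X0, y0)
  p <- ncol(X)
  R <- matrix(0, p, A); V <- matrix(0, p, A); q <- numeric(A)
  for (a in seq_len(A)) {
    r <- s
    t <- X0 %*% r
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    t <- t / nt; r <- r / nt
    pp <- crossprod(X0, t)
    q[a] <- sum(y0 * t)
    v <- pp
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pp)
    }
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
  }
  beta <- R %*% q
  list(beta = as.numeric(beta), intercept = my - sum(mx * beta))
}

## predictor matrix whose centered columns are exactly orthogonal (for the
## A = 1 exact-fit property, which needs in-sample uncorrelated predictors)
orthogonal_X <- function(n, p, seed = 1) {
  with_seed_local(seed, {
    M <- matrix(stats::rnorm(n * (p + 1)), n)
    M <- scale(M, center = TRUE, scale = FALSE)
    qr.Q(qr(M))[, seq_len(p), drop = FALSE]
  })
}

## rank-one predictor design: every subset admits an exact one-factor fit
rank_one_data <- function(n, p, seed = 1) {
  with_seed_local(seed, {
    t <- stats::rnorm(n)
    v <- stats::rnorm(p)
    list(X = outer(t, v), y = 3 * t + 0.5)
  })
}

## clean "easy regime" simulator configuration: no stochastic degradation;
## named arguments override the clean defaults
easy_config <- function(...) {
  args <- utils::modifyList(
    list(shift_sd = 0, broadening_sd = 0, energy_sd = 0, noise_sd = 0,
         n_matrix_lines = 0L, self_absorption = 0),
    list(...))
  do.call(sim_config, args)
}

## reduced-scale frog parameters for tests
test_rfa <- function(n_iterations = 150) rfa_params(n_iterations = n_iterations)
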