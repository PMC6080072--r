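## Random-frog variable selection and its bagged modification.
##
## The random-frog search is a reversible-jump-like walk over variable
## subsets: from the current subset of size Q, a candidate size Q* is drawn
## from a rounded normal around Q; shrinking keeps the variables with the
## largest absolute PLS coefficients, growing adds an oversampled pool of
## random outside variables and keeps the Q* best; the candidate replaces
## the current subset if its cross-validated error improves, or with
## probability eta * err_current / err_candidate otherwise.  Per-variable
## visit frequency over the iterations is the importance score.
##
## The bagged modification repeats the search on random 70% training
## subsamples and accumulates the per-run frequency vectors into a single
## probability score P; the top-P variable(s) are selected.

#' Random-frog search parameters
#'
#' Hyperparameters are not element-specific; the defaults follow the
#' published random-frog convention: `Q = 2` initial subset size,
#' `theta = 0.3` candidate-size spread, `omega = 3` candidate oversampling,
#' `eta = 0.1` acceptance damping, 10,000 iterations at full scale (use far
#' fewer for tests).  Within-run fitness is k-fold cross-validated RMSE.
#'
#' @param n_iterations number of search iterations.
#' @param Q initial subset size.
#' @param theta candidate-size spread (sd of Q* is `theta * Q`).
#' @param omega oversampling factor when growing.
#' @param eta acceptance damping in (0, 1].
#' @param cv_folds folds of the within-run cross-validation.
#' @return list of class `rfa_params`.
#' @export
rfa_params <- function(n_iterations = 10000L, Q = 2L, theta = 0.3,
                       omega = 3L, eta = 0.1, cv_folds = 5L) {
  stopifnot(n_iterations >= 1, Q >= 1, theta > 0, omega >= 1,
            eta > 0, eta <= 1, cv_folds >= 2)
  structure(list(n_iterations = as.integer(n_iterations), Q = as.integer(Q),
                 theta = theta, omega = as.integer(omega), eta = eta,
                 cv_folds = as.integer(cv_folds)),
            class = "rfa_params")
}

## k-fold CV rmse of a variable subset; folds precomputed (list of index sets)
subset_cv_error <- function(X, y, vars, A, folds) {
  preds <- numeric(length(y))
  Xs <- X[, vars, drop = FALSE]
  for (te in folds) {
    tr <- setdiff(seq_along(y), te)
    fit <- pls_beta(Xs[tr, , drop = FALSE], y[tr], A)
    preds[te] <- Xs[te, , drop = FALSE] %*% fit$beta + fit$intercept
  }
  rmsecv(y, preds)
}

#' One random-frog run
#'
#' Runs the stochastic subset search on `(X, y)` and returns the
#' per-variable visit frequency (in `[0, 1]`).  Deterministic for a fixed
#' seed.
#'
#' @param X numeric `n x p` predictor matrix, `n >= 6`.
#' @param y response vector.
#' @param A PLS factors used inside the search (capped at subset size and
#'   fold size automatically).
#' @param params an [rfa_params()] object.
#' @param seed integer seed.
#' @return numeric vector of length `p`: visit frequencies.
#' @export
rfa_run <- function(X, y, A = 2L, params = rfa_params(), seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 1L) stop("X has no variables")
  if (n < 6L) stop("need at least 6 samples")
  if (p == 1L) return(1)                    # forced selection
  with_seed(seed, {
    folds <- split(sample(seq_len(n)),
                   rep_len(seq_len(params$cv_folds), n))
    counts <- numeric(p)
    V <- sample.int(p, min(params$Q, p))
    err_V <- subset_cv_error(X, y, V, A, folds)
    for (it in seq_len(params$n_iterations)) {
      Qstar <- round(stats::rnorm(1L, length(V), params$theta * length(V)))
      Qstar <- max(1L, min(p, Qstar))
      if (Qstar == length(V)) {
        cand <- V
        err_cand <- err_V
      } else if (Qstar < length(V)) {
        fit <- pls_beta(X[, V, drop = FALSE], y, min(A, length(V)))
        cand <- V[order(abs(fit$beta), decreasing = TRUE)[seq_len(Qstar)]]
        err_cand <- subset_cv_error(X, y, cand, A, folds)
      } else {
        outside <- setdiff(seq_len(p), V)
        n_add <- min(length(outside), params$omega * (Qstar - length(V)))
        pool <- c(V, sample(outside, n_add))
        fit <- pls_beta(X[, pool, drop = FALSE], y, min(A, length(pool)))
        cand <- pool[order(abs(fit$beta),
                           decreasing = TRUE)[seq_len(min(Qstar, length(pool)))]]
        err_cand <- subset_cv_error(X, y, cand, A, folds)
      }
      accept <- err_cand <= err_V ||
        stats::runif(1L) < params$eta * (err_V / err_cand)
      if (accept) { V <- cand; err_V <- err_cand }
      counts[V] <- counts[V] + 1
    }
    counts / params$n_iterations
  })
}

#' Bagged random-frog selection
#'
#' Repeats [rfa_run()] `B` times, each on a fresh random `train_fraction`
#' subsample of the samples, and accumulates the per-run frequency vectors
#' into the selection probability `P` (a plain sum, so `0 <= P_j <= B`).
#' The remaining samples of each run are scored once as a holdout and logged
#' for audit.  Per-run seeds derive deterministically from `seed`.
#'
#' @param X predictor matrix (e.g. the HDWT coefficient matrix).
#' @param y response.
#' @param A PLS factors inside the search.
#' @param B number of bagged runs (1,000 at full scale).
#' @param train_fraction fraction of samples given to each run (default 0.7).
#' @param params an [rfa_params()] object.
#' @param seed master seed.
#' @param keep_runs if `TRUE`, retain the `B x p` matrix of per-run
#'   frequencies for audit.
#' @return object of class `selection_result` with `P`, `B`, `selected`
#'   (argmax of `P`, ties to the lowest index), `holdout_rmse` per run, and
#'   optionally `runs`.
#' @export
mrfa <- function(X, y, A = 2L, B = 1000L, train_fraction = 0.7,
                 params = rfa_params(), seed = 1L, keep_runs = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (B < 1L) stop("B must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_tr <- round(train_fraction * n)
  if (n_tr < 6L || n_tr >= n)
    stop(sprintf("train fraction %.2f leaves %d training samples; need >= 6 and < n",
                 train_fraction, n_tr))
  P <- numeric(p)
  runs <- if (keep_runs) matrix(0, B, p) else NULL
  holdout <- numeric(B)
  for (b in seq_len(B)) {
    sb <- child_seed(seed, b)
    tr <- with_seed(sb, sort(sample.int(n, n_tr)))
    freq <- rfa_run(X[tr, , drop = FALSE], y[tr], A, params,
                    seed = child_seed(sb, 1L))
    P <- P + freq
    if (keep_runs) runs[b, ] <- freq
    ## holdout audit: top variable of this run, scored on the 30%
    top_b <- which.max(freq)
    fit <- pls_beta(X[tr, top_b, drop = FALSE], y[tr], 1L)
    te <- setdiff(seq_len(n), tr)
    holdout[b] <- rmsecv(y[te],
                         X[te, top_b, drop = FALSE] %*% fit$beta + fit$intercept)
  }
  structure(list(P = P, B = B, selected = which.max(P),
                 holdout_rmse = holdout, runs = runs,
                 train_fraction = train_fraction, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d runs over %d variables; top variable %d (P = %.3f)\n",
              x$B, length(x$P), x$selected, x$P[x$selected]))
  invisible(x)
}

#' Top-probability variables
#'
#' Indices of the `k` largest accumulated selection probabilities; ties are
#' broken toward the lowest flat index so selections are reproducible.
#'
#' @param result a `selection_result`.
#' @param k number of variables, `1 <= k <= p`.
#' @return integer vector of length `k`, ordered by decreasing `P`.
#' @export
select_top <- function(result, k = 1L) {
  stopifnot(inherits(result, "selection_result"))
  p <- length(result$P)
  if (k < 1L || k > p) stop(sprintf("k must lie in 1..%d", p))
  order(-result$P, seq_len(p))[seq_len(k)]
}

#' Selection result as a table
#'
#' Per-coefficient table (`flat, scale, band, offset, P, rank`) suitable for
#' CSV export; `index_map` comes from the transform geometry.
#'
#' @param result a `selection_result`.
#' @param index_map optional index map from [hdwt_flatten()].
#' @return a data frame sorted by flat index.
#' @export
selection_as_table <- function(result, index_map = NULL) {
  p <- length(result$P)
  rank <- match(seq_len(p), order(-result$P, seq_len(p)))
  out <- data.frame(flat = seq_len(p), P = result$P, rank = rank)
  if (!is.null(index_map))
    out <- cbind(index_map[match(out$flat, index_map$flat),
                           c("scale", "band", "offset")], out)
  out[order(out$flat), , drop = FALSE]
}
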