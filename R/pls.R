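## Partial least squares (single response), cross-validation.
##
## Centered NIPALS; no variable autoscaling (mean-centering only, matching
## common LIBS practice).  Prediction is an affine map of the predictors.

#' Fit a PLS regression model
#'
#' Univariate-response PLS by the NIPALS algorithm with mean-centering and
#' no scaling.  Deterministic: no randomness is involved in the fit.
#'
#' @param X numeric `n x p` predictor matrix.
#' @param y numeric response vector of length `n`.
#' @param A number of latent factors, `1 <= A <= min(n - 1, p)`.
#' @return object of class `pls_model` with the weight/loading structure,
#'   regression coefficients `coefficients`, `intercept`, fitted values and
#'   training RMSE.
#' @export
pls_fit <- function(X, y, A) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (A < 1 || A > min(n - 1, p))
    stop(sprintf("A must lie in [1, %d]", min(n - 1, p)))
  if (all(apply(X, 2L, function(col) diff(range(col)) == 0)))
    stop("degenerate X: all columns constant")
  if (diff(range(y)) == 0) stop("constant response y")
  mx <- colMeans(X); my <- mean(y)
  E <- sweep(X, 2L, mx)
  f <- y - my
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  Tm <- matrix(0, n, A)
  for (a in seq_len(A)) {
    w <- crossprod(E, f)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * 1e3) {
      if (a == 1L) stop("X carries no covariance with y")
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[seq_len(a - 1L)]; Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      A <- a - 1L
      break
    }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    pl <- crossprod(E, t)[, 1L] / tt
    q <- sum(t * f) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - q * t
    W[, a] <- w; P[, a] <- pl; Q[a] <- q; Tm[, a] <- t
  }
  beta <- W %*% solve(crossprod(P, W), Q)
  intercept <- my - sum(mx * beta)
  fitted <- as.numeric(X %*% beta) + intercept
  structure(list(n_factors = A, coefficients = as.numeric(beta),
                 intercept = intercept,
                 x_means = mx, y_mean = my,
                 weights = W, loadings = P, y_loadings = Q,
                 fitted = fitted,
                 train_rmse = sqrt(mean((y - fitted)^2))),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d factor(s), %d predictors, training RMSE %.4g\n",
              x$n_factors, length(x$coefficients), x$train_rmse))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix with the training number of columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop(sprintf("newdata has %d columns, model was trained on %d",
                 ncol(newdata), length(object$coefficients)))
  as.numeric(newdata %*% object$coefficients) + object$intercept
}

## lean internal fit: centered NIPALS returning only (beta, intercept);
## used in the hot loops of cross-validation and the random-frog search
pls_beta <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  A <- min(A, n - 1L, p)
  mx <- colMeans(X); my <- mean(y)
  E <- sweep(X, 2L, mx)
  f <- y - my
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(E, f)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-300) break
    pl <- crossprod(E, t)[, 1L] / tt
    q <- sum(t * f) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - q * t
    W[, a] <- w; P[, a] <- pl; Q[a] <- q
    used <- a
  }
  if (used == 0L) return(list(beta = numeric(p), intercept = my))
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  beta <- W %*% solve(crossprod(P, W), Q[seq_len(used)])
  list(beta = as.numeric(beta), intercept = my - sum(mx * beta))
}

#' Cross-validated RMSE
#'
#' Assembles out-of-fold predictions for every sample and scores them with
#' [rmsecv()] (the `m - 1` denominator convention used throughout).  A model
#' never scores a sample it was trained on.
#'
#' @param X predictor matrix.
#' @param y response.
#' @param A PLS factors (must be feasible in every fold).
#' @param scheme `"loo"` (leave-one-out; default) or `"kfold"`.
#' @param k folds for `"kfold"`.
#' @param seed fold-assignment seed for `"kfold"` (deterministic given seed).
#' @return the cross-validated RMSE, with the out-of-fold predictions in
#'   attribute `"predictions"` and fold ids in `"folds"`.
#' @export
cross_validate <- function(X, y, A, scheme = c("loo", "kfold"),
                           k = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  scheme <- match.arg(scheme)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples for cross-validation")
  folds <- if (scheme == "loo") seq_len(n) else
    with_seed(seed, sample(rep_len(seq_len(k), n)))
  preds <- numeric(n)
  for (f in unique(folds)) {
    te <- which(folds == f); tr <- which(folds != f)
    if (A > min(length(tr) - 1L, ncol(X)))
      stop(sprintf("A = %d infeasible in a fold with %d training samples",
                   A, length(tr)))
    fit <- pls_beta(X[tr, , drop = FALSE], y[tr], A)
    preds[te] <- X[te, , drop = FALSE] %*% fit$beta + fit$intercept
  }
  out <- rmsecv(y, preds)
  attr(out, "predictions") <- preds
  attr(out, "folds") <- folds
  out
}

## one centered NIPALS per training set, predictions for all factor counts
## 1..A (nested models come for free)
pls_beta_path <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  A <- min(A, n - 1L, p)
  mx <- colMeans(X); my <- mean(y)
  E <- sweep(X, 2L, mx)
  f <- y - my
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(E, f)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-300) break
    pl <- crossprod(E, t)[, 1L] / tt
    q <- sum(t * f) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - q * t
    W[, a] <- w; P[, a] <- pl; Q[a] <- q
    used <- a
  }
  betas <- matrix(0, p, used)
  if (used > 0L) {
    R <- W[, seq_len(used), drop = FALSE] %*%
      solve(crossprod(P[, seq_len(used), drop = FALSE],
                      W[, seq_len(used), drop = FALSE]))
    for (a in seq_len(used))
      betas[, a] <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  }
  list(betas = betas, intercepts = my - crossprod(mx, betas)[1L, ],
       used = used, my = my)
}

#' Pick the factor count minimizing cross-validated RMSE
#'
#' Scans `A = 1..A_max` with out-of-fold predictions from a single nested
#' PLS decomposition per fold (so the scan costs little more than one
#' cross-validation at `A_max`).
#'
#' @param X predictor matrix.
#' @param y response.
#' @param A_max largest candidate factor count (default 15).
#' @param scheme `"loo"` or `"kfold"`.
#' @param k,seed fold parameters for `"kfold"`.
#' @return list with `A` (ties go to the smaller count) and the `rmsecv`
#'   value per candidate.
#' @export
choose_factors <- function(X, y, A_max = 15L, scheme = "loo",
                           k = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  A_max <- min(A_max, n - 2L, ncol(X))
  folds <- if (scheme == "loo") seq_len(n) else
    with_seed(seed, sample(rep_len(seq_len(k), n)))
  preds <- matrix(NA_real_, n, A_max)
  for (f in unique(folds)) {
    te <- which(folds == f); tr <- which(folds != f)
    path <- pls_beta_path(X[tr, , drop = FALSE], y[tr], A_max)
    pr <- X[te, , drop = FALSE] %*% path$betas
    pr <- sweep(pr, 2L, path$intercepts, `+`)
    if (path$used < A_max && path$used > 0L)
      pr <- cbind(pr, matrix(pr[, path$used], nrow(pr),
                             A_max - path$used))
    if (path$used == 0L) pr <- matrix(path$my, length(te), A_max)
    preds[te, ] <- pr
  }
  errs <- vapply(seq_len(A_max), function(a) rmsecv(y, preds[, a]),
                 numeric(1L))
  list(A = which.min(errs), rmsecv = errs)
}
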