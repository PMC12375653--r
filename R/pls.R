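# Compact SIMPLS engine for a single response. This is the workhorse behind
# both the PLSR regression route and the CARS inner loop (where hundreds of
# fits per selection run make speed matter). Coefficients are returned
# cumulatively for every component count so cross-validation over the
# component grid costs one fit per fold.

#' Fit a univariate SIMPLS partial least squares regression
#'
#' @param X Predictor matrix (n x p).
#' @param y Response vector (length n).
#' @param ncomp Maximum number of latent components; silently truncated at
#'   the rank limit `min(n - 1, p)` or when a deflated score collapses.
#' @return `pls_model`: `coef` (p x A matrix, column a = coefficients using
#'   a components), `intercept` (length A), `ncomp` (A actually fitted),
#'   plus the centering means.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2, p >= 1)
  ncomp <- min(ncomp, n - 1L, p)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  S <- crossprod(Xc, yc)               # p x 1
  R <- matrix(0, p, ncomp)             # weights
  Q <- numeric(ncomp)                  # y loadings
  V <- matrix(0, p, ncomp)             # orthonormal basis of X loadings
  A <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t_ <- Xc %*% r
    nt <- sqrt(sum(t_^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t_ <- t_ / nt; r <- r / nt
    pl <- crossprod(Xc, t_)            # X loading
    q <- sum(yc * t_)
    v <- pl
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pl)
    }
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[a] <- q; V[, a] <- v
    A <- a
  }
  if (A == 0L) stop("SIMPLS failed: X has no usable variance", call. = FALSE)
  coef <- matrix(0, p, A)
  acc <- numeric(p)
  for (a in seq_len(A)) {
    acc <- acc + R[, a] * Q[a]
    coef[, a] <- acc
  }
  intercept <- ym - as.numeric(xm %*% coef)
  structure(list(coef = coef, intercept = intercept, ncomp = A,
                 x_mean = xm, y_mean = ym),
            class = "pls_model")
}

#' Predict from a [pls_fit()] model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the same columns as the training data.
#' @param ncomp Component counts to predict with (default: all fitted).
#' @param ... Unused.
#' @return Matrix `nrow(newdata) x length(ncomp)`.
#' @export
predict.pls_model <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(ncomp)) ncomp <- seq_len(object$ncomp)
  stopifnot(all(ncomp >= 1), all(ncomp <= object$ncomp))
  out <- newdata %*% object$coef[, ncomp, drop = FALSE]
  sweep(out, 2L, object$intercept[ncomp], "+")
}

#' Regression coefficients at a given component count
#'
#' @param model A `pls_model`.
#' @param ncomp Component count (default: the largest fitted).
#' @return Numeric vector of length p (no intercept).
#' @export
pls_coef <- function(model, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pls_model"), ncomp >= 1, ncomp <= model$ncomp)
  model$coef[, ncomp]
}

# k-fold assignment, seeded by the caller's RNG state
cv_folds <- function(n, k) {
  k <- min(k, n)
  sample(rep(seq_len(k), length.out = n))
}

#' Cross-validated RMSE of a PLS model over a component grid
#'
#' @param X,y Training data.
#' @param max_ncomp Largest component count to assess.
#' @param folds Number of CV folds (default 10).
#' @return List `rmse` (per component count), `best_ncomp`, `best_rmse`.
#' @export
pls_cv_rmse <- function(X, y, max_ncomp = 10L, folds = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  max_ncomp <- min(max_ncomp, n - ceiling(n / folds) - 1L, ncol(X))
  max_ncomp <- max(max_ncomp, 1L)
  fold <- cv_folds(n, folds)
  sq <- matrix(NA_real_, n, max_ncomp)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], max_ncomp)
    a_use <- seq_len(min(max_ncomp, fit$ncomp))
    pred <- predict(fit, X[!tr, , drop = FALSE], ncomp = a_use)
    sq[!tr, a_use] <- (pred - y[!tr])^2
  }
  rmse <- sqrt(colMeans(sq, na.rm = TRUE))
  best <- which.min(rmse)
  list(rmse = rmse, best_ncomp = best, best_rmse = rmse[best])
}
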