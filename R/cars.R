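# Competitive adaptive reweighted sampling (CARS): Monte-Carlo PLS fits,
# variable weights from the absolute regression coefficients, exponentially
# decreasing forced retention, adaptive reweighted sampling among the
# survivors, and cross-validated RMSE to pick the winning subset.

#' CARS configuration
#'
#' The exponentially decreasing function (EDF) constants are fixed by the
#' boundary conditions: the first run retains all `p` variables and the last
#' retains 2, i.e. `r_i = round(p * a * exp(-k * i))` with
#' `a = (p/2)^(1/(N-1))` and `k = log(p/2)/(N-1)`.
#'
#' @param n_mc_runs Number of Monte-Carlo runs (default 50, >= 2).
#' @param ratio Fraction of training samples drawn per run (default 0.8).
#' @param max_ncomp Maximum PLS components (default 10).
#' @param folds CV folds for the per-run RMSECV (default 10).
#' @param seed Integer seed.
#' @return `cars_config` list.
#' @export
cars_config <- function(n_mc_runs = 50L, ratio = 0.8, max_ncomp = 10L,
                        folds = 10L, seed = 1L) {
  stopifnot(n_mc_runs >= 2, ratio > 0, ratio < 1, max_ncomp >= 1, folds >= 2)
  structure(list(n_mc_runs = as.integer(n_mc_runs), ratio = ratio,
                 max_ncomp = as.integer(max_ncomp), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "cars_config")
}

edf_counts <- function(p, n_runs) {
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  counts <- round(p * a * exp(-k * seq_len(n_runs)))
  pmin(pmax(counts, 2L), p)
}

#' Select informative bands with CARS
#'
#' Each run fits PLS on a random subsample of the training set restricted to
#' the currently retained variables, converts the absolute regression
#' coefficients to weights, enforces the EDF retention count by forced
#' selection of the top-weighted variables, then applies adaptive reweighted
#' sampling (weighted draws with replacement; unique survivors are kept, as
#' in the original algorithm). The RMSECV of a PLS model on each run's
#' retained set is recorded and the set with minimum RMSECV wins.
#'
#' @param X Training predictor matrix (n >= 20, p >= 5).
#' @param y Training response.
#' @param config A [cars_config()].
#' @return `cars_result`: `selected` (band indices of the winning run),
#'   `best_run`, `rmsecv` (per run), `retained` (list of per-run index
#'   sets), `counts` (EDF targets).
#' @export
cars_select <- function(X, y, config = cars_config()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 20) stop("CARS needs >= 20 samples", call. = FALSE)
  if (p < 5) stop("CARS needs >= 5 variables", call. = FALSE)
  stopifnot(length(y) == n, inherits(config, "cars_config"))
  set.seed(config$seed)
  counts <- edf_counts(p, config$n_mc_runs)
  retained <- seq_len(p)
  runs <- vector("list", config$n_mc_runs)
  rmsecv <- rep(NA_real_, config$n_mc_runs)
  for (i in seq_len(config$n_mc_runs)) {
    sub <- sample(n, max(2L, round(config$ratio * n)))
    ncomp <- min(config$max_ncomp, length(retained), length(sub) - 1L)
    fit <- tryCatch(
      pls_fit(X[sub, retained, drop = FALSE], y[sub], ncomp),
      error = function(e) NULL
    )
    if (is.null(fit)) {           # singular subsample: skip the reweighting
      warning(sprintf("CARS run %d skipped (singular PLS)", i))
      runs[[i]] <- retained
      next
    }
    w <- abs(pls_coef(fit))
    if (sum(w) <= 0) w <- rep(1, length(w))
    w <- w / sum(w)
    r_i <- min(counts[i], length(retained))
    # forced selection of the top-weighted variables
    forced <- order(w, decreasing = TRUE)[seq_len(r_i)]
    # adaptive reweighted sampling among the survivors
    if (length(forced) > 2L) {
      draw <- sample(forced, size = r_i, replace = TRUE, prob = w[forced])
      keep <- sort(unique(draw))
    } else {
      keep <- sort(forced)
    }
    if (length(keep) < 2L) {
      keep <- forced[order(w[forced], decreasing = TRUE)][1:2]
    }
    retained <- retained[keep]
    runs[[i]] <- retained
    cv <- pls_cv_rmse(X[, retained, drop = FALSE], y,
                      max_ncomp = config$max_ncomp, folds = config$folds)
    rmsecv[i] <- cv$best_rmse
  }
  best <- which.min(rmsecv)
  structure(list(selected = runs[[best]], best_run = best, rmsecv = rmsecv,
                 retained = runs, counts = counts, config = config),
            class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result> %d runs; best run %d (RMSECV %.4g); %d bands selected\n",
              length(x$retained), x$best_run, x$rmsecv[x$best_run],
              length(x$selected)))
  invisible(x)
}
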