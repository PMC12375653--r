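# Regression stage: seeded 8:2 split, train-fitted target standardization,
# grid search by 10-fold cross-validation, and PLSR / SVR / random-forest
# back ends. PLSR is the primary model; SVR (RBF) and RF are comparators.

#' Seeded train/test split
#'
#' @param n Number of samples.
#' @param ratio Training fraction (default 0.8, the 8:2 split).
#' @param seed Integer seed.
#' @return List `train`, `test` of disjoint, exhaustive index vectors.
#' @export
make_split <- function(n, ratio = 0.8, seed = 1L) {
  stopifnot(n >= 5, ratio > 0, ratio < 1)
  set.seed(seed)
  tr <- sort(sample(n, round(ratio * n)))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Train-fitted z-score scaler for the regression target
#'
#' @param y Training response values.
#' @return `target_scaler` with `mean`, `sd`.
#' @export
target_scaler <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s <= 0) stop("target has zero variance", call. = FALSE)
  structure(list(mean = mean(y), sd = s), class = "target_scaler")
}

#' @rdname target_scaler
#' @param scaler A `target_scaler`.
#' @export
scale_target <- function(scaler, y) (y - scaler$mean) / scaler$sd

#' @rdname target_scaler
#' @export
unscale_target <- function(scaler, y) y * scaler$sd + scaler$mean

#' Regressor specification
#'
#' @param model `"plsr"`, `"svr"` or `"rf"`.
#' @param grid Optional named list of hyperparameter vectors; defaults:
#'   PLSR `ncomp` 1..min(20, p); SVR (RBF) `cost` \{0.1, 1, 10, 100\},
#'   `gamma` \{1/p, 0.01, 0.1\}, `epsilon` \{0.01, 0.1\}; RF `ntree`
#'   \{100, 300\}, `maxnodes` \{unlimited, 16, 64\}.
#' @return `regressor_spec`.
#' @export
regressor_spec <- function(model = c("plsr", "svr", "rf"), grid = NULL) {
  model <- match.arg(model)
  structure(list(model = model, grid = grid), class = "regressor_spec")
}

default_grid <- function(model, p) {
  switch(model,
    plsr = list(ncomp = seq_len(min(20L, p))),
    svr = list(cost = c(0.1, 1, 10, 100),
               gamma = unique(c(1 / p, 0.01, 0.1)),
               epsilon = c(0.01, 0.1)),
    rf = list(ntree = c(100L, 300L), maxnodes = c(NA, 16L, 64L))
  )
}

fit_one <- function(model, params, X, y) {
  if (model == "svr") {
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
               cost = params$cost, gamma = params$gamma,
               epsilon = params$epsilon, scale = TRUE)
  } else {  # rf
    mx <- if (is.na(params$maxnodes)) NULL else params$maxnodes
    randomForest::randomForest(x = X, y = y, ntree = params$ntree,
                               maxnodes = mx)
  }
}

#' Grid-searched, cross-validated fit and test-set prediction
#'
#' Standardizes the target with a train-fitted z-score scaler, grid-searches
#' the model's hyperparameters by k-fold CV RMSE on the training set, refits
#' the best candidate on the full training set and returns test predictions
#' inverse-transformed to mg/g. All randomness (folds, RF bootstrap) is
#' governed by `seed`.
#'
#' @param spec A [regressor_spec()].
#' @param X_train,y_train Training spectra and response (mg/g).
#' @param X_test Test spectra.
#' @param cv_folds CV folds (default 10).
#' @param seed Integer seed.
#' @return List `predictions` (test, mg/g), `best_params`, `cv_rmse`
#'   (best candidate, standardized units), `scaler`.
#' @export
fit_predict <- function(spec, X_train, y_train, X_test, cv_folds = 10L,
                        seed = 1L) {
  stopifnot(inherits(spec, "regressor_spec"))
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  n <- nrow(X_train); p <- ncol(X_train)
  scaler <- target_scaler(y_train)
  ys <- scale_target(scaler, y_train)
  grid <- spec$grid
  if (is.null(grid)) grid <- default_grid(spec$model, p)
  set.seed(seed)

  if (spec$model == "plsr") {
    ncomps <- grid$ncomp
    cv <- pls_cv_rmse(X_train, ys, max_ncomp = max(ncomps), folds = cv_folds)
    ncomps <- ncomps[ncomps <= length(cv$rmse)]  # rank-limited candidates
    best_ncomp <- ncomps[which.min(cv$rmse[ncomps])]
    fit <- pls_fit(X_train, ys, best_ncomp)
    pred_s <- predict(fit, X_test, ncomp = min(best_ncomp, fit$ncomp))[, 1]
    best <- list(ncomp = best_ncomp)
    cv_rmse <- cv$rmse[best_ncomp]
  } else {
    cand <- expand.grid(grid, stringsAsFactors = FALSE)
    fold <- cv_folds(n, cv_folds)
    cv_rmse_all <- vapply(seq_len(nrow(cand)), function(ci) {
      params <- as.list(cand[ci, , drop = FALSE])
      sq <- numeric(n)
      for (f in sort(unique(fold))) {
        tr <- fold != f
        m <- fit_one(spec$model, params, X_train[tr, , drop = FALSE], ys[tr])
        sq[!tr] <- (predict(m, X_train[!tr, , drop = FALSE]) - ys[!tr])^2
      }
      sqrt(mean(sq))
    }, numeric(1))
    bi <- which.min(cv_rmse_all)
    best <- as.list(cand[bi, , drop = FALSE])
    set.seed(seed + 1L)
    fit <- fit_one(spec$model, best, X_train, ys)
    pred_s <- as.numeric(predict(fit, X_test))
    cv_rmse <- cv_rmse_all[bi]
  }
  list(predictions = unscale_target(scaler, pred_s),
       best_params = best, cv_rmse = cv_rmse, scaler = scaler,
       model = spec$model)
}
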