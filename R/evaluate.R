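# Prediction-set evaluation: R2p, RMSEP and RPD.
#
# Note on the RPD definition: the relation RPD = 1/sqrt(1 - R2p) (equivalent
# to SD/RMSEP when R2 is computed about the prediction-set mean) is the one
# that reproduces every internally consistent printed (R2, RPD) pair in the
# nutrient-prediction literature this pipeline follows; a form without the
# square root does not. This package therefore defines RPD with the square
# root. RPD > 2 conventionally indicates a usable calibration.

#' RPD from a coefficient of determination
#'
#' `1 / sqrt(1 - r2)`; returns `Inf` for `r2 >= 1`. Negative `r2` is allowed
#' (RPD < 1, a model worse than the mean).
#'
#' @param r2 Prediction-set coefficient of determination.
#' @return Residual predictive deviation (dimensionless).
#' @examples
#' rpd_from_r2(0.75)  # exactly 2
#' @export
rpd_from_r2 <- function(r2) {
  stopifnot(is.numeric(r2), all(is.finite(r2)))
  ifelse(r2 >= 1, Inf, 1 / sqrt(1 - r2))
}

#' Evaluate predictions on the test set
#'
#' `R2p = 1 - SS_residual / SS_total` with `SS_total` about the test-set
#' mean; `RMSEP = sqrt(mean((yhat - y)^2))`; `RPD = 1/sqrt(1 - R2p)`
#' (`Inf` when predictions are perfect).
#'
#' @param y_true Observed values (length >= 2, nonzero variance).
#' @param y_pred Predicted values, same length.
#' @return `eval_result`: list `r2p`, `rmsep`, `rpd`, `n`.
#' @export
evaluate <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2,
            all(is.finite(y_true)), all(is.finite(y_pred)))
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) stop("`y_true` has zero variance", call. = FALSE)
  ss_res <- sum((y_pred - y_true)^2)
  r2 <- 1 - ss_res / ss_tot
  structure(list(r2p = r2,
                 rmsep = sqrt(mean((y_pred - y_true)^2)),
                 rpd = rpd_from_r2(r2),
                 n = length(y_true)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n=%d  R2p=%.4f  RMSEP=%.4f  RPD=%s\n",
              x$n, x$r2p, x$rmsep,
              if (is.finite(x$rpd)) sprintf("%.4f", x$rpd) else "Inf"))
  invisible(x)
}

#' Relative change between two prediction R2p values
#'
#' The ablation report's formula for "the original model's best R2p was x%
#' lower": `(r2_full - r2_reduced) / r2_full`, returned as a percentage.
#'
#' @param r2_full R2p of the full (176-band) variant.
#' @param r2_reduced R2p of the reduced (31-band) variant.
#' @return Percent decrease (positive when the reduced variant is worse).
#' @export
percent_decrease <- function(r2_full, r2_reduced) {
  100 * (r2_full - r2_reduced) / r2_full
}
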