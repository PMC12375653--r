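# Spectral preprocessing: multiplicative scatter correction (MSC) and the
# first derivative (D1), plus their combination. MSC is fitted on training
# spectra only (its reference is the training mean) and then applied to both
# splits, mirroring how the regression stage must not see the test set.

#' Fit a multiplicative scatter correction model
#'
#' The reference is the mean training spectrum; each spectrum `s` is later
#' regressed on the reference `r` (`s ~ a + b r`, ordinary least squares)
#' and corrected to `(s - a) / b`, which exactly inverts per-sample affine
#' (multiplicative + offset) scatter.
#'
#' @param train_spectra Matrix of training spectra (rows = samples), >= 2
#'   rows.
#' @return `msc_model` with the reference spectrum.
#' @export
msc_fit <- function(train_spectra) {
  stopifnot(is.matrix(train_spectra) || inherits(train_spectra, "spectra_matrix"))
  if (nrow(train_spectra) < 2) stop("MSC needs >= 2 training spectra", call. = FALSE)
  structure(list(reference = colMeans(train_spectra)), class = "msc_model")
}

#' Apply multiplicative scatter correction
#'
#' @param model An [msc_fit()] model.
#' @param spectra Matrix of spectra with the same band count as the
#'   reference.
#' @return Corrected matrix (attributes preserved). A spectrum whose slope
#'   against the reference is ~0 cannot be corrected and raises an error.
#' @export
msc_apply <- function(model, spectra) {
  stopifnot(inherits(model, "msc_model"))
  r <- model$reference
  if (ncol(spectra) != length(r)) stop("band count mismatch", call. = FALSE)
  rc <- r - mean(r)
  denom <- sum(rc^2)
  out <- spectra
  for (i in seq_len(nrow(spectra))) {
    s <- spectra[i, ]
    b <- sum((s - mean(s)) * rc) / denom
    if (!is.finite(b) || abs(b) < 1e-8) {
      stop(sprintf("row %d is flat against the MSC reference", i), call. = FALSE)
    }
    a <- mean(s) - b * mean(r)
    out[i, ] <- (s - a) / b
  }
  out
}

#' First-derivative preprocessing
#'
#' Derivative of reflectance with respect to wavelength: central differences
#' in the interior, one-sided at the edges (length preserved), so constant
#' baselines map to zero and additive offsets are removed. A Savitzky-Golay
#' alternative (window 5, polynomial order 2) is available via
#' `method = "sg"`.
#'
#' @param spectra Matrix of spectra (rows = samples).
#' @param wavelengths Band-center wavelengths; taken from the `grid`
#'   attribute when omitted.
#' @param method `"central"` (default) or `"sg"`.
#' @return Matrix of derivative spectra (per-nm units), attributes
#'   preserved.
#' @export
d1 <- function(spectra, wavelengths = NULL, method = c("central", "sg")) {
  method <- match.arg(method)
  if (is.null(wavelengths)) {
    grid <- attr(spectra, "grid")
    if (is.null(grid)) stop("supply `wavelengths` or a grid attribute", call. = FALSE)
    wavelengths <- grid$values
  }
  p <- ncol(spectra)
  stopifnot(p >= 3, length(wavelengths) == p)
  out <- spectra
  if (method == "central") {
    for (i in seq_len(nrow(spectra))) {
      s <- spectra[i, ]
      ds <- numeric(p)
      ds[1] <- (s[2] - s[1]) / (wavelengths[2] - wavelengths[1])
      ds[p] <- (s[p] - s[p - 1]) / (wavelengths[p] - wavelengths[p - 1])
      ds[2:(p - 1)] <- (s[3:p] - s[1:(p - 2)]) /
        (wavelengths[3:p] - wavelengths[1:(p - 2)])
      out[i, ] <- ds
    }
  } else {
    h <- mean(diff(wavelengths))
    for (i in seq_len(nrow(spectra))) {
      out[i, ] <- signal::sgolayfilt(spectra[i, ], p = 2, n = 5, m = 1) / h
    }
  }
  out
}

#' Preprocessing method dispatcher
#'
#' `"raw"` is the identity; `"msc"` scatter-corrects; `"d1"` differentiates;
#' `"d1_msc"` differentiates first and then scatter-corrects (an MSC model
#' fitted on differentiated training spectra). Any state (the MSC reference)
#' is fitted on the training split only.
#'
#' @param method One of `"raw"`, `"msc"`, `"d1"`, `"d1_msc"`.
#' @param train,test Spectra matrices (test may be `NULL`).
#' @param wavelengths Optional wavelengths for [d1()].
#' @return List `train`, `test` (preprocessed), `method`, `state`.
#' @export
preprocess <- function(method, train, test = NULL, wavelengths = NULL) {
  method <- match.arg(tolower(method), c("raw", "msc", "d1", "d1_msc"))
  state <- NULL
  if (method == "raw") {
    out_train <- train; out_test <- test
  } else if (method == "msc") {
    state <- msc_fit(train)
    out_train <- msc_apply(state, train)
    out_test <- if (!is.null(test)) msc_apply(state, test)
  } else if (method == "d1") {
    out_train <- d1(train, wavelengths)
    out_test <- if (!is.null(test)) d1(test, wavelengths)
  } else {
    dtr <- d1(train, wavelengths)
    dte <- if (!is.null(test)) d1(test, wavelengths)
    state <- msc_fit(dtr)
    out_train <- msc_apply(state, dtr)
    out_test <- if (!is.null(dte)) msc_apply(state, dte)
  }
  list(train = out_train, test = out_test, method = method, state = state)
}

#' All preprocessing method labels
#' @export
preprocess_methods <- function() c("raw", "msc", "d1", "d1_msc")
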