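# ROI masking and mean-spectrum extraction: one reflectance vector per
# sample, then cropping to the 450-950 nm analysis window (the noisy grid
# edges 400-450 and 950-1000 nm are excluded before regression).

#' Threshold a cube into a foreground mask
#'
#' A pixel is foreground when its mean reflectance over the NIR plateau
#' (750--900 nm) exceeds `tau`; vegetation is bright there while the black
#' background board is not, which makes the rule robust to visible-range
#' variation. Connected components smaller than `min_size` pixels are
#' removed (8-connectivity).
#'
#' @param cube A [hypercube()].
#' @param tau Reflectance threshold (default 0.15).
#' @param nir_window NIR averaging window in nm (default `c(750, 900)`).
#' @param min_size Minimum component size in pixels (default 5).
#' @return Logical `H x W` matrix; errors if no pixel passes.
#' @export
foreground_mask <- function(cube, tau = 0.15, nir_window = c(750, 900),
                            min_size = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  idx <- band_index_range(cube$grid, nir_window[1], nir_window[2])
  nir_mean <- apply(cube$reflectance[, , idx, drop = FALSE], c(1, 2), mean)
  mask <- nir_mean > tau
  if (!any(mask)) {
    stop(sprintf("no pixel exceeds tau = %g in the %g-%g nm window",
                 tau, nir_window[1], nir_window[2]), call. = FALSE)
  }
  if (min_size > 1L && !all(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    keep <- as.integer(names(which(table(lab[lab > 0]) >= min_size)))
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    if (!any(mask)) {
      stop("all foreground components smaller than `min_size`", call. = FALSE)
    }
  }
  mask
}

#' Mean spectrum over a mask
#'
#' Per-band arithmetic mean of the masked pixels; with the instrument grid
#' this is the per-sample 176-value array entering the regression stage.
#'
#' @param cube A [hypercube()].
#' @param mask Logical `H x W` matrix with at least one `TRUE`.
#' @return Numeric vector of length `cube$grid$n_bands` with the grid
#'   attached as attribute `grid`.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"), is.logical(mask))
  d <- dim(cube$reflectance)
  if (!identical(dim(mask), d[1:2])) {
    stop("mask shape does not match cube", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  out <- colMeans(flat[as.vector(mask), , drop = FALSE])
  attr(out, "grid") <- cube$grid
  out
}

#' Assemble a spectra matrix from cubes and masks
#'
#' @param cubes List of [hypercube()]s on a common grid.
#' @param masks List of logical masks, one per cube.
#' @param sample_ids Row names (default `S001`, ...).
#' @return `spectra_matrix`: an `n x bands` matrix with the grid attached.
#' @export
spectra_matrix <- function(cubes, masks,
                           sample_ids = sprintf("S%03d", seq_along(cubes))) {
  stopifnot(length(cubes) == length(masks), length(cubes) >= 1)
  grid <- cubes[[1]]$grid
  mat <- t(vapply(seq_along(cubes), function(i) {
    as.numeric(mean_spectrum(cubes[[i]], masks[[i]]))
  }, numeric(grid$n_bands)))
  rownames(mat) <- sample_ids
  colnames(mat) <- sprintf("wl_%.1f", grid$values)
  attr(mat, "grid") <- grid
  class(mat) <- c("spectra_matrix", class(mat))
  mat
}

#' Crop a spectra matrix to a wavelength window
#'
#' Retains bands whose centers lie in `[lo_nm, hi_nm]`; the default window
#' 450--950 nm keeps 146 of the 176 instrument bands. Idempotent.
#'
#' @param spectra `spectra_matrix` (or plain matrix with a `grid` attribute).
#' @param lo_nm,hi_nm Window edges (defaults 450 and 950).
#' @return Cropped `spectra_matrix` with an updated `grid` attribute holding
#'   the retained wavelengths in `values`.
#' @export
crop_window <- function(spectra, lo_nm = 450, hi_nm = 950) {
  grid <- attr(spectra, "grid")
  if (is.null(grid)) stop("spectra matrix lacks a `grid` attribute", call. = FALSE)
  idx <- band_index_range(grid, lo_nm, hi_nm)
  out <- spectra[, idx, drop = FALSE]
  sub <- grid
  sub$values <- grid$values[idx]
  sub$n_bands <- length(idx)
  sub$lo_nm <- sub$values[1]
  sub$hi_nm <- sub$values[length(idx)]
  attr(out, "grid") <- sub
  class(out) <- c("spectra_matrix", "matrix", "array")
  out
}

#' Wavelengths of a spectra matrix
#' @param spectra A `spectra_matrix`.
#' @return Numeric vector of band-center wavelengths (nm).
#' @export
spectra_wavelengths <- function(spectra) {
  grid <- attr(spectra, "grid")
  if (is.null(grid)) stop("spectra matrix lacks a `grid` attribute", call. = FALSE)
  grid$values
}

#' Write a spectra matrix as CSV
#'
#' Header `sample_id, wl_<nm>, ...`, one row per sample.
#' @param spectra A `spectra_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(sample_id = rownames(spectra),
                   as.data.frame(unclass(spectra)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
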