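# Reconstruction quality metrics: MRAE (also the training loss), RMSE, PSNR,
# per-band relative-error heatmaps, and the Gaussian-blur robustness probe.

as_values <- function(x) if (inherits(x, "hypercube")) x$reflectance else x

check_same_shape <- function(a, b) {
  da <- dim(as_values(a)); db <- dim(as_values(b))
  if (is.null(da)) da <- length(as_values(a))
  if (is.null(db)) db <- length(as_values(b))
  if (!identical(da, db)) stop("shape mismatch between inputs", call. = FALSE)
}

#' Mean relative absolute error
#'
#' `mean(|reconstructed - truth| / max(truth, eps))` over all pixels and
#' bands. The denominator guard `eps` matters wherever the truth is
#' near zero (the black background board); it is reported alongside results.
#'
#' @param truth,recon [hypercube()]s or arrays of identical shape (truth
#'   first, matching the metric's reference role).
#' @param eps Denominator clamp, > 0 (default 1e-3).
#' @return Dimensionless scalar >= 0.
#' @export
mrae <- function(truth, recon, eps = 1e-3) {
  check_same_shape(truth, recon)
  stopifnot(eps > 0)
  g <- as_values(truth); r <- as_values(recon)
  mean(abs(r - g) / pmax(g, eps))
}

#' Root mean square error
#'
#' @inheritParams mrae
#' @return Scalar in reflectance units.
#' @export
rmse <- function(truth, recon) {
  check_same_shape(truth, recon)
  g <- as_values(truth); r <- as_values(recon)
  sqrt(mean((g - r)^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / rmse^2)` in dB; `rmse == 0` returns `Inf`.
#'
#' @param rmse_value RMSE (>= 0).
#' @param peak Signal ceiling (> 0), default 1 for reflectance.
#' @return PSNR in dB.
#' @export
psnr <- function(rmse_value, peak = 1.0) {
  if (!is.finite(peak) || peak <= 0) stop("`peak` must be > 0", call. = FALSE)
  if (!is.finite(rmse_value) || rmse_value < 0) {
    stop("`rmse_value` must be >= 0", call. = FALSE)
  }
  if (rmse_value == 0) return(Inf)
  10 * log10(peak^2 / rmse_value^2)
}

#' All three reconstruction metrics for a cube pair
#'
#' @inheritParams mrae
#' @return List `mrae`, `rmse`, `psnr`, `peak`, `eps`.
#' @export
recon_metrics <- function(truth, recon, eps = 1e-3) {
  pk <- if (inherits(truth, "hypercube")) truth$peak else 1.0
  rm <- rmse(truth, recon)
  list(mrae = mrae(truth, recon, eps), rmse = rm, psnr = psnr(rm, pk),
       peak = pk, eps = eps)
}

#' Per-pixel relative-error map at one wavelength
#'
#' The per-pixel `|recon - truth| / max(truth, eps)` at the band nearest the
#' requested wavelength; its mean equals the single-band MRAE.
#'
#' @param truth,recon [hypercube()]s on the same grid.
#' @param wavelength_nm Wavelength within the grid span.
#' @param eps Denominator clamp.
#' @return List of class `error_map`: `map` (H x W), `wavelength_nm` (the
#'   band center actually used), `band`.
#' @export
error_heatmap <- function(truth, recon, wavelength_nm, eps = 1e-3) {
  stopifnot(inherits(truth, "hypercube"), inherits(recon, "hypercube"))
  check_same_shape(truth, recon)
  k <- nearest_band(truth$grid, wavelength_nm)
  g <- truth$reflectance[, , k]
  r <- recon$reflectance[, , k]
  structure(list(map = abs(r - g) / pmax(g, eps),
                 wavelength_nm = truth$grid$values[k], band = k),
            class = "error_map")
}

#' Render an error map to a PNG with a fixed color scale
#'
#' @param em An [error_heatmap()] result.
#' @param path Output PNG path.
#' @param zmax Fixed upper end of the color scale (errors are clipped to it),
#'   so maps within a figure set are comparable.
#' @return `path`, invisibly.
#' @export
write_error_heatmap_png <- function(em, path, zmax = 1.0) {
  stopifnot(inherits(em, "error_map"), zmax > 0)
  z <- pmin(em$map / zmax, 1)
  pal <- grDevices::hcl.colors(256, "Inferno")
  idx <- 1L + as.integer(round(z * 255))
  col <- grDevices::col2rgb(pal[idx]) / 255
  h <- nrow(z); w <- ncol(z)
  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(col[ch, ], h, w)
  png::writePNG(img, target = path)
  invisible(path)
}

# Gaussian blur with the kernel-size -> sigma convention used by standard
# image libraries: sigma = 0.3 * ((k - 1) * 0.5 - 1) + 0.8. Separable,
# replicate-padded.
gaussian_kernel_1d <- function(ksize) {
  stopifnot(ksize >= 1, ksize %% 2 == 1)
  if (ksize == 1) return(1)
  sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  x <- seq(-(ksize - 1) / 2, (ksize - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

blur_matrix <- function(m, kern) {
  if (length(kern) == 1) return(m)
  r <- (length(kern) - 1L) / 2L
  pad_idx <- function(n) pmin(pmax(seq(1L - r, n + r), 1L), n)
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(kern)) {
    out <- out + kern[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
  }
  mp <- out[, pad_idx(ncol(m)), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(kern)) {
    out <- out + kern[i] * mp[, i:(i + ncol(m) - 1L), drop = FALSE]
  }
  out
}

#' Gaussian-blur a rectangular region of an image
#'
#' @param img `H x W x C` array (an RGB image).
#' @param ksize Odd kernel size; 1 is the identity.
#' @param region `c(row1, row2, col1, col2)` or `NULL` for the whole image.
#' @return Blurred array of the same shape.
#' @export
blur_region <- function(img, ksize, region = NULL) {
  stopifnot(length(dim(img)) == 3L, ksize %% 2 == 1, ksize >= 1)
  d <- dim(img)
  if (is.null(region)) region <- c(1L, d[1], 1L, d[2])
  if (region[1] < 1 || region[2] > d[1] || region[3] < 1 || region[4] > d[2] ||
      region[1] > region[2] || region[3] > region[4]) {
    stop("blur region outside image", call. = FALSE)
  }
  kern <- gaussian_kernel_1d(ksize)
  out <- img
  for (ch in seq_len(d[3])) {
    blurred <- blur_matrix(img[, , ch], kern)
    out[region[1]:region[2], region[3]:region[4], ch] <-
      blurred[region[1]:region[2], region[3]:region[4]]
  }
  out
}

central_region <- function(h, w, frac = 0.5) {
  rh <- max(1L, round(h * frac)); rw <- max(1L, round(w * frac))
  r1 <- floor((h - rh) / 2) + 1L; c1 <- floor((w - rw) / 2) + 1L
  c(r1, r1 + rh - 1L, c1, c1 + rw - 1L)
}

#' Gaussian-blur robustness probe
#'
#' Blurs the central region of the RGB input with increasing kernel sizes,
#' reconstructs each blurred image with the trained visible/NIR model pair,
#' and reports the mean MRAE over the blurred region (kernel size 1 is the
#' unblurred baseline and is always prepended).
#'
#' @param vis_model,nir_model Trained models from [train_recon()].
#' @param rgb `H x W x 3` input image.
#' @param truth Ground-truth [hypercube()].
#' @param sizes Odd, increasing kernel sizes (default `c(5, 15, 25, 35)`).
#' @param region_frac Side fraction of the central square region (default
#'   0.5).
#' @param eps MRAE denominator clamp.
#' @return Data frame `ksize`, `mrae` of class `blur_probe`, with the region
#'   stored as an attribute.
#' @export
blur_probe <- function(vis_model, nir_model, rgb, truth,
                       sizes = c(5, 15, 25, 35), region_frac = 0.5,
                       eps = 1e-3) {
  stopifnot(all(sizes %% 2 == 1), all(diff(sizes) > 0))
  d <- dim(rgb)
  region <- central_region(d[1], d[2], region_frac)
  sub <- function(cube) {
    cube$reflectance[region[1]:region[2], region[3]:region[4], , drop = FALSE]
  }
  truth_sub <- sub(truth)
  res <- vapply(c(1, sizes), function(k) {
    rec <- reconstruct(vis_model, nir_model, blur_region(rgb, k, region))
    mrae(truth_sub, sub(rec), eps)
  }, numeric(1))
  out <- data.frame(ksize = c(1, sizes), mrae = res)
  attr(out, "region") <- region
  class(out) <- c("blur_probe", class(out))
  out
}
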