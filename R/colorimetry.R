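# Colorimetric rendering: reflectance cube -> CIE XYZ -> sRGB under D65.
#
# The CIE 1931 2-degree color matching functions are evaluated from the
# published multi-lobe piecewise-Gaussian analytic fit (accurate to about 1%
# of peak); the D65 relative spectral power distribution is a condensed 10 nm
# table, linearly interpolated. Both are zero outside 380-780 nm, which is
# what makes near-infrared radiance invisible to the rendered RGB.
# Tristimulus integration is white-point anchored per channel: a perfect
# (unit-reflectance) diffuser maps exactly to the D65 white point
# (0.95047, 1, 1.08883), so approximation error in the tables cannot tint
# neutral surfaces; the Y channel normalization coincides with the standard
# k = 1/sum(S*ybar*dl) luminance normalizer.

piecewise_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 2-degree color matching functions
#'
#' @param wavelength_nm Numeric vector of wavelengths.
#' @return Matrix with columns `xbar`, `ybar`, `zbar`; zero outside
#'   380--780 nm, clipped to be nonnegative.
#' @export
cie_cmf <- function(wavelength_nm) {
  l <- wavelength_nm
  xbar <- 1.056 * piecewise_gauss(l, 599.8, 37.9, 31.0) +
          0.362 * piecewise_gauss(l, 442.0, 16.0, 26.7) -
          0.065 * piecewise_gauss(l, 501.1, 20.4, 26.2)
  ybar <- 0.821 * piecewise_gauss(l, 568.8, 46.9, 40.5) +
          0.286 * piecewise_gauss(l, 530.9, 16.3, 31.1)
  zbar <- 1.217 * piecewise_gauss(l, 437.0, 11.8, 36.0) +
          0.681 * piecewise_gauss(l, 459.0, 26.0, 13.8)
  out <- cbind(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0),
               zbar = pmax(zbar, 0))
  out[l < 380 | l > 780, ] <- 0
  out
}

# condensed D65 relative SPD, 380-780 nm at 10 nm (approximate standard table)
.d65_wl <- seq(380, 780, by = 10)
.d65_val <- c(
  49.98, 54.65, 82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81, 114.86,
  115.92, 108.81, 109.35, 107.80, 104.79, 107.69, 104.41, 104.05, 100.00,
  96.33, 95.79, 88.69, 90.01, 89.60, 87.70, 83.29, 83.70, 80.03, 80.21,
  82.28, 78.28, 69.72, 71.61, 74.35, 61.60, 69.89, 75.09, 63.59, 46.42,
  66.81, 63.38
)

#' Illuminant D65 relative spectral power
#'
#' @param wavelength_nm Numeric vector of wavelengths.
#' @return Relative SPD (100 at 560 nm); zero outside 380--780 nm.
#' @export
d65_spd <- function(wavelength_nm) {
  out <- stats::approx(.d65_wl, .d65_val, xout = wavelength_nm,
                       yleft = 0, yright = 0)$y
  out[!is.finite(out)] <- 0
  out
}

#' D65 white point in CIE XYZ (Y = 1)
#' @export
d65_white <- c(X = 0.95047, Y = 1.0, Z = 1.08883)

# per-band tristimulus weights on a grid; columns X, Y, Z
tristimulus_weights <- function(grid) {
  cmf <- cie_cmf(grid$values)
  spd <- d65_spd(grid$values)
  w <- cmf * spd * grid$step_nm
  sums <- colSums(w)
  if (any(sums <= 0)) {
    stop("wavelength grid does not overlap the visible range (380-780 nm)",
         call. = FALSE)
  }
  sweep(w, 2L, sums, "/") %*% diag(d65_white)
}

#' Tristimulus rendering of a reflectance cube under D65
#'
#' Integrates `reflectance * D65 * CMF` per pixel. Unit reflectance maps to
#' the D65 white point exactly (Y = 1); reflectance confined to wavelengths
#' above 780 nm contributes nothing.
#'
#' @param cube A [hypercube()] whose grid overlaps 380--780 nm.
#' @return `H x W x 3` array of X, Y, Z.
#' @export
cube_to_xyz <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$reflectance)
  w <- tristimulus_weights(cube$grid)
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  array(flat %*% w, dim = c(d[1], d[2], 3L))
}

# linear sRGB primaries, D65 white (IEC 61966-2-1)
.xyz_to_srgb_mat <- matrix(c(
   3.2406, -1.5372, -0.4986,
  -0.9689,  1.8758,  0.0415,
   0.0557, -0.2040,  1.0570
), nrow = 3, byrow = TRUE)

srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' Convert a tristimulus image to sRGB
#'
#' @param xyz `H x W x 3` XYZ array (or length-3 vector).
#' @param encode Apply the sRGB transfer curve (default `TRUE`); with
#'   `FALSE` the output is linear-light sRGB. Out-of-gamut values are hard
#'   clipped to `[0, 1]`.
#' @return `rgb_image`: `H x W x 3` array in `[0, 1]` with an `encoding`
#'   attribute (`"sRGB"` or `"linear"`).
#' @export
xyz_to_rgb <- function(xyz, encode = TRUE) {
  vec_in <- is.null(dim(xyz))
  if (vec_in) xyz <- array(xyz, dim = c(1L, 1L, 3L))
  d <- dim(xyz)
  stopifnot(length(d) == 3L, d[3] == 3L, all(is.finite(xyz)))
  flat <- matrix(xyz, d[1] * d[2], 3L)
  rgb <- flat %*% t(.xyz_to_srgb_mat)
  rgb <- pmin(pmax(rgb, 0), 1)
  if (encode) rgb <- srgb_encode(rgb)
  out <- array(rgb, dim = d)
  structure(out, encoding = if (encode) "sRGB" else "linear",
            class = c("rgb_image", class(out)))
}

#' Render an RGB image from a hyperspectral cube
#'
#' Composition of [cube_to_xyz()] and [xyz_to_rgb()]; the reconstruction
#' network's input is exactly this rendering.
#'
#' @inheritParams cube_to_xyz
#' @inheritParams xyz_to_rgb
#' @return An `rgb_image`.
#' @export
render_rgb <- function(cube, encode = TRUE) {
  xyz_to_rgb(cube_to_xyz(cube), encode = encode)
}

#' Write / read an RGB image as 8-bit PNG
#'
#' @param img `rgb_image` (values in `[0, 1]`).
#' @param path PNG file path.
#' @return `path` (write) / an `H x W x 3` array in `[0,1]` (read).
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(pmin(pmax(unclass(img), 0), 1), target = path)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_rgb_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L && dim(arr)[3] > 3L) arr <- arr[, , 1:3]  # drop alpha
  arr
}
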