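#' Uniform wavelength grid
#'
#' Construct a uniform, endpoint-inclusive grid of band-center wavelengths.
#' The instrument grid used throughout the pipeline is 176 bands over
#' 400--1000 nm, i.e. a step of 600/175 nm (reported as "3.4 nm" resolution);
#' the 31-band 400--700 nm grid of the original visible-range reconstruction
#' models (10 nm step) is expressed on the same footing.
#'
#' @param n_bands Number of bands (>= 2).
#' @param lo_nm Wavelength of the first band center, nm.
#' @param hi_nm Wavelength of the last band center, nm (> `lo_nm`).
#' @return An object of class `wavelength_grid`: a list with `n_bands`,
#'   `lo_nm`, `hi_nm`, `step_nm` and `values` (band centers, nm).
#' @examples
#' g <- make_wavelength_grid(176, 400, 1000)
#' g$step_nm            # 600/175 = 3.42857...
#' g$values[c(88, 89)]  # band centers straddling the visible/NIR split
#' @export
make_wavelength_grid <- function(n_bands, lo_nm, hi_nm) {
  if (length(n_bands) != 1L || !is.finite(n_bands) || n_bands < 2 ||
      n_bands != round(n_bands)) {
    stop("`n_bands` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.finite(lo_nm) || !is.finite(hi_nm) || hi_nm <= lo_nm) {
    stop("need finite wavelengths with `hi_nm` > `lo_nm`", call. = FALSE)
  }
  n_bands <- as.integer(n_bands)
  step <- (hi_nm - lo_nm) / (n_bands - 1L)
  values <- lo_nm + step * (seq_len(n_bands) - 1L)
  values[n_bands] <- hi_nm  # exact endpoint regardless of rounding
  structure(
    list(n_bands = n_bands, lo_nm = lo_nm, hi_nm = hi_nm,
         step_nm = step, values = values),
    class = "wavelength_grid"
  )
}

#' The 176-band 400--1000 nm instrument grid
#'
#' Convenience constructor for the default analysis grid.
#' @return A [make_wavelength_grid()] object with 176 bands over 400--1000 nm.
#' @export
instrument_grid <- function() make_wavelength_grid(176L, 400, 1000)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %.6g-%.6g nm, step %.6g nm\n",
              x$n_bands, x$lo_nm, x$hi_nm, x$step_nm))
  invisible(x)
}

#' Band indices whose centers fall in a wavelength window
#'
#' Returns the 1-based indices of all bands with center wavelength inside the
#' closed interval `[lo_nm, hi_nm]`. Used e.g. to crop spectra to the
#' 450--950 nm analysis window (146 bands on the instrument grid) and to
#' address the 400--700 nm visible half (88 bands).
#'
#' @param grid A `wavelength_grid`.
#' @param lo_nm,hi_nm Window edges in nm, `lo_nm < hi_nm`.
#' @return Integer vector of band indices (1-based, contiguous).
#' @export
band_index_range <- function(grid, lo_nm, hi_nm) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (!is.finite(lo_nm) || !is.finite(hi_nm) || lo_nm >= hi_nm) {
    stop("need `lo_nm` < `hi_nm`", call. = FALSE)
  }
  idx <- which(grid$values >= lo_nm & grid$values <= hi_nm)
  if (length(idx) == 0L) {
    stop(sprintf("no band centers in [%g, %g] nm", lo_nm, hi_nm),
         call. = FALSE)
  }
  idx
}

#' Index of the band whose center is nearest a wavelength
#' @param grid A `wavelength_grid`.
#' @param wavelength_nm Target wavelength, must lie within the grid span.
#' @return Single band index.
#' @export
nearest_band <- function(grid, wavelength_nm) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (!is.finite(wavelength_nm) || wavelength_nm < grid$lo_nm ||
      wavelength_nm > grid$hi_nm) {
    stop("wavelength outside grid span", call. = FALSE)
  }
  which.min(abs(grid$values - wavelength_nm))
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_bands == b$n_bands && abs(a$lo_nm - b$lo_nm) < tol &&
    abs(a$hi_nm - b$hi_nm) < tol
}
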