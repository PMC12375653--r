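#' Hyperspectral reflectance cube
#'
#' A cube is an `H x W x B` array of reflectance values (dimensionless,
#' nominally in `[0, peak]`) with an attached [make_wavelength_grid()] grid.
#' Coordinates follow the (row, col) = (height, width) convention.
#'
#' @param reflectance Numeric `H x W x B` array.
#' @param grid `wavelength_grid` with `n_bands == B`.
#' @param peak Signal ceiling used by PSNR; default 1 for reflectance.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(reflectance, grid, peak = 1.0) {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3L) {
    stop("`reflectance` must be a 3-d array (H x W x B)", call. = FALSE)
  }
  stopifnot(inherits(grid, "wavelength_grid"))
  if (dim(reflectance)[3] != grid$n_bands) {
    stop(sprintf("cube has %d bands but grid has %d",
                 dim(reflectance)[3], grid$n_bands), call. = FALSE)
  }
  if (!all(is.finite(reflectance))) {
    stop("reflectance contains non-finite values", call. = FALSE)
  }
  if (!is.finite(peak) || peak <= 0) stop("`peak` must be > 0", call. = FALSE)
  out <- structure(
    list(reflectance = reflectance, grid = grid, peak = peak),
    class = "hypercube"
  )
  if (any(reflectance > peak)) {
    # tolerated (specular pixels can exceed the nominal ceiling) but flagged
    attr(out, "over_peak") <- sum(reflectance > peak)
  }
  out
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hypercube> %d x %d px, %d bands (%g-%g nm), peak %g\n",
              d[1], d[2], d[3], x$grid$lo_nm, x$grid$hi_nm, x$peak))
  if (!is.null(attr(x, "over_peak"))) {
    cat(sprintf("  note: %d values exceed peak\n", attr(x, "over_peak")))
  }
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$reflectance)

# ---- ENVI-style I/O ---------------------------------------------------------
# Plain-text .hdr (samples/lines/bands/data type/interleave/wavelength list)
# next to a raw little-endian binary. Only BSQ interleave and IEEE double
# (data type 5) / float (4) are supported; that is all the pipeline writes.

#' Write a cube as an ENVI-style header + raw binary pair
#'
#' @param cube A [hypercube()].
#' @param path Path of the binary file; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param data_type 5 (double, default) or 4 (single precision).
#' @return `path`, invisibly.
#' @export
write_cube_envi <- function(cube, path, data_type = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  if (!data_type %in% c(4L, 5L)) stop("data_type must be 4 or 5", call. = FALSE)
  d <- dim(cube$reflectance)
  hdr <- c(
    "ENVI",
    "description = {needlespec reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    "interleave = bsq",
    "byte order = 0",
    sprintf("wavelength units = Nanometers"),
    sprintf("reflectance peak = %.17g", cube$peak),
    sprintf("wavelength = {%s}",
            paste(sprintf("%.10f", cube$grid$values), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-sequential; within a band ENVI stores row-major (line by line)
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- aperm(cube$reflectance, c(2L, 1L, 3L))  # (W, H, B): W fastest = row-major
  writeBin(as.vector(vals), con,
           size = if (data_type == 5L) 8L else 4L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*([0-9]+)"), txt))[[1]]
    if (length(m) < 2) NA_integer_ else as.integer(m[2])
  }
  wl_m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  peak_m <- regmatches(txt,
                       regexec("reflectance peak\\s*=\\s*([0-9.eE+-]+)", txt))[[1]]
  list(
    samples = get_num("samples"), lines = get_num("lines"),
    bands = get_num("bands"), data_type = get_num("data type"),
    wavelengths = if (length(wl_m) >= 2) {
      as.numeric(strsplit(wl_m[2], ",")[[1]])
    } else NULL,
    peak = if (length(peak_m) >= 2) as.numeric(peak_m[2]) else 1.0
  )
}

#' Read a cube written by [write_cube_envi()]
#'
#' @param path Path of the binary file (header at `paste0(path, ".hdr")`).
#' @return A [hypercube()]. Errors on header/binary size mismatch or a
#'   missing wavelength list.
#' @export
read_cube_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path, call. = FALSE)
  if (!file.exists(path)) stop("missing ENVI binary: ", path, call. = FALSE)
  h <- parse_envi_header(hdr_path)
  if (anyNA(c(h$samples, h$lines, h$bands))) {
    stop("ENVI header lacks samples/lines/bands", call. = FALSE)
  }
  if (is.null(h$wavelengths)) {
    stop("ENVI header lacks a wavelength list", call. = FALSE)
  }
  if (length(h$wavelengths) != h$bands) {
    stop("ENVI wavelength list length does not match band count", call. = FALSE)
  }
  size <- if (identical(h$data_type, 4L)) 4L else 8L
  n <- h$samples * h$lines * h$bands
  if (file.info(path)$size != n * size) {
    stop(sprintf("ENVI binary holds %d bytes but header implies %d",
                 file.info(path)$size, n * size), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = size, endian = "little")
  arr <- aperm(array(vals, dim = c(h$samples, h$lines, h$bands)), c(2L, 1L, 3L))
  wl <- h$wavelengths
  grid <- make_wavelength_grid(h$bands, wl[1], wl[h$bands])
  hypercube(arr, grid, peak = h$peak)
}

# ---- archive I/O ------------------------------------------------------------

#' Write/read a cube in the package archive format
#'
#' A compressed single-file container (serialized list of reflectance array,
#' grid parameters and metadata) used for fast fixtures and intermediate
#' artifacts; ENVI remains the interchange format.
#'
#' @param cube A [hypercube()].
#' @param path File path (conventionally `.nsc`).
#' @param metadata Optional list stored alongside the cube.
#' @return `path` (write) / a [hypercube()] with a `metadata` attribute (read).
#' @export
write_cube_archive <- function(cube, path, metadata = list()) {
  stopifnot(inherits(cube, "hypercube"))
  saveRDS(list(format = "needlespec-cube", version = 1L,
               reflectance = cube$reflectance,
               grid = list(n_bands = cube$grid$n_bands, lo_nm = cube$grid$lo_nm,
                           hi_nm = cube$grid$hi_nm),
               peak = cube$peak, metadata = metadata),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_cube_archive
#' @export
read_cube_archive <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "needlespec-cube")) {
    stop("not a needlespec cube archive: ", path, call. = FALSE)
  }
  cube <- hypercube(obj$reflectance,
                    make_wavelength_grid(obj$grid$n_bands, obj$grid$lo_nm,
                                         obj$grid$hi_nm),
                    peak = obj$peak)
  attr(cube, "metadata") <- obj$metadata
  cube
}
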