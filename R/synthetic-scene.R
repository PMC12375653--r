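# Synthetic pine-canopy scenes.
#
# Labeled stand-in for canopy imagery of potted pine seedlings on a black
# background board: thin needle-like strokes carrying a vegetation-shaped
# reflectance spectrum (chlorophyll absorption wells, green peak, red edge
# near 715 nm, NIR plateau), with nutrient-dependent absorption depths
# planted in the literature's N/P/K-sensitive wavelength windows so that
# band selection and regression have a recoverable ground truth.
# Per-sample multiplicative/additive scatter gives MSC a correctable
# distortion; per-pixel Gaussian noise emulates sensor noise.

#' Nutrient sensitivity windows (nm)
#'
#' Wavelength windows reported in the literature as sensitive to needle
#' nitrogen, phosphorus and potassium; the generator plants its
#' nutrient-dependent absorption in exactly these windows.
#' @return Named list of two-column matrices (`lo`, `hi`).
#' @export
nutrient_windows <- function() {
  list(
    N = cbind(lo = c(510, 670, 910, 985), hi = c(540, 690, 920, 995)),
    P = cbind(lo = c(575, 620, 670, 685, 965),
              hi = c(585, 635, 685, 700, 975)),
    K = cbind(lo = c(505, 555, 590, 685, 920, 950),
              hi = c(515, 570, 605, 700, 930, 965))
  )
}

#' Needle endmember reflectance model
#'
#' Parametric needle spectrum: a visible floor plus a green-peak Gaussian at
#' 550 nm, a red-edge logistic rise to the NIR plateau, fixed chlorophyll
#' absorption Gaussians (460 and 650 nm), and per-nutrient absorption depths
#' applied inside [nutrient_windows()], linear in the min-max-scaled label.
#' Nitrogen additionally deepens the chlorophyll wells and flattens the
#' green peak (the chlorophyll--nitrogen correlation), so higher nitrogen
#' strictly lowers visible (450--600 nm) reflectance.
#'
#' @param depth_scale Multiplier on all nutrient depth coefficients; 0 turns
#'   the nutrient signal off (the spectrum is then the baseline exactly).
#' @param label_ranges Calibrated label ranges (mg/g) used for min-max
#'   scaling; defaults to [default_label_ranges()].
#' @return An object of class `endmember_model`.
#' @export
endmember_model <- function(depth_scale = 1.0,
                            label_ranges = default_label_ranges()) {
  structure(list(
    visible_floor = 0.10,
    green_amp = 0.08, green_center = 550, green_sd = 25,
    nir_plateau = 0.45, rededge_center = 715, rededge_width = 12,
    chl_centers = c(460, 650), chl_sd = c(20, 25), chl_depth = c(0.05, 0.05),
    windows = nutrient_windows(),
    # per-window depths (reflectance units at full-scale label), 0.03-0.08
    depths = list(
      N = depth_scale * c(0.08, 0.06, 0.05, 0.04),
      P = depth_scale * c(0.05, 0.04, 0.04, 0.03, 0.05),
      K = depth_scale * c(0.06, 0.05, 0.05, 0.03, 0.06, 0.05)
    ),
    # nitrogen-chlorophyll coupling: extra well depth and green-peak loss
    n_chl_depth = depth_scale * c(0.05, 0.05),
    n_green_loss = depth_scale * 0.03,
    label_ranges = label_ranges,
    clip = c(0.005, 0.95)
  ), class = "endmember_model")
}

#' Default nutrient label sampling ranges (mg/g)
#'
#' The phosphorus range 0.8--1.6 mg/g follows the reported typical needle
#' concentration; nitrogen and potassium ranges are generator defaults
#' (assumptions, not estimates of any field study).
#' @export
default_label_ranges <- function() {
  list(N = c(8, 25), P = c(0.8, 1.6), K = c(4, 12))
}

# raised-cosine bump: 1 at window center, 0 at and beyond the edges
window_bump <- function(wl, lo, hi) {
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  ifelse(abs(wl - mid) <= half, 0.5 * (1 + cos(pi * (wl - mid) / half)), 0)
}

scale01 <- function(x, range) {
  u <- (x - range[1]) / (range[2] - range[1])
  min(max(u, 0), 1)
}

#' Noiseless needle spectrum for a given nutrient label
#'
#' @param labels Named list/vector with `N`, `P`, `K` in mg/g.
#' @param model An [endmember_model()].
#' @param grid Wavelength grid (default [instrument_grid()]).
#' @return Numeric reflectance vector on `grid`, clipped to `[0.005, 0.95]`.
#' @export
needle_spectrum <- function(labels, model = endmember_model(),
                            grid = instrument_grid()) {
  stopifnot(inherits(model, "endmember_model"))
  wl <- grid$values
  base <- model$visible_floor +
    model$green_amp * exp(-(wl - model$green_center)^2 / (2 * model$green_sd^2)) +
    model$nir_plateau /
      (1 + exp(-(wl - model$rededge_center) / model$rededge_width)) -
    model$chl_depth[1] * exp(-(wl - model$chl_centers[1])^2 / (2 * model$chl_sd[1]^2)) -
    model$chl_depth[2] * exp(-(wl - model$chl_centers[2])^2 / (2 * model$chl_sd[2]^2))
  u <- vapply(c("N", "P", "K"), function(q) {
    scale01(as.numeric(labels[[q]]), model$label_ranges[[q]])
  }, numeric(1))
  spec <- base
  for (q in c("N", "P", "K")) {
    w <- model$windows[[q]]
    dep <- model$depths[[q]]
    for (i in seq_len(nrow(w))) {
      spec <- spec - u[[q]] * dep[i] * window_bump(wl, w[i, "lo"], w[i, "hi"])
    }
  }
  # nitrogen-chlorophyll coupling
  spec <- spec -
    u[["N"]] * model$n_chl_depth[1] *
      exp(-(wl - model$chl_centers[1])^2 / (2 * model$chl_sd[1]^2)) -
    u[["N"]] * model$n_chl_depth[2] *
      exp(-(wl - model$chl_centers[2])^2 / (2 * model$chl_sd[2]^2)) -
    u[["N"]] * model$n_green_loss *
      exp(-(wl - model$green_center)^2 / (2 * model$green_sd^2))
  pmin(pmax(spec, model$clip[1]), model$clip[2])
}

#' Scene generator configuration
#'
#' @param height,width Image size in pixels (>= 16).
#' @param stroke_count Number of needle strokes per scene (>= 1).
#' @param background Flat background reflectance (black board), default 0.02.
#' @param scatter_mult Range of the per-sample multiplicative scatter factor.
#' @param scatter_add Range of the per-sample additive offset.
#' @param noise_sd Per-pixel, per-band Gaussian noise sd, default 0.005.
#' @param label_ranges Nutrient sampling ranges, see [default_label_ranges()].
#' @param seed Integer seed fixing the whole dataset.
#' @return `scene_config` list.
#' @export
scene_config <- function(height = 64, width = 64, stroke_count = 40,
                         background = 0.02,
                         scatter_mult = c(0.8, 1.2),
                         scatter_add = c(-0.02, 0.02),
                         noise_sd = 0.005,
                         label_ranges = default_label_ranges(),
                         seed = 1L) {
  stopifnot(height >= 16, width >= 16, stroke_count >= 1,
            background >= 0, noise_sd >= 0,
            scatter_mult[1] <= scatter_mult[2],
            scatter_add[1] <= scatter_add[2])
  structure(list(height = height, width = width, stroke_count = stroke_count,
                 background = background, scatter_mult = scatter_mult,
                 scatter_add = scatter_add, noise_sd = noise_sd,
                 label_ranges = label_ranges, seed = as.integer(seed)),
            class = "scene_config")
}

#' Needle-stroke foreground mask
#'
#' Rasterizes thin elongated strokes (random center, orientation and length)
#' until the requested count is drawn; additional strokes are appended if the
#' foreground fraction falls below 0.1 (bounded retries). Errors if the
#' fraction cannot be brought into `[0.1, 0.6]`.
#'
#' @param height,width Mask size (>= 16).
#' @param stroke_count Number of strokes (>= 1).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Logical `height x width` matrix.
#' @export
needle_mask <- function(height, width, stroke_count, seed = NULL) {
  if (height < 16 || width < 16) stop("mask must be at least 16 x 16", call. = FALSE)
  if (stroke_count < 1) stop("`stroke_count` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(FALSE, height, width)
  draw_stroke <- function(mask) {
    cy <- stats::runif(1, 1, height)
    cx <- stats::runif(1, 1, width)
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.3, 0.7) * min(height, width)
    thick <- sample(c(1L, 1L, 2L), 1L)  # mostly 1 px wide
    t <- seq(-len / 2, len / 2, by = 0.5)
    ys <- round(cy + t * sin(ang))
    xs <- round(cx + t * cos(ang))
    for (o in seq_len(thick) - 1L) {
      yy <- ys + o
      ok <- yy >= 1 & yy <= height & xs >= 1 & xs <= width
      mask[cbind(yy[ok], xs[ok])] <- TRUE
    }
    mask
  }
  for (i in seq_len(stroke_count)) mask <- draw_stroke(mask)
  tries <- 0L
  while (mean(mask) < 0.1 && tries < 10L * stroke_count) {
    mask <- draw_stroke(mask)
    tries <- tries + 1L
  }
  frac <- mean(mask)
  if (frac < 0.1 || frac > 0.6) {
    stop(sprintf("foreground fraction %.3f outside [0.1, 0.6]", frac),
         call. = FALSE)
  }
  mask
}

#' Render one labeled scene cube
#'
#' Foreground pixels carry the sample's [needle_spectrum()] times a single
#' per-sample multiplicative scatter factor, plus a per-sample additive
#' offset and per-pixel Gaussian noise; background is the flat board
#' reflectance plus noise. Values are clipped to `[0, 1]`.
#'
#' @param mask Logical foreground mask.
#' @param labels Named `N`, `P`, `K` values (mg/g).
#' @param model An [endmember_model()].
#' @param config A [scene_config()].
#' @param grid Wavelength grid (default [instrument_grid()]).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A [hypercube()].
#' @export
render_cube <- function(mask, labels, model = endmember_model(),
                        config = scene_config(), grid = instrument_grid(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- nrow(mask); w <- ncol(mask); b <- grid$n_bands
  spec <- needle_spectrum(labels, model, grid)
  m <- stats::runif(1, config$scatter_mult[1], config$scatter_mult[2])
  a <- stats::runif(1, config$scatter_add[1], config$scatter_add[2])
  arr <- array(config$background, dim = c(h, w, b))
  fg <- which(mask)  # linear indices within an H x W slice
  if (length(fg) > 0) {
    fg_vals <- outer(rep(1, length(fg)), spec * m + a)
    for (k in seq_len(b)) arr[fg + (k - 1L) * h * w] <- fg_vals[, k]
  }
  if (config$noise_sd > 0) {
    arr <- arr + stats::rnorm(length(arr), 0, config$noise_sd)
  }
  hypercube(pmin(pmax(arr, 0), 1), grid)
}

#' Generate a labeled synthetic dataset
#'
#' Samples nutrient labels uniformly in the configured ranges and renders one
#' cube + mask per sample. The whole dataset is a pure function of
#' `(config, config$seed)`.
#'
#' @param n_samples Number of samples (>= 10).
#' @param config A [scene_config()].
#' @param model An [endmember_model()] (its label ranges are taken from
#'   `config`).
#' @param grid Wavelength grid.
#' @return List with `cubes` (list of [hypercube()]), `masks` (list of
#'   logical matrices), `labels` (data.frame `sample_id, N_mg_g, P_mg_g,
#'   K_mg_g`), `config`, `model`, `grid`.
#' @export
generate_dataset <- function(n_samples, config = scene_config(),
                             model = endmember_model(label_ranges = config$label_ranges),
                             grid = instrument_grid()) {
  if (n_samples < 10) stop("`n_samples` must be >= 10", call. = FALSE)
  set.seed(config$seed)
  r <- config$label_ranges
  labels <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    N_mg_g = stats::runif(n_samples, r$N[1], r$N[2]),
    P_mg_g = stats::runif(n_samples, r$P[1], r$P[2]),
    K_mg_g = stats::runif(n_samples, r$K[1], r$K[2]),
    stringsAsFactors = FALSE
  )
  cubes <- vector("list", n_samples)
  masks <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    masks[[i]] <- needle_mask(config$height, config$width, config$stroke_count)
    cubes[[i]] <- render_cube(
      masks[[i]],
      list(N = labels$N_mg_g[i], P = labels$P_mg_g[i], K = labels$K_mg_g[i]),
      model, config, grid
    )
  }
  list(cubes = cubes, masks = masks, labels = labels,
       config = config, model = model, grid = grid)
}

#' Write a dataset to disk
#'
#' One archive cube per sample plus `labels.csv` and a `manifest.yaml`
#' recording the configuration and seed.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param format `"archive"` (default) or `"envi"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("archive", "envi")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$cubes)) {
    id <- dataset$labels$sample_id[i]
    if (format == "archive") {
      write_cube_archive(dataset$cubes[[i]], file.path(dir, paste0(id, ".nsc")))
    } else {
      write_cube_envi(dataset$cubes[[i]], file.path(dir, paste0(id, ".raw")))
    }
  }
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  yaml::write_yaml(list(
    n_samples = nrow(dataset$labels), format = format,
    config = unclass(cfg)[setdiff(names(cfg), "label_ranges")],
    label_ranges = cfg$label_ranges
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
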