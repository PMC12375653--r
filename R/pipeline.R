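# End-to-end orchestration: simulate -> render RGB -> train/reconstruct ->
# extract spectra -> preprocess -> (CARS) -> regress -> report. A single
# global seed fans out to per-stage seeds by fixed offsets so any stage can
# be re-run in isolation.

#' Pipeline configuration
#'
#' @param n_samples Scenes to simulate (default 120).
#' @param scene A [scene_config()]; its seed is overridden by the fan-out.
#' @param n_feat Reconstruction feature channels (desk default 8).
#' @param train A [train_config()] for both half models.
#' @param recon_train_images Training images used for the reconstruction
#'   stage (drawn from the regression training split; default 24).
#' @param models Regression back ends to run (default `"plsr"`; add
#'   `"svr"`, `"rf"` for the full comparison).
#' @param preprocess Preprocessing methods (default all four).
#' @param split_ratio Train fraction of the regression split (default 0.8).
#' @param do_recon Train/apply the reconstruction branch (default TRUE).
#' @param do_cars Run CARS band selection per nutrient (default FALSE).
#' @param cars A [cars_config()].
#' @param crop Analysis window in nm (default `c(450, 950)`).
#' @param seed Global seed.
#' @return `pipeline_config`.
#' @export
pipeline_config <- function(n_samples = 120L, scene = scene_config(),
                            n_feat = 8L, train = train_config(),
                            recon_train_images = 24L,
                            models = "plsr",
                            preprocess = preprocess_methods(),
                            split_ratio = 0.8,
                            do_recon = TRUE, do_cars = FALSE,
                            cars = cars_config(), crop = c(450, 950),
                            seed = 1L) {
  structure(list(n_samples = as.integer(n_samples), scene = scene,
                 n_feat = as.integer(n_feat), train = train,
                 recon_train_images = as.integer(recon_train_images),
                 models = models, preprocess = preprocess,
                 split_ratio = split_ratio, do_recon = do_recon,
                 do_cars = do_cars, cars = cars, crop = crop,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# fixed per-stage seed offsets (global seed + offset, kept below 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, split = 211L, train_vis = 307L,
               train_nir = 401L, regress = 503L, cars = 601L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Regression comparison over preprocess x model x nutrient
#'
#' Fits every requested combination on one spectra source and evaluates on
#' the test split; the layout mirrors the ground-truth-vs-reconstructed
#' comparison table of the analysis.
#'
#' @param spectra Cropped `spectra_matrix` (all samples).
#' @param labels Label data frame (`N_mg_g`, `P_mg_g`, `K_mg_g`).
#' @param split A [make_split()] result.
#' @param source Label for the `spectra_source` column.
#' @param models,preprocess Character vectors of back ends / methods.
#' @param seed Seed for CV folds and stochastic learners.
#' @return Data frame `nutrient, spectra_source, preprocess, model, r2p,
#'   rmsep, rpd, best_params`.
#' @export
regress_table <- function(spectra, labels, split, source = "ground_truth",
                          models = "plsr",
                          preprocess = preprocess_methods(), seed = 1L) {
  wl <- spectra_wavelengths(spectra)
  rows <- list()
  for (pp in preprocess) {
    prep <- preprocess(pp,
                       train = spectra[split$train, , drop = FALSE],
                       test = spectra[split$test, , drop = FALSE],
                       wavelengths = wl)
    for (nutrient in c("N", "P", "K")) {
      y <- labels[[paste0(nutrient, "_mg_g")]]
      for (mdl in models) {
        fp <- fit_predict(regressor_spec(mdl), prep$train, y[split$train],
                          prep$test, seed = seed)
        ev <- evaluate(y[split$test], fp$predictions)
        rows[[length(rows) + 1L]] <- data.frame(
          nutrient = nutrient, spectra_source = source, preprocess = pp,
          model = mdl, r2p = ev$r2p, rmsep = ev$rmsep, rpd = ev$rpd,
          best_params = paste(names(fp$best_params),
                              unlist(fp$best_params),
                              sep = "=", collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

train_half_models <- function(rgb_list, cubes, train_images, n_feat,
                              tconf, seed) {
  halves <- lapply(train_images, function(i) split_bands(cubes[[i]]))
  n_out <- halves[[1]]$vis$grid$n_bands
  fit_half <- function(half, tag, sd) {
    prs <- lapply(seq_along(train_images), function(j) {
      list(rgb = rgb_list[[train_images[j]]],
           target = halves[[j]][[half]]$reflectance)
    })
    cfg <- recon_config(n_feat = n_feat, n_out = n_out, seed = sd)
    tc <- tconf; tc$seed <- sd
    train_recon(build_recon(cfg), prs, tc, band_half = tag)
  }
  list(vis = fit_half("vis", "vis", stage_seed(seed, "train_vis")),
       nir = fit_half("nir", "nir", stage_seed(seed, "train_nir")))
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return `run_report`: list with `labels`, `split`, `spectra_gt`,
#'   `spectra_recon` (cropped matrices), `regression` (combined table),
#'   `recon_metrics` (per-sample MRAE/RMSE/PSNR), `cars` (per-nutrient
#'   selections, if requested), `models` (trained half models), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  scene <- config$scene
  scene$seed <- stage_seed(config$seed, "simulate")
  say("stage simulate: %d scenes (%dx%d)", config$n_samples,
      scene$height, scene$width)
  ds <- generate_dataset(config$n_samples, scene)

  say("stage render-rgb")
  rgb_list <- lapply(ds$cubes, function(cb) unclass(render_rgb(cb)))

  say("stage extract-spectra (ground truth)")
  masks <- lapply(ds$cubes, foreground_mask)
  sp_gt <- spectra_matrix(ds$cubes, masks, ds$labels$sample_id)

  split <- make_split(config$n_samples, config$split_ratio,
                      stage_seed(config$seed, "split"))

  models <- NULL; sp_recon <- NULL; rc_metrics <- NULL
  if (config$do_recon) {
    n_train_img <- min(config$recon_train_images, length(split$train))
    train_images <- split$train[seq_len(n_train_img)]
    say("stage train-recon: %d images, %d iterations x2 halves",
        n_train_img, config$train$iterations)
    models <- train_half_models(rgb_list, ds$cubes, train_images,
                                config$n_feat, config$train, config$seed)
    say("stage reconstruct + extract-spectra (reconstructed)")
    rec_spectra <- matrix(0, config$n_samples, ds$grid$n_bands)
    met <- vector("list", config$n_samples)
    for (i in seq_len(config$n_samples)) {
      rec <- reconstruct(models$vis, models$nir, rgb_list[[i]], ds$grid)
      rec_spectra[i, ] <- mean_spectrum(rec, masks[[i]])
      m <- recon_metrics(ds$cubes[[i]], rec)
      met[[i]] <- data.frame(sample_id = ds$labels$sample_id[i],
                             mrae = m$mrae, rmse = m$rmse, psnr = m$psnr,
                             in_test = i %in% split$test)
    }
    rownames(rec_spectra) <- ds$labels$sample_id
    colnames(rec_spectra) <- colnames(sp_gt)
    attr(rec_spectra, "grid") <- ds$grid
    class(rec_spectra) <- class(sp_gt)
    sp_recon <- rec_spectra
    rc_metrics <- do.call(rbind, met)
  }

  say("stage predict-nutrients")
  crop_gt <- crop_window(sp_gt, config$crop[1], config$crop[2])
  tab <- regress_table(crop_gt, ds$labels, split, "ground_truth",
                       config$models, config$preprocess,
                       stage_seed(config$seed, "regress"))
  crop_recon <- NULL
  if (!is.null(sp_recon)) {
    crop_recon <- crop_window(sp_recon, config$crop[1], config$crop[2])
    tab <- rbind(tab,
                 regress_table(crop_recon, ds$labels, split, "reconstructed",
                               config$models, config$preprocess,
                               stage_seed(config$seed, "regress")))
  }

  cars_out <- NULL
  if (config$do_cars) {
    say("stage cars")
    cc <- config$cars
    cc$seed <- stage_seed(config$seed, "cars")
    cars_out <- lapply(c(N = "N", P = "P", K = "K"), function(q) {
      res <- cars_select(crop_gt[split$train, , drop = FALSE],
                         ds$labels[[paste0(q, "_mg_g")]][split$train], cc)
      res$wavelengths <- spectra_wavelengths(crop_gt)[res$selected]
      res
    })
  }

  structure(list(
    labels = ds$labels, split = split,
    spectra_gt = crop_gt, spectra_recon = crop_recon,
    regression = tab, recon_metrics = rc_metrics,
    cars = cars_out, models = models,
    manifest = list(config = unclass(config)[setdiff(names(unclass(config)),
                                                     c("scene", "train", "cars"))],
                    scene = unclass(scene),
                    train = unclass(config$train),
                    seed = config$seed)
  ), class = "run_report")
}

# linear interpolation matrix mapping spectra on old_wl to new_wl
interp_matrix <- function(old_wl, new_wl) {
  W <- matrix(0, length(old_wl), length(new_wl))
  for (j in seq_along(new_wl)) {
    x <- new_wl[j]
    if (x <= old_wl[1]) { W[1, j] <- 1; next }
    n_old <- length(old_wl)
    if (x >= old_wl[n_old]) { W[n_old, j] <- 1; next }
    hi <- which(old_wl >= x)[1]
    lo <- hi - 1L
    t <- (x - old_wl[lo]) / (old_wl[hi] - old_wl[lo])
    W[lo, j] <- 1 - t; W[hi, j] <- t
  }
  W
}

#' Resample a cube onto another wavelength grid
#'
#' Per-pixel linear interpolation along the spectral axis; used to derive
#' the 31-band (400--700 nm) variant from the same 176-band scenes.
#'
#' @param cube A [hypercube()].
#' @param new_grid Target [make_wavelength_grid()].
#' @return A [hypercube()] on `new_grid`.
#' @export
resample_cube <- function(cube, new_grid) {
  stopifnot(inherits(cube, "hypercube"), inherits(new_grid, "wavelength_grid"))
  W <- interp_matrix(cube$grid$values, new_grid$values)
  d <- dim(cube$reflectance)
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  hypercube(array(flat %*% W, dim = c(d[1], d[2], new_grid$n_bands)),
            new_grid, peak = cube$peak)
}

#' Band-count ablation: 176-band pipeline vs the 31-band visible variant
#'
#' Runs the full pipeline, then derives a 31-band (400--700 nm, 10 nm step)
#' variant from the *same* scenes by spectral resampling, trains a single
#' reconstruction model on it (no visible/NIR split -- the reduced range has
#' no NIR half), and evaluates identical downstream settings. Reports both
#' regression tables and the relative change of the per-nutrient best R2p,
#' `(r2_176 - r2_31) / r2_176`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return List `full` (the 176-band `run_report`), `reduced31` (regression
#'   table of the 31-band variant), `comparison` (per-nutrient best R2p of
#'   each variant and `pct_decrease`).
#' @export
ablate_band_count <- function(config = pipeline_config(), verbose = FALSE) {
  report <- run_pipeline(config, verbose = verbose)
  say <- function(...) if (verbose) message(sprintf(...))

  # rebuild the scenes deterministically (same stage seed as run_pipeline)
  scene <- config$scene
  scene$seed <- stage_seed(config$seed, "simulate")
  ds <- generate_dataset(config$n_samples, scene)
  grid31 <- make_wavelength_grid(31L, 400, 700)
  say("ablation: resampling %d scenes to 31 bands", config$n_samples)
  cubes31 <- lapply(ds$cubes, resample_cube, new_grid = grid31)
  rgb_list <- lapply(ds$cubes, function(cb) unclass(render_rgb(cb)))
  masks <- lapply(ds$cubes, foreground_mask)
  split <- report$split

  n_train_img <- min(config$recon_train_images, length(split$train))
  train_images <- split$train[seq_len(n_train_img)]
  say("ablation: training the single 31-band model")
  prs <- lapply(train_images, function(i) {
    list(rgb = rgb_list[[i]], target = cubes31[[i]]$reflectance)
  })
  tc <- config$train; tc$seed <- stage_seed(config$seed, "train_vis")
  cfg <- recon_config(n_feat = config$n_feat, n_out = 31L,
                      seed = stage_seed(config$seed, "train_vis"))
  trained <- train_recon(build_recon(cfg), prs, tc, band_half = "vis")

  rec31 <- matrix(0, config$n_samples, 31L)
  for (i in seq_len(config$n_samples)) {
    arr <- recon_forward(trained$model, rgb_list[[i]])
    cube <- hypercube(pmax(arr, 0), grid31)
    rec31[i, ] <- mean_spectrum(cube, masks[[i]])
  }
  rownames(rec31) <- ds$labels$sample_id
  colnames(rec31) <- sprintf("wl_%.1f", grid31$values)
  attr(rec31, "grid") <- grid31
  class(rec31) <- c("spectra_matrix", "matrix", "array")
  crop31 <- crop_window(rec31, config$crop[1], min(config$crop[2], 700))
  tab31 <- regress_table(crop31, ds$labels, split, "reconstructed_31band",
                         config$models, config$preprocess,
                         stage_seed(config$seed, "regress"))

  full_best <- stats::aggregate(
    r2p ~ nutrient,
    data = report$regression[report$regression$spectra_source == "reconstructed", ],
    FUN = max)
  red_best <- stats::aggregate(r2p ~ nutrient, data = tab31, FUN = max)
  comparison <- merge(full_best, red_best, by = "nutrient",
                      suffixes = c("_176", "_31"))
  comparison$pct_decrease <- percent_decrease(comparison$r2p_176,
                                              comparison$r2p_31)
  list(full = report, reduced31 = tab31, comparison = comparison,
       model31 = trained)
}
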