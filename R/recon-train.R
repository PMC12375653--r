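# Training of the reconstruction network: band-half splitting, aligned
# patch extraction on a stride lattice, Adam optimization of the MRAE loss,
# and best-on-validation checkpointing. The visible and NIR halves are
# trained as two independent models and merged at reconstruction time.

#' Split a 176-band cube into its visible and NIR halves
#'
#' Bands 1--88 (centers <= ~698.3 nm) form the visible half, bands 89--176
#' (centers >= ~701.7 nm) the NIR half; the two 88-band halves partition the
#' grid with no overlap and no gap, and [merge_bands()] restores the cube
#' exactly.
#'
#' @param cube A [hypercube()] with an even band count (176 on the
#'   instrument grid).
#' @return List `vis`, `nir` of [hypercube()]s.
#' @export
split_bands <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  b <- cube$grid$n_bands
  if (b %% 2L != 0L) stop("band count must be even to split", call. = FALSE)
  half <- b %/% 2L
  wl <- cube$grid$values
  mk <- function(idx) {
    hypercube(cube$reflectance[, , idx, drop = FALSE],
              make_wavelength_grid(length(idx), wl[idx[1]], wl[idx[length(idx)]]),
              peak = cube$peak)
  }
  list(vis = mk(seq_len(half)), nir = mk(seq(half + 1L, b)))
}

#' @rdname split_bands
#' @param vis,nir The two half-cubes (visible first).
#' @export
merge_bands <- function(vis, nir) {
  stopifnot(inherits(vis, "hypercube"), inherits(nir, "hypercube"))
  dv <- dim(vis$reflectance); dn <- dim(nir$reflectance)
  if (!identical(dv[1:2], dn[1:2])) stop("spatial shape mismatch", call. = FALSE)
  if (vis$grid$hi_nm >= nir$grid$lo_nm) {
    stop("halves overlap in wavelength", call. = FALSE)
  }
  arr <- array(0, dim = c(dv[1], dv[2], dv[3] + dn[3]))
  arr[, , seq_len(dv[3])] <- vis$reflectance
  arr[, , dv[3] + seq_len(dn[3])] <- nir$reflectance
  hypercube(arr,
            make_wavelength_grid(dv[3] + dn[3], vis$grid$lo_nm, nir$grid$hi_nm),
            peak = vis$peak)
}

#' MRAE training loss
#'
#' Identical definition to the evaluation metric [mrae()]; exposed under
#' the loss name because the network is trained on it.
#' @inheritParams mrae
#' @param pred,target Arrays of matching shape (prediction first).
#' @export
mrae_loss <- function(pred, target, eps = 1e-3) mrae(target, pred, eps)

#' Aligned patch positions on a stride lattice
#'
#' @param height,width Image size.
#' @param patch Patch side (<= min(height, width)).
#' @param stride Lattice stride (>= 1).
#' @return Two-column matrix (`row`, `col`) of top-left corners; includes
#'   the single whole-image patch when `patch == height == width`.
#' @export
patch_lattice <- function(height, width, patch, stride) {
  if (patch > min(height, width)) stop("patch larger than image", call. = FALSE)
  stopifnot(stride >= 1)
  rows <- seq(1L, height - patch + 1L, by = stride)
  cols <- seq(1L, width - patch + 1L, by = stride)
  as.matrix(expand.grid(row = rows, col = cols))
}

#' Extract aligned RGB / half-cube patch pairs
#'
#' @param rgb `H x W x 3` array.
#' @param target `H x W x B` target array (same spatial size).
#' @param patch,stride Lattice parameters.
#' @param shuffle Shuffle patch order (uses the current RNG state).
#' @return List of `list(rgb = ..., target = ...)` patch pairs.
#' @export
extract_patches <- function(rgb, target, patch, stride, shuffle = FALSE) {
  stopifnot(identical(dim(rgb)[1:2], dim(target)[1:2]))
  lat <- patch_lattice(dim(rgb)[1], dim(rgb)[2], patch, stride)
  ord <- seq_len(nrow(lat))
  if (shuffle) ord <- sample(ord)
  lapply(ord, function(i) {
    r <- lat[i, 1]; c <- lat[i, 2]
    list(rgb = rgb[r:(r + patch - 1L), c:(c + patch - 1L), , drop = FALSE],
         target = target[r:(r + patch - 1L), c:(c + patch - 1L), , drop = FALSE])
  })
}

#' Training configuration
#'
#' Instrument-scale values (200 epochs x 1000 iterations, batch 2, learning
#' rate 1e-4, patch 128, stride 8) remain expressible; the defaults here are
#' the desk scale used throughout the synthetic study: patch 32, stride 16,
#' a few hundred to 2000 iterations, and a larger learning rate suited to
#' the small model.
#'
#' @param iterations Total training iterations (batches).
#' @param batch_size Patch pairs per iteration (default 2).
#' @param lr Adam learning rate (default 3e-3 at desk scale).
#' @param beta1,beta2 Adam moment decay rates (0.9, 0.999).
#' @param patch,stride Patch lattice (default 32 / 16).
#' @param eps_loss MRAE denominator clamp (default 1e-3).
#' @param val_frac Fraction of images held out for validation (default 0.1,
#'   at least one image when there are >= 2).
#' @param val_every Validation cadence in iterations (default 50).
#' @param seed Seed for shuffling and initialization.
#' @return `train_config`.
#' @export
train_config <- function(iterations = 1000L, batch_size = 2L, lr = 3e-3,
                         beta1 = 0.9, beta2 = 0.999, patch = 32L,
                         stride = 16L, eps_loss = 1e-3, val_frac = 0.1,
                         val_every = 50L, seed = 1L) {
  stopifnot(iterations >= 1, batch_size >= 1, lr > 0, stride >= 1, patch >= 4)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, patch = as.integer(patch),
                 stride = as.integer(stride), eps_loss = eps_loss,
                 val_frac = val_frac, val_every = as.integer(val_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_step <- function(params, lr, beta1, beta2, t, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    hw <- attr(p$val, "hw")
    p$val <- p$val - lr * (p$m / corr1) / (sqrt(p$v / corr2) + eps)
    attr(p$val, "hw") <- hw
    p$grad <- NULL
  }
  invisible(NULL)
}

snapshot_params <- function(params) lapply(params, function(p) p$val)

restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$val <- snap[[i]]
  invisible(NULL)
}

eval_pairs_mrae <- function(model, pairs, eps) {
  mean(vapply(pairs, function(pr) {
    pred <- recon_forward(model, pr$rgb)
    mrae_loss(pred, pr$target, eps)
  }, numeric(1)))
}

#' Train one band-half reconstruction model
#'
#' Adam optimization of the MRAE loss over shuffled patch pairs drawn
#' globally across all training images each epoch; a validation subset of
#' images is scored every `val_every` iterations and the best-on-validation
#' weights are the ones returned. Fully seeded; training aborts with a
#' diagnostic if the loss turns non-finite.
#'
#' @param model A [build_recon()] model (modified in place and returned).
#' @param pairs List of `list(rgb = HxWx3 array, target = HxWxB array)`
#'   image pairs for one band-half.
#' @param config A [train_config()].
#' @param band_half `"vis"` or `"nir"` tag carried on the checkpoint.
#' @param verbose Print progress.
#' @return `trained_recon`: `model`, `band_half`, `history` (data frame of
#'   iteration, training loss, validation MRAE), `best_val`, `config`.
#' @export
train_recon <- function(model, pairs, config = train_config(),
                        band_half = c("vis", "nir"), verbose = FALSE) {
  band_half <- match.arg(band_half)
  stopifnot(inherits(model, "recon_model"), length(pairs) >= 1)
  set.seed(config$seed)
  n_val <- if (length(pairs) >= 2) max(1L, round(config$val_frac * length(pairs))) else 0L
  val_idx <- if (n_val > 0) sample(length(pairs), n_val) else integer(0)
  train_idx <- setdiff(seq_along(pairs), val_idx)
  if (length(train_idx) == 0L) { train_idx <- seq_along(pairs); val_idx <- integer(0) }
  val_pairs <- pairs[val_idx]

  # global patch pool: (image, row, col) triples, reshuffled each epoch
  pool <- do.call(rbind, lapply(train_idx, function(i) {
    d <- dim(pairs[[i]]$rgb)
    lat <- patch_lattice(d[1], d[2], config$patch, config$stride)
    cbind(img = i, lat)
  }))
  params <- collect_params(model$params)
  history <- list()
  best_val <- Inf
  best_snap <- snapshot_params(params)
  cursor <- nrow(pool)  # force initial shuffle
  ord <- seq_len(nrow(pool))
  pk <- config$patch
  for (it in seq_len(config$iterations)) {
    losses <- numeric(config$batch_size)
    for (bi in seq_len(config$batch_size)) {
      if (cursor >= nrow(pool)) { ord <- sample(nrow(pool)); cursor <- 0L }
      cursor <- cursor + 1L
      pos <- pool[ord[cursor], ]
      pr <- pairs[[pos["img"]]]
      rsel <- pos["row"]:(pos["row"] + pk - 1L)
      csel <- pos["col"]:(pos["col"] + pk - 1L)
      tape <- new_tape()
      out <- recon_forward(model, pr$rgb[rsel, csel, , drop = FALSE], tape)
      tgt <- pr$target[rsel, csel, , drop = FALSE]
      tgt_mat <- matrix(tgt, length(rsel) * length(csel), dim(tgt)[3])
      loss <- nn_mrae_loss(tape, out, tgt_mat, config$eps_loss)
      losses[bi] <- loss$val[1, 1]
      tape_backward(tape, loss)
    }
    if (!all(is.finite(losses))) {
      stop(sprintf("training diverged at iteration %d (loss not finite)", it),
           call. = FALSE)
    }
    # average the accumulated batch gradients
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / config$batch_size
    adam_step(params, config$lr, config$beta1, config$beta2, it)
    do_val <- (it %% config$val_every == 0L) || it == config$iterations
    val_mrae <- NA_real_
    if (do_val && length(val_pairs) > 0) {
      val_mrae <- eval_pairs_mrae(model, val_pairs, config$eps_loss)
      if (val_mrae < best_val) {
        best_val <- val_mrae
        best_snap <- snapshot_params(params)
      }
    }
    history[[it]] <- c(iteration = it, loss = mean(losses), val = val_mrae)
    if (verbose && (it %% 50L == 0L || it == 1L)) {
      message(sprintf("[%s] iter %d  loss %.4f  val %.4f",
                      band_half, it, mean(losses), val_mrae))
    }
  }
  if (length(val_pairs) > 0) restore_params(params, best_snap) else best_val <- NA_real_
  structure(list(model = model, band_half = band_half,
                 history = as.data.frame(do.call(rbind, history)),
                 best_val = best_val, config = config),
            class = "trained_recon")
}

#' Reconstruct a full cube from RGB with a trained model pair
#'
#' Runs the visible and NIR half models on the same RGB input, concatenates
#' the two 88-band outputs along the spectral axis, clips negative
#' reflectance to zero and attaches the instrument grid.
#'
#' @param vis_model,nir_model `trained_recon` objects (or bare
#'   `recon_model`s) for the visible and NIR halves.
#' @param rgb `H x W x 3` array.
#' @param grid Full grid of the merged cube (default [instrument_grid()]).
#' @return A [hypercube()] with `2 * n_out` bands.
#' @export
reconstruct <- function(vis_model, nir_model, rgb, grid = instrument_grid()) {
  vm <- if (inherits(vis_model, "trained_recon")) vis_model$model else vis_model
  nm <- if (inherits(nir_model, "trained_recon")) nir_model$model else nir_model
  stopifnot(inherits(vm, "recon_model"), inherits(nm, "recon_model"))
  if (vm$config$n_out != nm$config$n_out) {
    stop("half models disagree on output band count", call. = FALSE)
  }
  if (2L * vm$config$n_out != grid$n_bands) {
    stop("grid band count does not match the merged output", call. = FALSE)
  }
  vis <- recon_forward(vm, rgb)
  nir <- recon_forward(nm, rgb)
  d <- dim(rgb)
  arr <- array(0, dim = c(d[1], d[2], grid$n_bands))
  arr[, , seq_len(vm$config$n_out)] <- vis
  arr[, , vm$config$n_out + seq_len(nm$config$n_out)] <- nir
  hypercube(pmax(arr, 0), grid)
}

#' Save / load a trained checkpoint
#'
#' Serialized weights + configs + band-half tag + seed.
#' @param trained A `trained_recon`.
#' @param path File path.
#' @return `path` / the restored `trained_recon`.
#' @export
save_checkpoint <- function(trained, path) {
  stopifnot(inherits(trained, "trained_recon"))
  params <- collect_params(trained$model$params)
  saveRDS(list(format = "needlespec-checkpoint",
               weights = snapshot_params(params),
               model_config = unclass(trained$model$config),
               train_config = unclass(trained$config),
               band_half = trained$band_half,
               best_val = trained$best_val,
               history = trained$history),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "needlespec-checkpoint")) {
    stop("not a needlespec checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(recon_config, obj$model_config[
    c("n_feat", "n_out", "n_rrg", "mrb_scales", "variant", "seed")])
  model <- build_recon(cfg)
  restore_params(collect_params(model$params), obj$weights)
  structure(list(model = model, band_half = obj$band_half,
                 history = obj$history, best_val = obj$best_val,
                 config = do.call(train_config, obj$train_config)),
            class = "trained_recon")
}
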