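test_that("a tiny model overfits one noiseless scene (capacity check)", {
  fx <- overfit_fixture()
  pred_vis <- recon_forward(fx$vis$model, fx$rgb)
  expect_lt(mrae_loss(pred_vis, fx$halves$vis$reflectance), 0.1)
  # merged full-cube error follows from the half-wise overfit
  rec <- reconstruct(fx$vis, fx$nir, fx$rgb)
  expect_equal(dim(rec$reflectance), c(64, 64, 176))
  expect_lt(mrae(fx$cube, rec), 0.15)
  expect_true(all(rec$reflectance >= 0))
})

test_that("training is deterministic under a fixed seed", {
  mask <- needle_mask(32, 32, 15, seed = 21)
  cube <- render_cube(mask, list(N = 15, P = 1.2, K = 8),
                      config = scene_config(height = 32, width = 32),
                      seed = 22)
  rgb <- unclass(render_rgb(cube))
  tgt <- split_bands(cube)$vis$reflectance
  tc <- train_config(iterations = 15, patch = 16, stride = 16,
                     val_frac = 0, seed = 4)
  run <- function() {
    train_recon(build_recon(recon_config(4, 88, seed = 3)),
                list(list(rgb = rgb, target = tgt)), tc, "vis")
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1$history$loss, t2$history$loss)
  expect_identical(t1$model$params$head$W$val, t2$model$params$head$W$val)
})

test_that("the best-on-validation checkpoint is retained", {
  mask <- needle_mask(32, 32, 15, seed = 31)
  cfg <- scene_config(height = 32, width = 32)
  mk_pair <- function(seed) {
    cube <- render_cube(mask, list(N = 15, P = 1.2, K = 8),
                        config = cfg, seed = seed)
    list(rgb = unclass(render_rgb(cube)),
         target = split_bands(cube)$vis$reflectance)
  }
  pairs <- lapply(31:34, mk_pair)
  tc <- train_config(iterations = 60, patch = 16, stride = 16,
                     val_frac = 0.25, val_every = 10, seed = 5)
  tr <- train_recon(build_recon(recon_config(4, 88, seed = 3)), pairs,
                    tc, "vis")
  vals <- tr$history$val[is.finite(tr$history$val)]
  expect_gt(length(vals), 1)
  expect_equal(tr$best_val, min(vals), tolerance = 1e-12)
  # the retained checkpoint is at least as good as the final epoch
  expect_lte(tr$best_val, vals[length(vals)])
})

test_that("reconstruction validates half/grid compatibility", {
  v <- build_recon(recon_config(4, 88, seed = 1))
  n <- build_recon(recon_config(4, 88, seed = 2))
  rgb <- array(0, c(32, 32, 3))
  rec <- reconstruct(v, n, rgb)
  expect_equal(dim(rec$reflectance), c(32, 32, 176))
  expect_true(all(is.finite(rec$reflectance)))
  n31 <- build_recon(recon_config(4, 31, seed = 2))
  expect_error(reconstruct(v, n31, rgb), "band count")
  expect_error(reconstruct(v, n, rgb, grid = make_wavelength_grid(31, 400, 700)),
               "grid")
})

test_that("checkpoints round-trip through disk", {
  fx <- overfit_fixture()
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fx$vis, p)
  back <- load_checkpoint(p)
  expect_identical(back$band_half, "vis")
  expect_equal(recon_forward(back$model, fx$rgb),
               recon_forward(fx$vis$model, fx$rgb), tolerance = 1e-12)
})

test_that("blur of the central region degrades reconstruction gracefully", {
  fx <- overfit_fixture()
  bp <- blur_probe(fx$vis, fx$nir, fx$rgb, fx$cube, sizes = c(5, 35))
  base <- bp$mrae[bp$ksize == 1]
  expect_lte(base, max(bp$mrae))
  # information destroyed by heavy blur on an overfit pair
  expect_gt(bp$mrae[bp$ksize == 35], base)
  expect_error(blur_probe(fx$vis, fx$nir, fx$rgb, fx$cube, sizes = c(4, 8)))
})
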