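# Shared, lazily built fixtures. Expensive objects (trained models, the
# desk-scale pipeline run) are cached so several test files can assert
# against one computation.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

random_cube <- function(h = 6, w = 5, b = 4, seed = 1, lo = 400, hi = 700) {
  set.seed(seed)
  hypercube(array(runif(h * w * b, 0.05, 0.95), c(h, w, b)),
            make_wavelength_grid(b, lo, hi))
}

# One noiseless synthetic scene plus both half models overfitted to it (the
# capacity fixture). The visible half needs only 300 patch iterations; the
# NIR half's six-fold larger foreground/background contrast makes the MRAE
# valley around "predict the board everywhere" much steeper, so it gets the
# full desk-scale schedule (2000 stochastic patch iterations to escape, then
# a short whole-image phase so padding contexts match deployment).
overfit_fixture <- function() {
  fixture("overfit", function() {
    mask <- needle_mask(64, 64, 40, seed = 11)
    cube <- render_cube(mask, list(N = 18, P = 1.2, K = 8),
                        config = scene_config(noise_sd = 0), seed = 12)
    rgb <- unclass(render_rgb(cube))
    halves <- split_bands(cube)
    vis <- train_recon(build_recon(recon_config(8, 88, seed = 1)),
                       list(list(rgb = rgb, target = halves$vis$reflectance)),
                       train_config(iterations = 300, batch_size = 2,
                                    val_frac = 0),
                       "vis")
    nir1 <- train_recon(build_recon(recon_config(8, 88, seed = 2)),
                        list(list(rgb = rgb, target = halves$nir$reflectance)),
                        train_config(iterations = 2000, batch_size = 2,
                                     val_frac = 0, seed = 2),
                        "nir")
    nir <- train_recon(nir1$model,
                       list(list(rgb = rgb, target = halves$nir$reflectance)),
                       train_config(iterations = 200, batch_size = 1,
                                    patch = 64, stride = 64, lr = 1e-3,
                                    val_frac = 0, seed = 2),
                       "nir")
    list(mask = mask, cube = cube, rgb = rgb, halves = halves,
         vis = vis, nir = nir)
  })
}

# the desk-scale end-to-end pipeline run (n = 120, 64x64, tiny network)
pipeline_fixture <- function() {
  fixture("pipeline", function() run_pipeline(pipeline_config(seed = 1L)))
}
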