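test_that("needle masks are deterministic, bounded and validated", {
  m1 <- needle_mask(64, 64, 40, seed = 0)
  m2 <- needle_mask(64, 64, 40, seed = 0)
  expect_identical(m1, m2)
  expect_error(needle_mask(64, 64, 0))
  expect_error(needle_mask(8, 8, 10))
  frac <- mean(needle_mask(128, 128, 60, seed = 1))
  expect_gte(frac, 0.1)
  expect_lte(frac, 0.6)
})

test_that("higher nitrogen strictly lowers 450-600 nm reflectance", {
  g <- instrument_grid()
  vis <- band_index_range(g, 450, 600)
  ns <- seq(8, 25, length.out = 10)
  means <- vapply(ns, function(nv) {
    mean(needle_spectrum(list(N = nv, P = 1.2, K = 8))[vis])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("needle spectra show a red edge and respect the clip range", {
  g <- instrument_grid()
  sp <- needle_spectrum(list(N = 15, P = 1.2, K = 8))
  expect_true(all(sp >= 0.005 & sp <= 0.95))
  nir <- mean(sp[band_index_range(g, 750, 950)])
  red <- mean(sp[band_index_range(g, 600, 680)])
  expect_gt(nir, 2 * red)
})

test_that("zero depth coefficients reproduce the baseline exactly", {
  m0 <- endmember_model(depth_scale = 0)
  a <- needle_spectrum(list(N = 25, P = 1.6, K = 12), m0)
  b <- needle_spectrum(list(N = 8, P = 0.8, K = 4), m0)
  expect_identical(a, b)
  # and the baseline equals the full model evaluated at the range minima
  m1 <- endmember_model()
  expect_equal(a, needle_spectrum(list(N = 8, P = 0.8, K = 4), m1),
               tolerance = 1e-12)
})

test_that("perturbing only potassium changes only the potassium windows", {
  g <- instrument_grid()
  lo <- needle_spectrum(list(N = 15, P = 1.2, K = 4))
  hi <- needle_spectrum(list(N = 15, P = 1.2, K = 12))
  changed <- which(abs(hi - lo) > 1e-12)
  w <- nutrient_windows()$K
  in_windows <- rep(FALSE, g$n_bands)
  for (i in seq_len(nrow(w))) {
    in_windows <- in_windows | (g$values > w[i, "lo"] & g$values < w[i, "hi"])
  }
  expect_true(all(changed %in% which(in_windows)))
  expect_gt(length(changed), 0)
})

test_that("noiseless rendering reproduces the needle spectrum per pixel", {
  cfg <- scene_config(noise_sd = 0, scatter_mult = c(1, 1),
                      scatter_add = c(0, 0))
  mask <- needle_mask(32, 32, 15, seed = 5)
  labels <- list(N = 20, P = 1.0, K = 6)
  cube <- render_cube(mask, labels, config = cfg, seed = 6)
  sp <- needle_spectrum(labels)
  fg <- which(mask)
  for (k in c(1, 60, 120, 176)) {
    slice <- cube$reflectance[, , k]
    expect_equal(unname(slice[fg]), rep(sp[k], length(fg)), tolerance = 1e-12)
    expect_equal(unname(slice[-fg]), rep(cfg$background, 32 * 32 - length(fg)),
                 tolerance = 1e-12)
  }
})

test_that("rendering is deterministic and noise averages out by the CLT", {
  mask <- needle_mask(64, 64, 40, seed = 7)
  labels <- list(N = 12, P = 1.4, K = 10)
  c1 <- render_cube(mask, labels, seed = 8)
  c2 <- render_cube(mask, labels, seed = 8)
  expect_identical(c1$reflectance, c2$reflectance)

  # mean foreground spectrum vs the scattered noiseless spectrum
  big_mask <- needle_mask(128, 128, 80, seed = 9)
  expect_gt(sum(big_mask), 1000)
  cfg <- scene_config(height = 128, width = 128, scatter_mult = c(1, 1),
                      scatter_add = c(0, 0))
  cube <- render_cube(big_mask, labels, config = cfg, seed = 10)
  sp <- needle_spectrum(labels)
  fg_mean <- mean_spectrum(cube, big_mask)
  expect_true(all(abs(fg_mean - sp) < 0.002))
})

test_that("generated datasets are reproducible with labels in range", {
  cfg <- scene_config(height = 32, width = 32, stroke_count = 15, seed = 7)
  d1 <- generate_dataset(12, cfg)
  d2 <- generate_dataset(12, cfg)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$cubes[[3]]$reflectance, d2$cubes[[3]]$reflectance)
  expect_identical(d1$masks[[7]], d2$masks[[7]])
  r <- cfg$label_ranges
  expect_true(all(d1$labels$N_mg_g >= r$N[1] & d1$labels$N_mg_g <= r$N[2]))
  expect_true(all(d1$labels$P_mg_g >= 0.8 & d1$labels$P_mg_g <= 1.6))
  expect_true(all(d1$labels$K_mg_g >= r$K[1] & d1$labels$K_mg_g <= r$K[2]))
  expect_error(generate_dataset(5, cfg))
})

test_that("datasets round-trip through the on-disk layout", {
  cfg <- scene_config(height = 32, width = 32, stroke_count = 15, seed = 3)
  ds <- generate_dataset(10, cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  expect_equal(lab$N_mg_g, ds$labels$N_mg_g, tolerance = 1e-12)
  back <- read_cube_archive(file.path(dir, "S004.nsc"))
  expect_identical(back$reflectance, ds$cubes[[4]]$reflectance)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$config$seed, 3)
})
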