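test_that("NIR thresholding recovers the generator's mask", {
  mask <- needle_mask(64, 64, 40, seed = 41)
  cube <- render_cube(mask, list(N = 15, P = 1.2, K = 8), seed = 42)
  fm <- foreground_mask(cube)
  jac <- sum(fm & mask) / sum(fm | mask)
  expect_gte(jac, 0.95)
  expect_error(foreground_mask(cube, tau = 2), "tau")
  # an all-foreground cube yields a full mask
  flat <- hypercube(array(0.5, c(16, 16, 176)), instrument_grid())
  expect_true(all(foreground_mask(flat)))
})

test_that("mean spectra match a brute-force masked loop", {
  cube <- random_cube(7, 6, 176, seed = 43, lo = 400, hi = 1000)
  set.seed(44)
  mask <- matrix(runif(42) > 0.5, 7, 6)
  sp <- mean_spectrum(cube, mask)
  expect_length(sp, 176)
  brute <- numeric(176)
  for (k in 1:176) {
    acc <- 0; cnt <- 0
    for (i in 1:7) for (j in 1:6) if (mask[i, j]) {
      acc <- acc + cube$reflectance[i, j, k]; cnt <- cnt + 1
    }
    brute[k] <- acc / cnt
  }
  expect_equal(as.numeric(sp), brute, tolerance = 1e-12)
  # constant foreground
  cst <- hypercube(array(0.8, c(4, 4, 176)), instrument_grid())
  expect_true(all(mean_spectrum(cst, matrix(TRUE, 4, 4)) == 0.8))
  expect_error(mean_spectrum(cube, matrix(FALSE, 7, 6)), "empty")
})

test_that("a noiseless cube reproduces the needle spectrum exactly", {
  cfg <- scene_config(noise_sd = 0, scatter_mult = c(1, 1),
                      scatter_add = c(0, 0), height = 32, width = 32)
  mask <- needle_mask(32, 32, 15, seed = 45)
  labels <- list(N = 22, P = 0.9, K = 11)
  cube <- render_cube(mask, labels, config = cfg, seed = 46)
  sp <- mean_spectrum(cube, mask)
  expect_true(all(abs(sp - needle_spectrum(labels)) < 1e-6))
})

test_that("window cropping keeps 146 bands and is idempotent", {
  cubes <- lapply(1:3, function(i) random_cube(5, 5, 176, seed = 50 + i,
                                               lo = 400, hi = 1000))
  masks <- lapply(1:3, function(i) matrix(TRUE, 5, 5))
  sp <- spectra_matrix(cubes, masks)
  expect_equal(dim(sp), c(3L, 176L))
  cr <- crop_window(sp)
  expect_equal(ncol(cr), 146)
  wl <- spectra_wavelengths(cr)
  expect_true(all(wl >= 450 & wl <= 950))
  # idempotence and the identity window
  expect_equal(unclass(crop_window(cr)), unclass(cr))
  expect_equal(unclass(crop_window(sp, 400, 1000)), unclass(sp))
  expect_error(crop_window(sp, 698.5, 701.5))
})

test_that("spectra CSVs carry wavelength-labelled columns", {
  cubes <- lapply(1:2, function(i) random_cube(4, 4, 176, seed = 60 + i,
                                               lo = 400, hi = 1000))
  sp <- spectra_matrix(cubes, lapply(1:2, function(i) matrix(TRUE, 4, 4)),
                       sample_ids = c("A", "B"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(crop_window(sp), p)
  df <- utils::read.csv(p, check.names = FALSE)
  expect_equal(df$sample_id, c("A", "B"))
  expect_equal(ncol(df), 147)
  expect_true("wl_451.4" %in% colnames(df))
  expect_true("wl_948.6" %in% colnames(df))
})
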