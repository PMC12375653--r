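test_that("CMF tables have the expected support and shape", {
  wl <- seq(350, 1000, by = 1)
  cmf <- cie_cmf(wl)
  expect_true(all(cmf >= 0))
  expect_true(all(cmf[wl < 380 | wl > 780, ] == 0))
  # luminous efficiency peaks near 555 nm
  expect_lt(abs(wl[which.max(cmf[, "ybar"])] - 555), 6)
  spd <- d65_spd(wl)
  expect_true(all(spd[wl >= 400 & wl <= 780] > 0))
  expect_true(all(spd[wl > 780] == 0))
})

test_that("unit reflectance maps to the D65 white point, zero to black", {
  g <- instrument_grid()
  xyz <- cube_to_xyz(hypercube(array(1, c(3, 2, 176)), g))
  expect_equal(as.vector(xyz[2, 2, ]), unname(d65_white), tolerance = 1e-12)
  expect_true(all(abs(xyz[, , 2] - 1) < 1e-12))  # Y = 1 at every pixel
  xyz0 <- cube_to_xyz(hypercube(array(0, c(2, 2, 176)), g))
  expect_true(all(xyz0 == 0))
  expect_error(cube_to_xyz(hypercube(array(1, c(2, 2, 4)),
                                     make_wavelength_grid(4, 800, 1000))),
               "visible")
})

test_that("XYZ to sRGB maps the white point to white and black to black", {
  w <- xyz_to_rgb(c(0.95047, 1, 1.08883), encode = FALSE)
  expect_equal(as.vector(unclass(w)), c(1, 1, 1), tolerance = 1e-3)
  expect_equal(as.vector(unclass(xyz_to_rgb(c(0, 0, 0)))), c(0, 0, 0))
})

test_that("NIR-only reflectance is invisible to the rendered RGB", {
  g <- instrument_grid()
  base <- array(runif(6 * 6 * 176, 0, 0.6), c(6, 6, 176))
  pert <- base
  nir_only <- which(g$values > 780)
  pert[, , nir_only] <- pert[, , nir_only] + runif(length(nir_only) * 36, 0, 0.3)
  r1 <- render_rgb(hypercube(base, g))
  r2 <- render_rgb(hypercube(pmin(pert, 1), g))
  expect_identical(unclass(r1), unclass(r2))
  # byte-identical PNG output (metamerism across the NIR boundary)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_rgb_png(r1, p1); write_rgb_png(r2, p2)
  expect_identical(readBin(p1, "raw", file.info(p1)$size),
                   readBin(p2, "raw", file.info(p2)$size))
})

test_that("a 550 nm spike renders green-dominant", {
  g <- instrument_grid()
  arr <- array(0, c(1, 1, 176))
  arr[, , nearest_band(g, 550)] <- 1
  rgb <- as.vector(unclass(render_rgb(hypercube(arr, g), encode = FALSE)))
  expect_gt(rgb[2], rgb[1])
  expect_gt(rgb[2], rgb[3])
})

test_that("rendering is linear before encoding and flat spectra are neutral", {
  cube <- random_cube(4, 4, 176, seed = 9, lo = 400, hi = 1000)
  half <- hypercube(cube$reflectance * 0.5, cube$grid)
  r1 <- unclass(render_rgb(cube, encode = FALSE))
  r2 <- unclass(render_rgb(half, encode = FALSE))
  expect_equal(r2, r1 * 0.5, tolerance = 1e-12)
  for (r in c(0.05, 0.4, 1)) {
    flat <- unclass(render_rgb(
      hypercube(array(r, c(1, 1, 176)), instrument_grid()), encode = FALSE))
    expect_lt(diff(range(flat)) / mean(flat), 0.01)
  }
})

test_that("PNG rendering is deterministic and round-trips at 8-bit depth", {
  cube <- random_cube(5, 5, 176, seed = 10, lo = 400, hi = 1000)
  img <- render_rgb(cube)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_rgb_png(img, p1); write_rgb_png(img, p2)
  expect_identical(readBin(p1, "raw", file.info(p1)$size),
                   readBin(p2, "raw", file.info(p2)$size))
  back <- read_rgb_png(p1)
  expect_equal(as.vector(back), as.vector(unclass(img)), tolerance = 1 / 255)
})
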