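# independent brute-force oracles, written against the plain definitions
brute_mrae <- function(g, r, eps) {
  d <- dim(g); tot <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    tot <- tot + abs(r[i, j, k] - g[i, j, k]) / max(g[i, j, k], eps)
  }
  tot / prod(d)
}
brute_rmse <- function(g, r) {
  d <- dim(g); tot <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    tot <- tot + (g[i, j, k] - r[i, j, k])^2
  }
  sqrt(tot / prod(d))
}

test_that("MRAE matches hand calculations and its ratio properties", {
  g <- array(0.5, c(2, 2, 3)); r <- array(0.55, c(2, 2, 3))
  expect_equal(mrae(g, r), 0.1, tolerance = 1e-12)
  expect_equal(mrae(g, g), 0)
  # denominator guard
  expect_equal(mrae(array(0, c(1, 1, 2)), array(0.1, c(1, 1, 2)), eps = 1e-3),
               100, tolerance = 1e-9)
  # scale equivariance
  a <- random_cube(4, 4, 4, seed = 1)$reflectance
  b <- random_cube(4, 4, 4, seed = 2)$reflectance
  expect_equal(mrae(a, b), mrae(2 * a, 2 * b), tolerance = 1e-12)
  expect_error(mrae(a, b[1:3, , ]), "shape")
})

test_that("MRAE/RMSE agree with brute-force loops to 1e-12", {
  set.seed(20)
  for (rep in 1:3) {
    g <- array(runif(8 * 8 * 4, 0.01, 1), c(8, 8, 4))
    r <- array(runif(8 * 8 * 4, 0.01, 1), c(8, 8, 4))
    expect_equal(mrae(g, r), brute_mrae(g, r, 1e-3), tolerance = 1e-12)
    expect_equal(rmse(g, r), brute_rmse(g, r), tolerance = 1e-12)
  }
  # constant offset residual
  g <- array(0.4, c(3, 3, 2))
  expect_equal(rmse(g, g + 0.05), 0.05, tolerance = 1e-12)
  expect_equal(rmse(g, g), 0)
})

test_that("PSNR follows the closed form with an infinite sentinel at zero", {
  expect_identical(psnr(0.1, 1), 20)
  expect_equal(psnr(0.05, 1), -20 * log10(0.05), tolerance = 1e-12)
  expect_equal(psnr(0.05, 1), 26.0206, tolerance = 1e-4)
  expect_identical(psnr(0, 1), Inf)
  expect_error(psnr(-0.1, 1))
  expect_error(psnr(0.1, 0))
  set.seed(21)
  for (v in runif(5, 0.001, 0.5)) {
    expect_equal(psnr(v, 1), -20 * log10(v), tolerance = 1e-12)
  }
  m <- recon_metrics(random_cube(4, 4, 4, 5), random_cube(4, 4, 4, 6))
  expect_equal(m$psnr, 10 * log10(m$peak^2 / m$rmse^2), tolerance = 1e-12)
})

test_that("error heatmaps are local and consistent with single-band MRAE", {
  g <- instrument_grid()
  truth <- random_cube(8, 8, 176, seed = 7, lo = 400, hi = 1000)
  expect_true(all(error_heatmap(truth, truth, 700)$map == 0))
  recon <- truth
  recon$reflectance[1:4, 1:4, ] <- recon$reflectance[1:4, 1:4, ] + 0.2
  em <- error_heatmap(truth, recon, 700)
  expect_true(all(em$map[1:4, 1:4] > 0))
  expect_true(all(em$map[5:8, , drop = FALSE] == 0))
  k <- em$band
  expect_equal(mean(em$map),
               mrae(truth$reflectance[, , k, drop = FALSE],
                    recon$reflectance[, , k, drop = FALSE]),
               tolerance = 1e-12)
  expect_error(error_heatmap(truth, recon, 1200))
  p <- withr::local_tempfile(fileext = ".png")
  write_error_heatmap_png(em, p)
  expect_gt(file.info(p)$size, 0)
})

test_that("gaussian blur respects the kernel-size convention", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(blur_region(img, 1), img)  # identity kernel
  b <- blur_region(img, 5)
  expect_false(identical(b, img))
  expect_equal(dim(b), dim(img))
  # a constant image is a fixed point of blurring
  cst <- array(0.3, c(12, 12, 3))
  expect_equal(blur_region(cst, 15), cst, tolerance = 1e-12)
  # blur confined to the requested region
  b2 <- blur_region(img, 5, region = c(5, 12, 5, 12))
  expect_identical(b2[1:4, , ], img[1:4, , ])
  expect_error(blur_region(img, 5, region = c(0, 12, 5, 12)))
})
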