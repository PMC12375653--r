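test_that("MSC exactly inverts affine distortions of the reference", {
  r <- needle_spectrum(list(N = 15, P = 1.2, K = 8))
  train <- rbind(r, r * 1.1 + 0.01, r * 0.9 - 0.01)
  m <- msc_fit(train)
  ref <- m$reference
  # s = 2 r + 0.1 corrects back to the reference exactly
  corr <- msc_apply(m, rbind(2 * ref + 0.1))
  expect_equal(as.numeric(corr), as.numeric(ref), tolerance = 1e-10)
  # the reference itself is a fixed point
  expect_equal(as.numeric(msc_apply(m, rbind(ref))), as.numeric(ref),
               tolerance = 1e-10)
  # random affine distortions all collapse onto the reference
  set.seed(70)
  for (i in 1:5) {
    b <- runif(1, 0.5, 2); a <- runif(1, -0.1, 0.1)
    expect_equal(as.numeric(msc_apply(m, rbind(b * ref + a))),
                 as.numeric(ref), tolerance = 1e-9)
  }
  expect_error(msc_fit(rbind(r)), ">= 2")
  expect_error(msc_apply(m, rbind(rep(0.5, length(ref)))), "flat")
})

test_that("MSC reduces between-sample scatter variance on synthetic spectra", {
  set.seed(71)
  base <- needle_spectrum(list(N = 15, P = 1.2, K = 8))
  n <- 30
  spectra <- t(vapply(1:n, function(i) {
    base * runif(1, 0.8, 1.2) + runif(1, -0.02, 0.02) + rnorm(176, 0, 1e-4)
  }, numeric(176)))
  corrected <- msc_apply(msc_fit(spectra), spectra)
  v_before <- mean(apply(spectra, 2, var))
  v_after <- mean(apply(corrected, 2, var))
  expect_lt(v_after, v_before)
})

test_that("the first derivative removes baselines and recovers slopes", {
  g <- instrument_grid()
  wl <- g$values
  const <- matrix(0.3, 2, 176)
  expect_true(all(d1(const, wl) == 0))
  lin <- rbind(0.001 * wl, 0.002 * wl)
  dl <- d1(lin, wl)
  expect_equal(dl[1, ], rep(0.001, 176), tolerance = 1e-10)
  expect_equal(dl[2, ], rep(0.002, 176), tolerance = 1e-10)
  # additive offsets vanish
  s <- matrix(needle_spectrum(list(N = 15, P = 1.2, K = 8)), 1)
  expect_equal(d1(s, wl), d1(s + 0.05, wl), tolerance = 1e-12)
  # Savitzky-Golay option stays finite and kills constants too
  expect_true(all(abs(d1(const, wl, method = "sg")) < 1e-10))
  expect_error(d1(matrix(1, 1, 2), c(1, 2)))
})

test_that("the preprocessing dispatcher respects train/test separation", {
  set.seed(72)
  wl <- instrument_grid()$values
  base <- needle_spectrum(list(N = 15, P = 1.2, K = 8))
  mk <- function(n) t(vapply(1:n, function(i) {
    base * runif(1, 0.8, 1.2) + runif(1, -0.02, 0.02)
  }, numeric(176)))
  train <- mk(10); test <- mk(4)
  expect_identical(preprocess("raw", train, test)$train, train)
  for (m in preprocess_methods()) {
    out <- preprocess(m, train, test, wavelengths = wl)
    expect_identical(dim(out$train), dim(train))
    expect_identical(dim(out$test), dim(test))
    expect_identical(out$method, m)
  }
  # the MSC state is fitted on the training split
  out <- preprocess("msc", train, test, wavelengths = wl)
  expect_equal(out$state$reference, colMeans(train))
  expect_error(preprocess("bogus", train, test))
})
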