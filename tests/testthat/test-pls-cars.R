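test_that("SIMPLS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(80)
  X <- matrix(rnorm(40 * 12), 40, 12)
  colnames(X) <- paste0("v", 1:12)
  y <- as.vector(X %*% rnorm(12)) + rnorm(40, 0, 0.3)
  fit <- pls_fit(X, y, 4)
  mo <- suppressMessages(mixOmics::pls(X, y, ncomp = 4, mode = "regression",
                                       scale = FALSE))
  for (a in 1:4) {
    pr_mo <- predict(mo, X)$predict[, 1, a]
    pr_us <- predict(fit, X, ncomp = a)[, 1]
    expect_equal(unname(pr_us), unname(pr_mo), tolerance = 1e-9)
  }
})

test_that("PLS recovers an exact linear map and truncates at rank", {
  set.seed(81)
  X <- matrix(rnorm(30 * 8), 30, 8)
  beta <- rnorm(8)
  y <- as.vector(X %*% beta) + 2
  fit <- pls_fit(X, y, 8)
  pred <- predict(fit, X, ncomp = fit$ncomp)[, 1]
  expect_equal(pred, y, tolerance = 1e-8)
  expect_equal(pls_coef(fit), beta, tolerance = 1e-8)
  # collinear X cannot support more components than its rank
  Xc <- cbind(X[, 1:3], X[, 1:3])
  fit2 <- pls_fit(Xc, as.vector(X[, 1:3] %*% rnorm(3)), 6)
  expect_lte(fit2$ncomp, 3)
})

test_that("cross-validated component choice is seeded and sensible", {
  set.seed(82)
  X <- matrix(rnorm(60 * 20), 60, 20)
  y <- as.vector(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(60, 0, 0.1)
  set.seed(7); cv1 <- pls_cv_rmse(X, y, max_ncomp = 8)
  set.seed(7); cv2 <- pls_cv_rmse(X, y, max_ncomp = 8)
  expect_identical(cv1$rmse, cv2$rmse)
  expect_lt(cv1$best_rmse, sd(y))
})

test_that("the EDF retention schedule runs from p to 2, non-increasing", {
  ns <- asNamespace("needlespec")
  for (p in c(10, 60, 146)) {
    counts <- ns$edf_counts(p, 50)
    expect_lte(counts[1], p)
    expect_equal(counts[50], 2)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("CARS is deterministic and its retained sets shrink", {
  set.seed(83)
  X <- matrix(rnorm(40 * 25), 40, 25)
  y <- as.vector(X[, c(3, 10)] %*% c(1, -1)) + rnorm(40, 0, 0.1)
  cfg <- cars_config(n_mc_runs = 20, seed = 9)
  r1 <- cars_select(X, y, cfg)
  r2 <- cars_select(X, y, cfg)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$rmsecv, r2$rmsecv)
  sizes <- vapply(r1$retained, length, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_gte(min(sizes), 2)
  expect_identical(r1$selected, r1$retained[[r1$best_run]])
  expect_error(cars_select(X[1:10, ], y[1:10], cfg), ">= 20")
})

test_that("CARS finds strongly planted variables in a single draw", {
  set.seed(84)
  n <- 120; p <- 60
  planted <- c(7, 18, 29, 41, 55)
  X <- matrix(rnorm(n * p), n, p)
  y0 <- as.vector(X[, planted] %*% c(1, -1, 0.8, 1.2, -0.9))
  y <- y0 + rnorm(n, 0, 0.05 * sd(y0))
  res <- cars_select(X, y, cars_config(n_mc_runs = 50, seed = 85))
  expect_true(all(planted %in% res$selected))
})
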