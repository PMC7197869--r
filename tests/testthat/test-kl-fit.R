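# KL feature-distribution matching and the soft-minimum estimator.

test_that("median split against own medians halves each feature", {
  set.seed(4)
  f <- data.frame(a = rnorm(400), b = runif(400), c = rexp(400))
  med <- vapply(f, median, 0)
  p1 <- median_split_joint(f, med, "a")
  expect_equal(p1, c(0.5, 0.5))
  # independent continuous features: all joint bins near uniform 2^-n,
  # cross-checked by exhaustive counting
  p3 <- median_split_joint(f, med, c("a", "b", "c"))
  expect_length(p3, 8)
  expect_equal(sum(p3), 1)
  idx_manual <- 1 + (f$a > med["a"]) + 2 * (f$b > med["b"]) +
    4 * (f$c > med["c"])
  expect_equal(p3, as.numeric(table(factor(idx_manual, levels = 1:8))) / 400)
  expect_true(all(abs(p3 - 1 / 8) < 0.07))
})

test_that("KL distance reproduces hand arithmetic and epsilon behaviour", {
  expect_equal(kl_distance(c(0.75, 0.25), c(0.5, 0.5), eps = 0),
               0.75 * log(1.5) + 0.25 * log(0.5))
  # identical distributions: tiny negative offset of order eps allowed
  k0 <- kl_distance(c(0.3, 0.7), c(0.3, 0.7))
  expect_lt(abs(k0), 1e-6)
  # empty model bin where data has mass stays finite through eps
  k <- kl_distance(c(0.5, 0.5), c(1, 0))
  expect_true(is.finite(k))
  expect_gt(k, 1)
  expect_error(kl_distance(c(1, 0), c(0.25, 0.25, 0.25, 0.25)), "mismatch")
})

test_that("soft-minimum weighting matches hand arithmetic and limits", {
  # equal distances: unweighted mean
  e <- subset_estimate(c(2, 2, 2), c(10, 20, 30))
  expect_equal(e$estimate, 20)
  # K = {1, 2}, beta = 3: weights {8/9, 1/9}
  e2 <- subset_estimate(c(1, 2), c(10, 20), beta = 3)
  expect_equal(e2$weights, c(8 / 9, 1 / 9))
  expect_equal(e2$estimate, 100 / 9)
  expect_equal(e2$se, sqrt((10 - 100 / 9)^2 * 8 / 9 + (20 - 100 / 9)^2 / 9))
  # one distance at the floor: estimate collapses onto that model
  e3 <- subset_estimate(c(1e-9, 1, 1), c(5, 50, 70))
  expect_equal(e3$estimate, 5, tolerance = 1e-6)
  expect_lt(e3$se, 1e-3)
  expect_equal(sum(e3$weights), 1, tolerance = 1e-12)
})

test_that("fit_dataset recovers the generating model on synthetic features", {
  # library of Gaussian feature clouds whose means shift along the grid;
  # the data are fresh draws from one interior grid point
  set.seed(31)
  feats <- feature_names()
  grid <- expand.grid(g_E = c(25, 50, 75), g_I = c(9, 21, 33, 45, 57))
  make_cloud <- function(g_E, g_I, n = 150) {
    mu <- c(g_E / 50, g_I / 30, (g_E + g_I) / 60, g_E * g_I / 1000,
            rep(0, 11))
    as.data.frame(setNames(lapply(seq_along(feats), function(j)
      rnorm(n, mu[j], 0.5)), feats))
  }
  lib <- list(grid = grid,
              features = lapply(seq_len(nrow(grid)), function(i)
                make_cloud(grid$g_E[i], grid$g_I[i])))
  truth <- list(g_E = 50, g_I = 33)
  data <- make_cloud(truth$g_E, truth$g_I, n = 300)
  fit <- fit_dataset(data, lib, seed = 99)
  expect_lt(abs(fit$gI - truth$g_I), 12)   # within one grid step
  expect_lt(abs(fit$gE - truth$g_E), 25)
  # estimates stay in the grid hull and weights are normalized
  expect_gte(fit$gE, min(grid$g_E)); expect_lte(fit$gE, max(grid$g_E))
  expect_gte(fit$gI, min(grid$g_I)); expect_lte(fit$gI, max(grid$g_I))
  expect_equal(sum(fit$phi_gE), 1, tolerance = 1e-12)
  # reproducibility from the seed
  fit2 <- fit_dataset(data, lib, seed = 99)
  expect_identical(fit$gE, fit2$gE)
  expect_identical(fit$kl_grid, fit2$kl_grid)
  # n_subsets = 1 equals the single-subset estimate
  fit1 <- fit_dataset(data, lib, n_subsets = 1, seed = 7)
  e <- subset_estimate(fit1$k_mat[, 1], grid$g_E, beta = 3)
  expect_equal(fit1$gE, e$estimate)
})

test_that("fit refuses undersized datasets with a size report", {
  lib <- list(grid = data.frame(g_E = 1, g_I = 1),
              features = list(data.frame()))
  small <- as.data.frame(setNames(as.list(rep(0, 15)), feature_names()))
  expect_error(fit_dataset(small, lib), "too small")
})

test_that("errors-in-both-coordinates regression behaves at its limits", {
  # exact line with tiny errors
  x <- 1:10
  f <- eiv_regression(x, 2 * x + 1, sx = 1e-6, sy = 1e-6)
  expect_equal(f$slope, 2, tolerance = 1e-6)
  expect_equal(f$intercept, 1, tolerance = 1e-5)
  expect_lt(f$p_value, 1e-10)
  # with sx = 0 it coincides with weighted ordinary least squares
  set.seed(8)
  y <- 3 * x - 2 + rnorm(10, 0, 0.5)
  w <- runif(10, 0.5, 2)
  f2 <- eiv_regression(x, y, sx = 0, sy = w)
  ls <- lm(y ~ x, weights = 1 / w^2)
  expect_equal(f2$slope, unname(coef(ls)[2]), tolerance = 1e-8)
  expect_equal(f2$se_slope,
               unname(sqrt(vcov(ls)[2, 2] / summary(ls)$sigma^2)),
               tolerance = 1e-6)
  expect_error(eiv_regression(rep(1, 5), rnorm(5)), "singular")
})

test_that("regression p-values are calibrated under the null", {
  # pure noise: p-values approximately uniform over replicates
  set.seed(123)
  ps <- replicate(400, {
    x <- rnorm(20); y <- rnorm(20)
    eiv_regression(x, y, sx = 0.1, sy = 1)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
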