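# ISI statistics battery: moments, serial correlations, local CV, ML fits.

test_that("ISI moments match hand-computed two-point values", {
  m <- isi_moments(rep(c(1, 3), 50))
  expect_equal(m$mu, 2)
  expect_equal(m$cv, 0.5)
  expect_false(m$degenerate)
  # rate is count / window, independent of ISI layout
  m2 <- isi_moments(diff(seq(0, 10, length.out = 100)), t_seg = 200,
                    n_spikes = 100)
  expect_equal(m2$rate, 0.5)
})

test_that("constant ISIs are flagged degenerate with zero CV", {
  m <- isi_moments(rep(0.5, 20))
  expect_true(m$degenerate)
  expect_equal(m$cv, 0)
  expect_true(is.na(m$rescaled_skew))
})

test_that("serial autocorrelation has the right limits", {
  # perfectly alternating sequence: rho(1) -> -1
  expect_equal(serial_autocorrelation(rep(c(1, 3), 500), 1), -1,
               tolerance = 1e-2)
  # i.i.d. ISIs: rho(n) ~ 0 at every small lag
  set.seed(7)
  x <- rexp(2e4)
  for (lag in 1:3)
    expect_lt(abs(serial_autocorrelation(x, lag)), 0.03)
  # degenerate variance -> NA
  expect_true(is.na(serial_autocorrelation(rep(1, 50), 1)))
})

test_that("local CV quintiles partition and handle the 0.5 boundary", {
  # periodic train: all mass in the first bin
  expect_equal(local_cv_quintiles(rep(2, 30)), c(1, 0, 0, 0, 0))
  # alternating {3b, b}: X = 0.5 exactly, lands in bin 3
  expect_equal(local_cv_quintiles(rep(c(3, 1), 20)), c(0, 0, 1, 0, 0))
  # partition property on arbitrary positive sequences
  set.seed(11)
  for (i in 1:20) {
    x <- rgamma(50, shape = runif(1, 0.3, 4), scale = 1)
    expect_equal(sum(local_cv_quintiles(x)), 1)
  }
})

test_that("lognormal ML estimator is exact on transformed pairs and recovers
           planted parameters", {
  f <- ml_lognormal(rep(c(exp(1), exp(3)), 20))
  expect_equal(f$mu_ln, 2)
  expect_equal(f$sigma_ln, 1)
  set.seed(3)
  x <- rlnorm(1e5, meanlog = -0.4, sdlog = 0.9)
  f2 <- ml_lognormal(x)
  # exact ML: within 3 standard errors of the planted parameters
  expect_lt(abs(f2$mu_ln + 0.4), 3 * 0.9 / sqrt(1e5))
  expect_lt(abs(f2$sigma_ln - 0.9), 3 * 0.9 / sqrt(2e5))
})

test_that("gamma shape closed form matches the digamma oracle", {
  # oracle: for gamma(shape a), E[z] = log(a) - digamma(a); the closed-form
  # approximation evaluated at that z is the large-sample limit
  shape_from_z <- function(z) (3 - z + sqrt((3 - z)^2 + 24 * z)) / (12 * z)
  expect_equal(shape_from_z(log(2) - digamma(2)), 1.992, tolerance = 1e-3)
  # Euler-Mascheroni: exponential data give shape close to 1
  expect_equal(shape_from_z(-digamma(1)), 0.9909, tolerance = 1e-3)
  set.seed(5)
  x <- rgamma(1e5, shape = 2, scale = 1.5)
  f <- ml_gamma(x)
  expect_equal(f$shape, 1.992, tolerance = 0.03)
  expect_equal(f$scale * f$shape, 3, tolerance = 0.05)   # mean preserved
  expect_equal(f$log_scale, log(f$scale))
  # constant data: degenerate, shape -> Inf
  expect_true(ml_gamma(rep(2, 10))$degenerate)
})

test_that("inverse-Gaussian ML estimator is exact", {
  # hand arithmetic: ISIs {0.5, 2}: mu = 1.25, <1/I> = 1.25, shape = 1/0.45
  f <- ml_invgauss(rep(c(0.5, 2), 10))
  expect_equal(f$shape, 1 / 0.45)
  expect_equal(f$mean, 1.25)
  set.seed(9)
  x <- statmod_rinvgauss(1e5, mu = 1, lambda = 2)
  f2 <- ml_invgauss(x)
  expect_equal(f2$shape, 2, tolerance = 0.05)
  expect_true(ml_invgauss(rep(1, 10))$degenerate)
})

test_that("feature vector has canonical form and permutation behaviour", {
  set.seed(21)
  st <- cumsum(rgamma(120, shape = 0.8, scale = 1))
  st <- st[st < 200]
  fv <- feature_vector(st, 200)
  expect_length(fv, 15)
  expect_identical(names(fv), feature_names())
  # bit-stable across calls
  expect_identical(fv, feature_vector(st, 200))
  # permuting the ISI order changes sequence statistics only
  isis <- diff(st)
  set.seed(1)
  st2 <- cumsum(c(st[1], sample(isis)))
  fv2 <- feature_vector(st2, 200)
  order_free <- c("mu", "cv", "rescaled_skew", "rate", "log_mu_gamma",
                  "sigma_gamma", "mu_ln", "sigma_ln", "sigma_ig")
  expect_equal(fv[order_free], fv2[order_free])
  expect_false(isTRUE(all.equal(fv["rho1"], fv2["rho1"])))
})

test_that("segment filters implement the inclusion rules", {
  seg <- function(n_spikes, rate = 1, skew = 1)
    list(spike_times = seq_len(n_spikes) * 0.1, t_seg = 200,
         cell_rate = rate, cell_skew = skew)
  segs <- list(seg(10), seg(50), seg(50, rate = 12), seg(50, skew = 70))
  fx <- filter_segments(segs, "experimental")
  expect_length(fx$kept, 1)
  expect_setequal(fx$log$reason,
                  c("fewer than 11 spikes", "cell rate > 10 Hz",
                    "cell skew > 60"))
  # model mode keeps high-rate cells, still drops short trains
  fm <- filter_segments(segs, "model")
  expect_length(fm$kept, 3)
  expect_identical(filter_segments(list(), "model")$kept, list())
})
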