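test_that("window fits recover a pure sinusoid exactly", {
  tr <- sinusoid_trace(A = 3, f = 100, phi0 = 0.4, B = 1, noise_sd = 0,
                       duration = 200)
  fits <- window_sine_fit(tr$value, bin = 0.1)
  expect_equal(nrow(fits), 10)
  expect_equal(fits$A, rep(3, 10), tolerance = 1e-4)
  expect_equal(fits$f_hz, rep(100, 10), tolerance = 1e-4)
  expect_equal(fits$B, rep(1, 10), tolerance = 1e-4)
  expect_true(all(fits$rmse < 1e-4))
  expect_true(all(fits$A >= 0))
})

test_that("window fits recover parameters under noise", {
  tr <- sinusoid_trace(A = 2, f = 110, phi0 = 1, B = -4, noise_sd = 0.2,
                       duration = 2000, seed = 12)
  fits <- window_sine_fit(tr$value, bin = 0.1)
  expect_equal(mean(fits$A), 2, tolerance = 0.05)
  expect_equal(mean(fits$f_hz), 110, tolerance = 0.02)
  expect_true(all(abs(fits$f_hz - 110) / 110 < 0.05))
})

test_that("constant series yields near-zero amplitude", {
  fits <- window_sine_fit(rep(2.5, 600), bin = 0.1)
  expect_true(all(fits$A < 1e-8))
})

test_that("window selection keeps clean fixtures and drops corrupted ones", {
  tr <- sinusoid_trace(A = 1, f = 100, noise_sd = 0.05, duration = 1000,
                       seed = 3)
  fits <- window_sine_fit(tr$value, bin = 0.1)
  acc <- select_windows(fits)
  expect_equal(attr(acc, "rejection_fraction"), 0)

  # corrupt 5 of 50 windows with pure white noise
  bad <- c(7, 19, 23, 31, 44)
  y <- tr$value
  set.seed(41)
  for (w in bad) y[((w - 1) * 200 + 1):(w * 200)] <- rnorm(200, sd = 1)
  fits2 <- window_sine_fit(y, bin = 0.1)
  acc2 <- select_windows(fits2)
  expect_gte(sum(!acc2[bad]), 4)       # at least 4 of 5 corrupted rejected
  expect_lte(sum(!acc2[-bad]), 3)      # few clean windows lost
})

test_that("phase leads recover constructed phase relationships", {
  dur <- 400
  v <- sinusoid_trace(A = 1, f = 100, phi0 = 0, duration = dur)
  antiphase <- sinusoid_trace(A = 2, f = 100, phi0 = pi, duration = dur)
  quarter <- sinusoid_trace(A = 2, f = 100, phi0 = -pi / 2, duration = dur)
  fv <- window_sine_fit(v$value)
  fa <- window_sine_fit(antiphase$value)
  fq <- window_sine_fit(quarter$value)
  rec <- phase_leads(fv, fa, fq)
  expect_equal(rec$dphi_syn, rep(-pi, nrow(rec)), tolerance = 1e-3)
  expect_equal(abs(rec$dphi_int + 3 * pi / 2) < 1e-3 |
                 abs(rec$dphi_int + pi / 2) < 1e-3,
               rep(TRUE, nrow(rec)))  # quarter-period lag
  expect_true(all(rec$dphi_syn <= 0 & rec$dphi_syn > -2 * pi))
})

test_that("circular-linear correlation matches its defining formula", {
  set.seed(7)
  for (rep in 1:5) {
    th <- runif(200, -pi, pi)
    x <- cos(th) + rnorm(200, sd = rep / 2)
    cl <- circ_linear_corr(th, x)
    expect_equal(cl$r, circ_linear_oracle(th, x), tolerance = 1e-12)
  }
  # exact functional dependence
  th <- runif(100, -pi, pi)
  expect_equal(circ_linear_corr(th, cos(th))$r, 1, tolerance = 1e-9)
  expect_error(circ_linear_corr(th[1:5], cos(th)[1:5]))
})

test_that("circular-linear p-values are calibrated under the null", {
  set.seed(19)
  ps <- replicate(400, {
    th <- runif(60, -pi, pi)
    circ_linear_corr(th, rnorm(60))$p
  })
  expect_equal(mean(ps), 0.5, tolerance = 0.08)
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.04)
})

test_that("phase-conditioned densities normalize and select correctly", {
  # deterministic sinusoid: value samples tagged by their own phase
  tr <- sinusoid_trace(A = 1, f = 100, duration = 2000)
  fits <- window_sine_fit(tr$value)
  acc <- select_windows(fits)
  d_all <- phase_conditioned_pdf(tr$value, tr$t, fits, acc, "all")
  expect_equal(trapz(d_all$x, d_all$y), 1, tolerance = 1e-3)
  d_peak <- phase_conditioned_pdf(tr$value, tr$t, fits, acc, "peak",
                                  half_width = pi / 8)
  # phase band of width 2*(pi/8) out of 2*pi -> ~1/8 of samples (the
  # inclusive band boundary adds one discretized sample per cycle)
  expect_equal(attr(d_peak, "n_kept") / length(tr$value), 1 / 8,
               tolerance = 0.05)
  # peak-conditioned samples of sin all lie within cos(pi/8) of its maximum
  mean_val <- trapz(d_peak$x, d_peak$x * d_peak$y)
  expect_gt(mean_val, 0.9)
})

test_that("KDE is consistent against a known normal density", {
  set.seed(5)
  x <- rnorm(1e5, mean = 2, sd = 3)
  d <- density(x)
  truth <- dnorm(d$x, 2, 3)
  l1 <- trapz(d$x, abs(d$y - truth))
  expect_lt(l1, 0.05)
})

test_that("deviation from independence behaves at both extremes", {
  set.seed(11)
  a <- rnorm(8000); b <- rnorm(8000)
  ind <- deviation_from_independence(a, b)
  expect_equal(grid2_integral(ind$x, ind$y, ind$D), 0, tolerance = 1e-3)
  expect_equal(grid2_integral(ind$x, ind$y, ind$joint), 1, tolerance = 1e-2)
  expect_lt(max(abs(ind$D)), 0.02)

  cpl <- deviation_from_independence(a, a + rnorm(8000, sd = 0.2))
  expect_equal(grid2_integral(cpl$x, cpl$y, cpl$D), 0, tolerance = 1e-3)
  # positive on the diagonal, negative off it
  idx <- seq(20, 108, by = 8)
  diag_vals <- vapply(idx, function(i) {
    j <- which.min(abs(cpl$y - cpl$x[i])); cpl$D[i, j]
  }, numeric(1))
  expect_gt(mean(diag_vals), 0)
  expect_gt(max(abs(cpl$D)), 5 * max(abs(ind$D)))
})

test_that("mean/SD density degenerates gracefully and normalizes", {
  pt <- mean_sd_density(rep(1.5, 100), rep(0, 100))
  expect_equal(pt$x[which.max(rowSums(pt$z))], 1.5, tolerance = 0.01)
  set.seed(2)
  mv <- rnorm(5000); sv <- abs(rnorm(5000, 1, 0.1))
  dd <- mean_sd_density(mv, sv)
  expect_equal(grid2_integral(dd$x, dd$y, dd$z), 1, tolerance = 1e-2)
})

test_that("phase machinery is invariant to a constant baseline shift", {
  tr <- sinusoid_trace(A = 1.5, f = 95, noise_sd = 0.1, duration = 600,
                       seed = 9)
  f1 <- window_sine_fit(tr$value)
  f2 <- window_sine_fit(tr$value + 42)
  expect_equal(f1$A, f2$A, tolerance = 1e-6)
  expect_equal(f1$omega, f2$omega, tolerance = 1e-6)
  expect_equal(f2$B - f1$B, rep(42, nrow(f1)), tolerance = 1e-6)
})
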