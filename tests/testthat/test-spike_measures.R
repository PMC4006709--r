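test_that("isi_stats handles periodic, Poisson and degenerate trains", {
  expect_equal(isi_stats(seq(0, 1000, by = 10)),
               c(rate = 100, cv = 0))
  expect_error(isi_stats(c(1, 2)))
  pois <- poisson_raster(1, rate = 30, duration = 4e5, seed = 13)
  st <- isi_stats(pois$spikes[[1]])
  expect_equal(st[["rate"]], 30, tolerance = 0.03)
  expect_equal(st[["cv"]], 1, tolerance = 0.03)
})

test_that("mpc_pair recovers locking, antiphase and independence", {
  b <- seq(10, 5000, by = 10)
  # in-phase: a slightly after every b spike (epsilon/ISI = 1e-4 cycles)
  expect_lt(Mod(mpc_pair(b + 0.001, b) - (1 + 0i)), 1e-3)
  # exact antiphase: a at the midpoints of b's intervals
  expect_equal(mpc_pair(b + 5, b), -1 + 0i, ignore_attr = TRUE,
               tolerance = 1e-12)
  # coincident spikes get phase 0 of the following interval
  v <- mpc_pair(b[-length(b)], b)
  expect_equal(v, 1 + 0i, ignore_attr = TRUE, tolerance = 1e-12)
  # independent Poisson: resultant of ~uniform phases
  pa <- poisson_raster(2, 50, 40000, seed = 21)
  v <- mpc_pair(pa$spikes[[1]], pa$spikes[[2]])
  expect_lt(Mod(v), 4 / sqrt(attr(v, "S")))
})

test_that("mpc_pair agrees with the brute-force oracle to 1e-12", {
  ra <- poisson_raster(6, 40, 5000, seed = 3)
  for (i in 1:3) {
    a <- ra$spikes[[2 * i - 1]]
    b <- ra$spikes[[2 * i]]
    expect_equal(as.complex(mpc_pair(a, b)), mpc_oracle(a, b),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(as.complex(mpc_pair(b, a)), mpc_oracle(b, a),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("distance-resolved MPC has equal pair counts and exact limits", {
  # all neurons spiking identically: R_MPC(d) = 1 everywhere
  clock <- locked_raster(16, f_osc = 100, participation_p = 1,
                         jitter_kappa = Inf, duration = 2000, seed = 1)
  bd <- mpc_by_distance(clock)
  expect_equal(bd$r_mpc, rep(1, nrow(bd)), tolerance = 1e-9)
  expect_equal(as.numeric(mpc_global(clock)), 1, tolerance = 1e-9)
  # pair-count bookkeeping on a 4x4 grid: m=1 axial pairs: 16*4; m=2
  # (antipodal): 16*2
  expect_equal(bd$n_pairs, c(64, 32))
  # independent Poisson: no coherence
  pois <- poisson_raster(16, 40, 30000, seed = 8)
  expect_lt(abs(as.numeric(mpc_global(pois))), 0.02)
})

test_that("MPC matches the von Mises resultant on locked fixtures", {
  kappa <- 4
  # jittered trains against an unjittered reference: resultant I1/I0
  ra <- locked_raster(9, f_osc = 100, participation_p = 1,
                      jitter_kappa = c(Inf, rep(kappa, 8)),
                      duration = 20000, seed = 17)
  vals <- vapply(2:9, function(j)
    Re(mpc_pair(ra$spikes[[j]], ra$spikes[[1]])), numeric(1))
  expect_equal(mean(vals), vm_resultant(kappa), tolerance = 0.02)
  # two independently jittered trains: resultant of a phase *difference*,
  # i.e. the square of the single-train resultant
  vals2 <- vapply(seq(2, 8, by = 2), function(j)
    Re(mpc_pair(ra$spikes[[j]], ra$spikes[[j + 1]])), numeric(1))
  expect_equal(mean(vals2), vm_resultant(kappa)^2, tolerance = 0.04)
})

test_that("R_MPC is invariant to time shifts and within-class relabeling", {
  ra <- locked_raster(16, f_osc = 100, participation_p = 0.5,
                      jitter_kappa = 6, duration = 5000, seed = 23)
  shifted <- spike_raster(lapply(ra$spikes, `+`, 500), ra$x, ra$y, ra$L,
                          ra$duration + 500)
  expect_equal(as.numeric(mpc_global(ra)), as.numeric(mpc_global(shifted)),
               tolerance = 1e-12)
  # relabel: rotate the whole grid by one column (a torus symmetry)
  n <- 4
  id <- 0:(n * n - 1)
  rot <- (id %/% n) * n + (id %% n + 1) %% n
  rotated <- spike_raster(ra$spikes[rot + 1], ra$x, ra$y, ra$L, ra$duration)
  expect_equal(as.numeric(mpc_global(ra)), as.numeric(mpc_global(rotated)),
               tolerance = 1e-12)
})

test_that("population rate bins every spike exactly once", {
  ra <- poisson_raster(5, 20, 1000, seed = 4)
  pr <- population_rate(ra, bin = 0.5)
  expect_equal(sum(pr), sum(lengths(ra$spikes)))
  empty <- poisson_raster(5, 0, 1000, seed = 4)
  expect_true(all(population_rate(empty, bin = 1) == 0))
  one <- spike_raster(rep(list(250.2), 7), x = rep(0, 7), y = rep(0, 7),
                      L = 1, duration = 1000)
  pr1 <- population_rate(one, bin = 1)
  expect_equal(max(pr1), 7)
  expect_equal(sum(pr1 > 0), 1)
})

test_that("network_frequency finds known modulation and flags white noise", {
  ra <- locked_raster(50, f_osc = 100, participation_p = 0.3,
                      jitter_kappa = 3, duration = 5000, seed = 6)
  nf <- network_frequency(population_rate(ra, bin = 0.5))
  expect_true(nf$oscillating)
  expect_equal(nf$frequency, 100, tolerance = 0.01)
  # amplitude invariance
  pr <- population_rate(ra, bin = 0.5)
  nf2 <- network_frequency(13.7 * as.numeric(pr), bin_ms = 0.5)
  expect_equal(nf$frequency, nf2$frequency, tolerance = 1e-9)
  # white Poisson raster: no spectral peak above the floor
  pois <- poisson_raster(50, 30, 5000, seed = 7)
  nfp <- network_frequency(population_rate(pois, bin = 0.5))
  expect_false(nfp$oscillating)
  expect_true(is.na(nfp$frequency))
})

test_that("correlation_by_distance has the right limits", {
  n_t <- 400
  common <- sin(2 * pi * (1:n_t) / 25)
  ident <- matrix(rep(common, 16), n_t, 16)
  cbd <- correlation_by_distance(ident, L = 1)
  expect_equal(cbd$r, rep(1, nrow(cbd)), tolerance = 1e-12)
  set.seed(99)
  noise <- matrix(rnorm(n_t * 16), n_t, 16)
  cbd0 <- correlation_by_distance(noise, L = 1)
  expect_true(all(abs(cbd0$r) < 0.1))
})
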