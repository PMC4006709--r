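test_that("torus distance wraps correctly", {
  expect_equal(torus_distance(c(0, 0), c(0.5, 0.5), 1), sqrt(0.5))
  expect_equal(torus_distance(c(0, 0), c(0.9, 0), 1), 0.1)
  expect_equal(torus_distance(c(0.3, 0.7), c(0.3, 0.7), 1), 0)
  # vectorized form
  expect_equal(torus_distance(rbind(c(0, 0), c(0, 0)),
                              rbind(c(0.5, 0.5), c(0.9, 0)), 1),
               c(sqrt(0.5), 0.1))
})

test_that("delay matrix combines conduction and synaptic delays", {
  cfg <- network_config(N = 400)
  dm <- build_delay_matrix(cfg)
  expect_true(isSymmetric(dm))
  expect_true(all(is.na(diag(dm))))
  # adjacent grid neurons: spacing 0.05 mm
  expect_equal(dm[1, 2], 0.05 / 0.141 + 1, tolerance = 0.005)
  # maximally separated pair on the torus
  expect_equal(max(dm, na.rm = TRUE), sqrt(0.5) / 0.141 + 1,
               tolerance = 0.005)
  expect_true(all(dm >= cfg$delta_syn - 1e-9, na.rm = TRUE))
  # instantaneous conduction limit: all delays collapse to delta_syn
  fast <- build_delay_matrix(network_config(N = 16, s = 1e9))
  expect_true(all(abs(fast - 1) < 1e-9, na.rm = TRUE))
})

test_that("simulations are deterministic given seed and config", {
  cfg <- network_config(N = 16, t_discard = 100, t_measure = 400, seed = 5)
  s1 <- simulate_network(gif_neuron(), canonical_bg(), cfg)
  s2 <- simulate_network(gif_neuron(), canonical_bg(), cfg)
  expect_identical(s1$raster$spikes, s2$raster$spikes)
  expect_identical(s1$trace, s2$trace)
  s3 <- simulate_network(gif_neuron(), canonical_bg(),
                         network_config(N = 16, t_discard = 100,
                                        t_measure = 400, seed = 6))
  expect_false(identical(s1$raster$spikes, s3$raster$spikes))
})

test_that("refractoriness and reset invariants hold in a spiking run", {
  cfg <- network_config(N = 16, t_discard = 200, t_measure = 1000, seed = 2)
  sim <- simulate_network(if_neuron(), canonical_bg(), cfg,
                          record_neurons = 0:15)
  isis <- unlist(lapply(sim$raster$spikes, diff))
  expect_true(length(isis) > 50)
  expect_true(all(isis >= if_neuron()$tau_ref - 1e-9))
  # recorded (post-reset) samples never sit above threshold
  expect_true(all(sim$rec_v < if_neuron()$v_th + 1e-9))
})

test_that("uncoupled network reproduces isolated single-neuron statistics", {
  bg <- canonical_bg()
  cfg <- network_config(N = 25, ghat = 0, t_discard = 500,
                        t_measure = 20000, seed = 31)
  sim <- simulate_network(gif_neuron(), bg, cfg)
  st <- t(vapply(sim$raster$spikes, isi_stats, numeric(2)))
  iso <- isi_stats(simulate_neuron(gif_neuron(), bg, t_measure = 20000,
                                   t_discard = 500, seed = 77,
                                   trace_bin = 0)$spikes)
  # population mean of 25 independent neurons vs one long isolated run
  se_rate <- sd(st[, "rate"]) / sqrt(nrow(st))
  expect_lt(abs(mean(st[, "rate"]) - iso[["rate"]]), 4 * se_rate)
  expect_equal(mean(st[, "cv"]), iso[["cv"]], tolerance = 0.05)
  # and no phase coherence beyond chance
  expect_lt(abs(mpc_global(sim$raster)), 0.05)
})

test_that("subthreshold configuration produces no spikes", {
  bg0 <- background_params(sigma_e = 0)
  cfg <- network_config(N = 16, t_discard = 100, t_measure = 300, seed = 1)
  sim <- simulate_network(gif_neuron(), bg0, cfg)
  expect_equal(sum(lengths(sim$raster$spikes)), 0)
})

test_that("trace bookkeeping is consistent", {
  cfg <- network_config(N = 16, t_discard = 100, t_measure = 500, seed = 8)
  sim <- simulate_network(gif_neuron(), canonical_bg(), cfg,
                          record_neurons = c(0L, 5L))
  tr <- sim$trace
  expect_equal(nrow(tr), 500 / 0.1)
  expect_equal(tr$t[1], 0.1)
  # I_int = -g v - g1 w on the mean-field samples
  expect_equal(tr$i_int, -1 * tr$v - 4 * tr$w, tolerance = 1e-10)
  # population counts sum to total spikes
  expect_equal(sum(sim$pop_counts), sum(lengths(sim$raster$spikes)))
})
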