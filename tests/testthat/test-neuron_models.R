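test_that("resting potential matches the closed form and its limits", {
  bg <- canonical_bg()
  expect_equal(resting_potential(if_neuron(), bg), 2.5)
  expect_equal(resting_potential(gif_neuron(), bg), 1.25)
  expect_equal(resting_potential(gif_neuron(), bg, ge0 = 0, gi0 = 0), 0)
  # explicit balance: plug the returned voltage back into the current sum
  v <- resting_potential(gif_neuron(), bg)
  expect_equal(-1 * v - 4 * v + 0.5 * (70 - v) + 2.5 * (-10 - v), 0,
               tolerance = 1e-12)
})

test_that("linearize reproduces the canonical eigenstructure", {
  la <- linearize(gif_neuron())
  expect_equal(la$tau_eff_ms, 10)
  expect_equal(la$f_eff_hz, 1000 * 0.2 / (2 * pi), tolerance = 1e-12)
  expect_true(la$f_eff_hz > 31 && la$f_eff_hz < 33)

  la_if <- linearize(if_neuron())
  expect_equal(Re(la_if$eigenvalues), -0.1)
  expect_equal(la_if$f_eff_hz, 0)
  expect_equal(la_if$tau_eff_ms, 10)

  la3 <- linearize(gif_neuron(), g_extra = 3)
  expect_equal(la3$tau_eff_ms, 4)
  expect_equal(la3$f_eff_hz, 21, tolerance = 0.01)
})

test_that("eigenvalues agree with an independent polynomial-root oracle", {
  for (gx in c(0, 0.7, 3, 8, 20)) {
    n <- gif_neuron()
    la <- linearize(n, g_extra = gx)
    # characteristic polynomial of the 2x2 system, solved generically
    a <- (n$g + gx) / n$C
    b <- n$g1 / n$C
    ct <- 1 / n$tau1
    roots <- polyroot(c(a * ct + b * ct, a + ct, 1))
    expect_equal(sort(Re(la$eigenvalues)), sort(Re(roots)),
                 tolerance = 1e-10)
    expect_equal(sort(abs(Im(la$eigenvalues))), sort(abs(Im(roots))),
                 tolerance = 1e-10)
  }
})

test_that("GIF intrinsic frequency decreases with background until passive", {
  gx <- seq(0, 6, by = 0.25)
  f <- vapply(gx, function(g) linearize(gif_neuron(), g_extra = g)$f_eff_hz,
              numeric(1))
  pos <- f > 0
  expect_true(all(diff(f[pos]) < 0))      # strictly decreasing while complex
  expect_true(any(!pos))                  # eigenvalues eventually coalesce
  expect_true(all(f[!pos] == 0))
  expect_true(all(which(!pos) > max(which(pos))))  # passive only beyond
})

test_that("noiseless simulation settles at the resting potential", {
  bg0 <- background_params(sigma_e = 0)
  for (neuron in list(if_neuron(), gif_neuron())) {
    out <- simulate_neuron(neuron, bg0, t_measure = 100, t_discard = 400,
                           seed = 3)
    expect_length(out$spikes, 0)  # v_th above v_rest: no spikes
    expect_equal(out$final_v, resting_potential(neuron, bg0),
                 tolerance = 1e-6)
  }
})

test_that("IPSP waveforms: GIF rebounds, IF returns monotonically", {
  expect_error(ipsp_waveform(gif_neuron(), horizon = -1))

  flat <- ipsp_waveform(gif_neuron(), ghat = 0)
  expect_equal(max(abs(flat$v - attr(flat, "v_rest"))), 0, tolerance = 1e-9)

  # no background: rest at 0, pulse toward Ei < 0 hyperpolarizes, and the
  # complex eigenvalues produce exactly one overshoot above rest
  reb <- ipsp_waveform(gif_neuron(), bg = NULL, E_syn = -10, horizon = 200)
  v <- reb$v - attr(reb, "v_rest")
  expect_lt(min(v), 0)
  expect_gt(max(v), 1e-3)                 # substantial rebound
  expect_lt(which.min(v), which.max(v))   # dip first, overshoot after
  # one dominant excursion above baseline; later ripples of the damped
  # oscillation are an order of magnitude smaller
  above <- v > 0.1 * max(v)
  runs <- rle(above)
  expect_equal(sum(runs$values), 1)

  mono <- ipsp_waveform(if_neuron(), bg = NULL, E_syn = -10, horizon = 200)
  vm <- mono$v - attr(mono, "v_rest")
  expect_true(all(vm <= 1e-9))  # never exceeds rest
  imin <- which.min(vm)
  expect_true(all(diff(vm[imin:length(vm)]) >= -1e-12))  # monotone return
})

test_that("IPSPs under background are smaller and rebound survives", {
  with_bg <- ipsp_waveform(gif_neuron(), bg = canonical_bg(), horizon = 150)
  no_bg <- ipsp_waveform(gif_neuron(), bg = NULL, horizon = 150)
  dip_bg <- min(with_bg$v - attr(with_bg, "v_rest"))
  dip_free <- min(no_bg$v - attr(no_bg, "v_rest"))
  expect_gt(dip_bg, dip_free)  # shallower (less negative) dip
})

test_that("parameter constructors validate their invariants", {
  expect_error(gif_neuron(g1 = -1))
  expect_error(if_neuron(v_reset = 7, v_th = 6.3))
  expect_equal(gif_neuron()$C / gif_neuron()$g, 10)  # 10 ms membrane
  la_json <- jsonlite::fromJSON(linear_analysis_json(gif_neuron()))
  expect_equal(la_json$tau_eff_ms, 10)
  expect_equal(la_json$f_eff_hz, 1000 * 0.2 / (2 * pi), tolerance = 1e-9)
})
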