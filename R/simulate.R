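#' Torus distance
#'
#' Euclidean distance on a square torus of side `L`: each coordinate
#' difference is wrapped to the shorter way around,
#' `dx = min(|x1 - x2|, L - |x1 - x2|)`.
#'
#' @param p1,p2 length-2 numeric vectors `(x, y)`, or 2-column matrices.
#' @param L torus side length (mm).
#' @return Distance(s) in mm.
#' @examples
#' torus_distance(c(0, 0), c(0.9, 0), 1)  # wraps to 0.1
#' @export
torus_distance <- function(p1, p2, L) {
  p1 <- rbind(p1); p2 <- rbind(p2)
  d <- abs(p1 - p2)
  d <- pmin(d, L - d)
  as.numeric(sqrt(rowSums(d^2)))
}

#' Pairwise conduction delays
#'
#' Delay from neuron i to neuron j is `d(i, j) / s + delta_syn`, rounded to
#' an integer number of integration steps so that deliveries align with the
#' once-per-step synaptic update. The matrix is symmetric; the diagonal is
#' set to `NA` (no self-synapse).
#'
#' @param config a [network_config()].
#' @return N x N matrix of delays in ms.
#' @export
build_delay_matrix <- function(config) {
  co <- grid_coordinates(config)
  dx <- abs(outer(co$x_mm, co$x_mm, "-")); dx <- pmin(dx, config$L - dx)
  dy <- abs(outer(co$y_mm, co$y_mm, "-")); dy <- pmin(dy, config$L - dy)
  delay <- sqrt(dx^2 + dy^2) / config$s + config$delta_syn
  delay <- round(delay / config$dt) * config$dt
  diag(delay) <- NA_real_
  delay
}

#' Spike raster container
#'
#' A raster bundles per-neuron ordered spike-time vectors (ms, measured from
#' the end of the discard period) with the neurons' torus coordinates.
#'
#' @param spikes list of numeric vectors, one per neuron, strictly
#'   increasing.
#' @param x,y coordinates (mm).
#' @param L torus side length (mm).
#' @param duration measured duration covered by the raster (ms).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, x, y, L, duration) {
  stopifnot(length(spikes) == length(x), length(x) == length(y))
  ok <- vapply(spikes, function(s) !is.unsorted(s, strictly = TRUE),
               logical(1))
  if (!all(ok)) stop("spike times must be strictly increasing per neuron")
  structure(list(spikes = spikes, x = x, y = y, L = L, duration = duration),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  ns <- lengths(x$spikes)
  cat(sprintf("<spike raster>  %d neurons, %d spikes over %g ms (L=%g mm)\n",
              length(x$spikes), sum(ns), x$duration, x$L))
  invisible(x)
}

n_neurons <- function(raster) length(raster$spikes)

engine_args <- function(neuron, bg, config, delay_steps, record_neurons,
                        threshold_on = TRUE, init_gsyn = 0,
                        sigma_scale = 1) {
  m <- bg_means(bg); s <- bg_sds(bg)
  list(gif = is_gif(neuron), C = neuron$C, g = neuron$g,
       g1 = if (is_gif(neuron)) neuron$g1 else 0,
       tau1 = if (is_gif(neuron)) neuron$tau1 else 1,
       v_th = neuron$v_th, v_reset = neuron$v_reset,
       tau_ref = neuron$tau_ref,
       ge0 = m[["ge0"]], sigma_e = s[["sigma_e"]] * sigma_scale,
       gi0 = m[["gi0"]], sigma_i = s[["sigma_i"]] * sigma_scale,
       tau_e = bg$tau_e, tau_i = bg$tau_i, Ee = bg$Ee, Ei = bg$Ei,
       N = config$N, delay_steps = delay_steps, ghat = config$ghat,
       tau_syn = config$tau_syn, E_syn = config$E_syn, dt = config$dt,
       t_discard = config$t_discard, t_measure = config$t_measure,
       trace_stride = as.integer(round(config$trace_bin / config$dt)),
       record_neurons = as.integer(record_neurons),
       seed = as.numeric(config$seed), threshold_on = threshold_on,
       init_gsyn = init_gsyn)
}

#' Simulate an inhibitory network on the torus
#'
#' Integrates the full network with the fixed-step sixth-order Runge-Kutta
#' engine. Per step: the latent background OU conductances advance with the
#' exact transition; each neuron's summed synaptic conductance decays by
#' `exp(-dt/tau_syn)` and collects `ghat` per delayed presynaptic spike
#' arriving this step; the subthreshold state advances one RK step with all
#' conductances held constant; finally threshold crossings are detected once
#' per step, resetting `v`, starting the refractory clock and enqueueing
#' delayed deliveries to every other neuron. The first `t_discard` ms are
#' excluded from all outputs and output times are re-zeroed at the end of
#' the discard.
#'
#' @param neuron a [gif_neuron()] or [if_neuron()].
#' @param bg a [background_params()].
#' @param config a [network_config()].
#' @param record_neurons integer ids (0-based) of neurons whose `v`,
#'   intrinsic current, and refractory state are sampled at `trace_bin`
#'   resolution (used by the phase-conditioned density analyses).
#' @return An object of class `network_sim`: list with `raster`
#'   ([spike_raster()]), `trace` (mean-field data.frame: `t`, `v`, `w`,
#'   `sd_v`, `i_syn`, `i_int`), `pop_counts` (spikes per `dt` bin),
#'   `rate_bin`, `trace_bin`, and the recorded per-neuron matrices `rec_v`,
#'   `rec_iint`, `rec_refractory`.
#' @examples
#' \donttest{
#' cfg <- network_config(N = 25, t_discard = 100, t_measure = 500, seed = 7)
#' sim <- simulate_network(gif_neuron(), background_params(), cfg)
#' mean(vapply(sim$raster$spikes, length, numeric(1))) / 0.5  # rates (Hz)
#' }
#' @export
simulate_network <- function(neuron, bg, config,
                             record_neurons = integer(0)) {
  delay_ms <- build_delay_matrix(config)
  delay_steps <- matrix(as.integer(round(delay_ms / config$dt)),
                        config$N, config$N)
  diag(delay_steps) <- 0L
  args <- engine_args(neuron, bg, config, delay_steps, record_neurons)
  out <- do.call(.sim_engine, args)
  co <- grid_coordinates(config)
  raster <- spike_raster(out$spikes, co$x_mm, co$y_mm, config$L,
                         config$t_measure)
  structure(list(raster = raster, trace = out$trace,
                 pop_counts = out$pop_counts, rate_bin = config$dt,
                 trace_bin = config$trace_bin,
                 rec_neurons = as.integer(record_neurons),
                 rec_v = out$rec_v, rec_iint = out$rec_iint,
                 rec_isyn = out$rec_isyn,
                 rec_refractory = out$rec_refractory,
                 neuron = neuron, bg = bg, config = config),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  print(x$raster)
  cat(sprintf("  model=%s  ghat=%g uS  E_syn=%g mV  seed=%s\n",
              x$neuron$model_kind, x$config$ghat, x$config$E_syn,
              format(x$config$seed)))
  invisible(x)
}

#' Simulate one isolated neuron under the noisy background
#'
#' Single uncoupled neuron driven by its rectified OU background
#' conductances; the workhorse for firing-rate calibration and for the
#' single-cell rows of the summary statistics.
#'
#' @inheritParams simulate_network
#' @param t_measure measured duration (ms).
#' @param t_discard discarded transient (ms).
#' @param dt integration step (ms).
#' @param seed RNG seed.
#' @param trace_bin trace sampling bin (ms); `0` disables the trace.
#' @param threshold if `FALSE`, the spike mechanism is disabled (useful for
#'   subthreshold analyses).
#' @return list with `spikes` (numeric vector, ms), `trace` (data.frame) and
#'   `final_v`.
#' @export
simulate_neuron <- function(neuron, bg, t_measure, t_discard = 2000,
                            dt = 0.01, seed = 1, trace_bin = 0.1,
                            threshold = TRUE) {
  cfg <- network_config(N = 1, ghat = 0, dt = dt, t_discard = t_discard,
                        t_measure = t_measure, seed = seed,
                        trace_bin = if (trace_bin > 0) trace_bin else dt,
                        E_syn = bg$Ei)
  args <- engine_args(neuron, bg, cfg, matrix(0L, 1, 1),
                      if (trace_bin > 0) 0L else integer(0),
                      threshold_on = threshold)
  if (trace_bin == 0) args$trace_stride <- 0L
  out <- do.call(.sim_engine, args)
  list(spikes = out$spikes[[1]], trace = out$trace,
       final_v = out$final_v[1])
}
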