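#' Neuron model parameters
#'
#' Constructors for the two linear spiking neuron models used throughout the
#' package. Voltage is measured as the deviation from the leak reversal
#' potential, so the leak reversal sits at 0 mV and all other potentials are
#' relative to it. The integrate-and-fire (IF) neuron has purely passive
#' (exponential) subthreshold relaxation with membrane time constant `C/g`.
#' The generalized integrate-and-fire (GIF) neuron adds a restorative
#' recovery variable `w` (conductance `g1`, time constant `tau1`) that gives
#' damped subthreshold oscillations, the linear caricature of the resonant
#' currents of fast-spiking interneurons:
#' \deqn{C \dot v = -g v - g_1 w + I_{syn} + I_{bg}, \qquad
#'       \tau_1 \dot w = v - w.}
#' Spikes are threshold-and-reset: when `v` crosses `v_th` from below a spike
#' is recorded, `v` jumps to `v_reset` and is clamped there for `tau_ref` ms
#' while `w` keeps evolving. The canonical parameters give a 10 ms membrane
#' time constant and, for the GIF, intrinsic subthreshold oscillations at
#' roughly 32 Hz.
#'
#' @param C membrane capacitance (nF).
#' @param g leak conductance (uS).
#' @param g1 conductance of the recovery variable `w` (uS, GIF only).
#' @param tau1 time constant of `w` (ms, GIF only).
#' @param v_th spike threshold (mV above the leak reversal).
#' @param v_reset post-spike reset potential (mV). The default +3 mV (just
#'   below the resting potential under the canonical background) reproduces
#'   the reference single-cell firing statistics; see the methods vignette
#'   for the rationale.
#' @param tau_ref absolute refractory period (ms).
#'
#' @return An object of class `neuron_params`.
#' @examples
#' gif_neuron()
#' if_neuron(v_th = 7.3)  # an r-matched threshold
#' @export
gif_neuron <- function(C = 10, g = 1, g1 = 4, tau1 = 10,
                       v_th = 6.3, v_reset = 3, tau_ref = 3) {
  stopifnot(C > 0, g > 0, g1 > 0, tau1 > 0, tau_ref >= 0, v_reset < v_th)
  structure(list(model_kind = "GIF", C = C, g = g, g1 = g1, tau1 = tau1,
                 v_th = v_th, v_reset = v_reset, tau_ref = tau_ref),
            class = "neuron_params")
}

#' @rdname gif_neuron
#' @export
if_neuron <- function(C = 10, g = 1, v_th = 6.3, v_reset = 3, tau_ref = 3) {
  stopifnot(C > 0, g > 0, tau_ref >= 0, v_reset < v_th)
  structure(list(model_kind = "IF", C = C, g = g, g1 = 0, tau1 = NA_real_,
                 v_th = v_th, v_reset = v_reset, tau_ref = tau_ref),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<%s neuron>  C=%g nF  g=%g uS", x$model_kind, x$C, x$g))
  if (x$model_kind == "GIF") cat(sprintf("  g1=%g uS  tau1=%g ms", x$g1, x$tau1))
  cat(sprintf("\n  v_th=%g mV  v_reset=%g mV  tau_ref=%g ms\n",
              x$v_th, x$v_reset, x$tau_ref))
  invisible(x)
}

is_gif <- function(neuron) identical(neuron$model_kind, "GIF")

#' Background conductance parameters
#'
#' Statistics of the noisy synaptic bombardment each neuron receives from
#' sources outside the local network, modelled as two spatially independent
#' rectified Ornstein-Uhlenbeck (OU) conductances: an excitatory one with
#' mean `ge0` and SD `sigma_e` and an inhibitory one tied to it by fixed
#' ratios, `gi0 = k * ge0` and `sigma_i = sigma_ratio * sigma_e`. The
#' inhibitory quantities are always derived from the ratios, never stored.
#' Reversal potentials are relative to the leak reversal.
#'
#' @param ge0 mean excitatory conductance (uS).
#' @param sigma_e SD of the excitatory conductance (uS).
#' @param k inhibition-to-excitation mean conductance ratio.
#' @param sigma_ratio inhibition-to-excitation conductance SD ratio.
#' @param tau_e,tau_i OU autocorrelation time constants (ms).
#' @param Ee,Ei excitatory/inhibitory reversal potentials (mV).
#' @return An object of class `background_params`.
#' @examples
#' bg <- background_params()
#' bg_means(bg)  # derived means: ge0 = 0.5, gi0 = 2.5 uS
#' @export
background_params <- function(ge0 = 0.5, sigma_e = 0.6, k = 5,
                              sigma_ratio = 2.5, tau_e = 1, tau_i = 1,
                              Ee = 70, Ei = -10) {
  stopifnot(ge0 >= 0, sigma_e >= 0, k >= 0, sigma_ratio >= 0,
            tau_e > 0, tau_i > 0)
  structure(list(ge0 = ge0, sigma_e = sigma_e, k = k,
                 sigma_ratio = sigma_ratio, tau_e = tau_e, tau_i = tau_i,
                 Ee = Ee, Ei = Ei),
            class = "background_params")
}

#' @rdname background_params
#' @param bg a `background_params` object.
#' @export
bg_means <- function(bg) {
  c(ge0 = bg$ge0, gi0 = bg$k * bg$ge0)
}

#' @rdname background_params
#' @export
bg_sds <- function(bg) {
  c(sigma_e = bg$sigma_e, sigma_i = bg$sigma_ratio * bg$sigma_e)
}

#' @export
print.background_params <- function(x, ...) {
  m <- bg_means(x); s <- bg_sds(x)
  cat(sprintf(paste0("<background>  ge0=%g (sd %g)  gi0=%g (sd %g) uS\n",
                     "  tau_e=%g tau_i=%g ms  Ee=%g Ei=%g mV\n"),
              m[["ge0"]], s[["sigma_e"]], m[["gi0"]], s[["sigma_i"]],
              x$tau_e, x$tau_i, x$Ee, x$Ei))
  invisible(x)
}

#' Network and integration configuration
#'
#' Geometry, coupling, and integration settings for an all-to-all inhibitory
#' network placed on the vertices of a square grid with periodic boundaries
#' (a torus). Synaptic weights are identical for every pair; spatial
#' structure enters only through conduction delays
#' `d(i, j) / s + delta_syn`, so nearby cells inhibit each other sooner.
#'
#' @param N number of neurons; must be a perfect square (default 400, a
#'   20 x 20 grid).
#' @param L torus side length (mm). 1 mm keeps the longest delay (~6 ms)
#'   below the ~10 ms oscillation period.
#' @param s conduction speed (mm/ms; 0.141 matches unmyelinated horizontal
#'   axons).
#' @param delta_syn fixed synaptic delay (ms).
#' @param ghat peak synaptic conductance increment per presynaptic spike (uS).
#' @param tau_syn synaptic conductance decay time constant (ms).
#' @param E_syn reversal potential of recurrent inhibition (mV); -10 for
#'   hyperpolarizing inhibition, +4 for the shunting variant.
#' @param dt integration step (ms).
#' @param t_discard initial transient discarded from all outputs (ms).
#' @param t_measure measured duration after the discard (ms).
#' @param trace_bin sampling bin for mean-field traces (ms). The population
#'   rate is binned at `dt`.
#' @param seed master seed; every neuron's two background processes draw
#'   from sub-streams derived from it.
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 400, L = 1, s = 0.141, delta_syn = 1,
                           ghat = 0.25, tau_syn = 1, E_syn = -10,
                           dt = 0.01, t_discard = 2000, t_measure = 3000,
                           trace_bin = 0.1, seed = 1) {
  n_side <- sqrt(N)
  if (abs(n_side - round(n_side)) > 1e-9)
    stop("N must be a perfect square (grid topology)")
  stopifnot(L > 0, s > 0, delta_syn > 0, dt > 0, tau_syn > 0,
            t_discard >= 0, t_measure > 0, trace_bin >= dt)
  structure(list(N = as.integer(N), n_side = as.integer(round(n_side)),
                 L = L, s = s, delta_syn = delta_syn, ghat = ghat,
                 tau_syn = tau_syn, E_syn = E_syn, dt = dt,
                 t_discard = t_discard, t_measure = t_measure,
                 trace_bin = trace_bin, seed = seed),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(paste0("<network config>  N=%d (%dx%d torus, L=%g mm)\n",
                     "  ghat=%g uS  tau_syn=%g ms  E_syn=%g mV  s=%g mm/ms",
                     "  delta_syn=%g ms\n  dt=%g ms  discard %g ms,",
                     " measure %g ms  seed=%s\n"),
              x$N, x$n_side, x$n_side, x$L, x$ghat, x$tau_syn, x$E_syn,
              x$s, x$delta_syn, x$dt, x$t_discard, x$t_measure,
              format(x$seed)))
  invisible(x)
}

#' Grid coordinates of the network
#'
#' Neurons are indexed 0..N-1 in row-major order on the `n x n` grid;
#' coordinates are in mm with spacing `L / n`.
#'
#' @param config a [network_config()].
#' @return data.frame with columns `neuron_id`, `x_mm`, `y_mm`.
#' @export
grid_coordinates <- function(config) {
  n <- config$n_side
  spacing <- config$L / n
  id <- seq_len(config$N) - 1L
  data.frame(neuron_id = id,
             x_mm = (id %% n) * spacing,
             y_mm = (id %/% n) * spacing)
}
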