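#' Resting potential under fixed background conductances
#'
#' The resting potential is the voltage at which all currents balance when
#' the background conductances are frozen at their mean values (and, for the
#' GIF, the recovery variable has equilibrated, `w = v`):
#' \deqn{0 = -g v - g_1 v + g_{e0}(E_e - v) + g_{i0}(E_i - v)}
#' which has the closed form
#' `(ge0 * Ee + gi0 * Ei) / (g + g1 + ge0 + gi0)` (the `g1` term is absent
#' for the IF). The restorative conductance pulls the GIF resting potential
#' closer to the leak reversal than the IF's.
#'
#' @param neuron a [gif_neuron()] or [if_neuron()].
#' @param bg a [background_params()]; alternatively supply `ge0`/`gi0`
#'   directly.
#' @param ge0,gi0 fixed conductances (uS), overriding `bg`.
#' @param Ee,Ei reversal potentials (mV), overriding `bg`.
#' @return Resting potential in mV (relative to the leak reversal).
#' @examples
#' resting_potential(if_neuron(), background_params())   # 2.5 mV
#' resting_potential(gif_neuron(), background_params())  # 1.25 mV
#' @export
resting_potential <- function(neuron, bg = background_params(),
                              ge0 = NULL, gi0 = NULL, Ee = NULL, Ei = NULL) {
  m <- bg_means(bg)
  if (is.null(ge0)) ge0 <- m[["ge0"]]
  if (is.null(gi0)) gi0 <- m[["gi0"]]
  if (is.null(Ee)) Ee <- bg$Ee
  if (is.null(Ei)) Ei <- bg$Ei
  stopifnot(ge0 >= 0, gi0 >= 0)
  g1 <- if (is_gif(neuron)) neuron$g1 else 0
  (ge0 * Ee + gi0 * Ei) / (neuron$g + g1 + ge0 + gi0)
}

#' Linear analysis of the subthreshold dynamics
#'
#' Eigenvalues of the subthreshold system when a fixed extra conductance
#' `g_extra` (the summed mean background conductance) is added to the leak.
#' For the IF this is the single rate `-(g + g_extra)/C`; for the GIF the
#' 2x2 Jacobian
#' \deqn{J = \begin{pmatrix} -(g+g_{extra})/C & -g_1/C \\
#'           1/\tau_1 & -1/\tau_1 \end{pmatrix}}
#' has a complex-conjugate pair for sufficiently resonant parameters. The
#' effective membrane time constant is `-1/max(Re(lambda))` and the
#' effective intrinsic frequency `|Im(lambda)| / (2 pi)` (0 when the
#' eigenvalues are real). Increasing background drive shortens the time
#' constant and lowers the intrinsic frequency until the eigenvalues
#' coalesce on the real axis and the dynamics become purely passive.
#'
#' @param neuron a [gif_neuron()] or [if_neuron()].
#' @param g_extra summed mean background conductance added to the leak (uS).
#' @param bg optional [background_params()]: if supplied, `g_extra` is taken
#'   as `ge0 + gi0` and the resting potential is filled in.
#' @return An object of class `linear_analysis`: list with `v_rest` (mV; NA
#'   unless `bg` given or `g_extra = 0`), `eigenvalues` (complex, 1/ms),
#'   `tau_eff_ms`, `f_eff_hz`.
#' @examples
#' linearize(gif_neuron())            # f_eff ~ 32 Hz, tau_eff = 10 ms
#' linearize(gif_neuron(), bg = background_params())  # faster, slower
#' @export
linearize <- function(neuron, g_extra = 0, bg = NULL) {
  stopifnot(g_extra >= 0)
  if (!is.null(bg)) {
    g_extra <- sum(bg_means(bg))
    v_rest <- resting_potential(neuron, bg)
  } else {
    v_rest <- if (g_extra == 0) 0 else NA_real_
  }
  gt <- neuron$g + g_extra
  if (is_gif(neuron)) {
    J <- matrix(c(-gt / neuron$C, 1 / neuron$tau1,
                  -neuron$g1 / neuron$C, -1 / neuron$tau1), 2, 2)
    lambda <- eigen(J, only.values = TRUE)$values
    lambda <- as.complex(lambda)
  } else {
    lambda <- as.complex(-gt / neuron$C)
  }
  tau_eff <- -1 / max(Re(lambda))
  f_eff <- max(abs(Im(lambda))) / (2 * pi) * 1000  # rad/ms -> Hz
  structure(list(v_rest = v_rest, eigenvalues = lambda,
                 tau_eff_ms = tau_eff, f_eff_hz = f_eff),
            class = "linear_analysis")
}

#' @export
print.linear_analysis <- function(x, ...) {
  cat(sprintf("<linear analysis>  v_rest=%s mV  tau_eff=%.4g ms  f_eff=%.4g Hz\n",
              format(x$v_rest), x$tau_eff_ms, x$f_eff_hz))
  cat("  eigenvalues (1/ms):", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' @rdname linearize
#' @export
linear_analysis_json <- function(neuron, g_extra = 0, bg = NULL) {
  la <- linearize(neuron, g_extra = g_extra, bg = bg)
  jsonlite::toJSON(list(v_rest = la$v_rest,
                        lambda_re = Re(la$eigenvalues),
                        lambda_im = Im(la$eigenvalues),
                        tau_eff_ms = la$tau_eff_ms,
                        f_eff_hz = la$f_eff_hz),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' Inhibitory post-synaptic potential waveform
#'
#' Deterministic voltage response of a neuron at rest to a single
#' presynaptic conductance pulse delivered at t = 0, with the background
#' conductances frozen at their means and the spike mechanism disabled. The
#' pulse raises the synaptic conductance by `ghat` instantaneously; it then
#' decays with `tau_syn` and drives current `gsyn (E_syn - v)`. For the GIF
#' with complex eigenvalues the trace overshoots the resting potential on
#' the way back (post-inhibitory rebound); the IF returns monotonically.
#'
#' @param neuron a [gif_neuron()] or [if_neuron()].
#' @param bg a [background_params()], or `NULL` for no background.
#' @param ghat pulse amplitude (uS).
#' @param tau_syn synaptic decay constant (ms).
#' @param E_syn synaptic reversal potential (mV).
#' @param horizon trace duration (ms).
#' @param dt integration step (ms).
#' @return data.frame with columns `t`, `v`, `w`, plus attribute `v_rest`.
#' @export
ipsp_waveform <- function(neuron, bg = background_params(), ghat = 0.25,
                          tau_syn = 1, E_syn = -10, horizon = 150,
                          dt = 0.01) {
  if (horizon <= 0) stop("horizon must be positive")
  if (is.null(bg)) {
    ge0 <- 0; gi0 <- 0; Ee <- 0; Ei <- 0
    v0 <- 0
  } else {
    m <- bg_means(bg)
    ge0 <- m[["ge0"]]; gi0 <- m[["gi0"]]; Ee <- bg$Ee; Ei <- bg$Ei
    v0 <- resting_potential(neuron, bg)
  }
  gif <- is_gif(neuron)
  C <- neuron$C; g <- neuron$g
  g1 <- if (gif) neuron$g1 else 0
  inv_tau1 <- if (gif) 1 / neuron$tau1 else 0
  n <- ceiling(horizon / dt)
  tt <- (0:n) * dt
  gsyn <- ghat * exp(-tt / tau_syn)
  deriv <- function(v, w, gs) {
    dv <- (-g * v - g1 * w + gs * (E_syn - v) +
             ge0 * (Ee - v) + gi0 * (Ei - v)) / C
    dw <- if (gif) (v - w) * inv_tau1 else 0
    c(dv, dw)
  }
  v <- numeric(n + 1); w <- numeric(n + 1)
  v[1] <- v0; w[1] <- v0
  for (i in seq_len(n)) {
    gs0 <- gsyn[i]
    gsh <- ghat * exp(-(tt[i] + dt / 2) / tau_syn)
    gs1 <- gsyn[i + 1]
    k1 <- deriv(v[i], w[i], gs0)
    k2 <- deriv(v[i] + dt / 2 * k1[1], w[i] + dt / 2 * k1[2], gsh)
    k3 <- deriv(v[i] + dt / 2 * k2[1], w[i] + dt / 2 * k2[2], gsh)
    k4 <- deriv(v[i] + dt * k3[1], w[i] + dt * k3[2], gs1)
    v[i + 1] <- v[i] + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    w[i + 1] <- w[i] + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  }
  structure(data.frame(t = tt, v = v, w = w), v_rest = v0)
}
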