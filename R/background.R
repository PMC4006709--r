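#' Exact Ornstein-Uhlenbeck transition
#'
#' One exact-in-distribution update of an OU process with mean `g0`, SD
#' `sigma` and autocorrelation time `tau` over a step `dt`:
#' \deqn{g' = g_0 + (g - g_0) e^{-dt/\tau} +
#'       \sigma \sqrt{1 - e^{-2 dt/\tau}} \; z, \quad z \sim N(0,1).}
#' The output is the latent (unrectified) state; rectification is applied
#' only where the conductance enters a current (see
#' [background_current()]). Vectorized over `g` and `z`.
#'
#' @param g current state (uS).
#' @param g0 stationary mean (uS).
#' @param sigma stationary SD (uS).
#' @param tau autocorrelation time constant (ms).
#' @param dt time step (ms).
#' @param z standard normal draw(s); supply your own for reproducibility.
#' @return Updated state, same length as `g`/`z`.
#' @export
ou_step <- function(g, g0, sigma, tau, dt, z) {
  stopifnot(dt > 0, tau > 0, sigma >= 0)
  a <- exp(-dt / tau)
  g0 + (g - g0) * a + sigma * sqrt(1 - a * a) * z
}

#' Background synaptic current
#'
#' Current delivered by the rectified background conductances at voltage
#' `v`: `max(ge, 0) (Ee - v) + max(gi, 0) (Ei - v)`, in nA. The latent OU
#' states may go negative; a negative conductance is physically meaningless,
#' so it is clipped to zero here, at the point of use.
#'
#' @param v membrane potential (mV).
#' @param ge,gi latent excitatory/inhibitory conductances (uS).
#' @param bg a [background_params()] supplying the reversal potentials.
#' @return Current in nA (vectorized).
#' @export
background_current <- function(v, ge, gi, bg = background_params()) {
  pmax(ge, 0) * (bg$Ee - v) + pmax(gi, 0) * (bg$Ei - v)
}

#' Generate a background conductance trace
#'
#' Convenience generator of a discretized OU path using the exact
#' transition, for diagnostics and tests.
#'
#' @param n number of steps.
#' @param g0,sigma,tau OU parameters.
#' @param dt step (ms).
#' @param seed RNG seed.
#' @param g_init initial state (defaults to `g0`, i.e. stationary start).
#' @return Numeric vector of length `n`.
#' @export
ou_trace <- function(n, g0, sigma, tau, dt = 0.01, seed = 1, g_init = g0) {
  with_seed(seed, {
    z <- rnorm(n)
    a <- exp(-dt / tau)
    b <- sigma * sqrt(1 - a * a)
    # linear recursion g[t] = g0(1-a) + a g[t-1] + b z[t], via filter()
    drive <- g0 * (1 - a) + b * z
    as.numeric(stats::filter(drive, a, method = "recursive",
                             init = g_init))
  })
}
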