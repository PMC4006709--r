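# Ground-truth generators: rasters and traces with known statistical
# structure, so every measure can be validated without running the network.

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# mean 0, concentration kappa. kappa = Inf returns exact zeros; kappa = 0
# returns uniform angles.
rvonmises0 <- function(n, kappa) {
  if (!is.finite(kappa)) return(numeric(n))
  if (kappa <= 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

fixture_coords <- function(n_neurons, L) {
  n_side <- ceiling(sqrt(n_neurons))
  spacing <- L / n_side
  id <- seq_len(n_neurons) - 1L
  list(x = (id %% n_side) * spacing, y = (id %/% n_side) * spacing)
}

#' Independent Poisson spike rasters
#'
#' Homogeneous Poisson trains, one per neuron, with grid coordinates
#' attached: the null fixture for coherence measures (phases uniform, MPC
#' near zero, ISI CV near one).
#'
#' @param n_neurons number of neurons.
#' @param rate firing rate (Hz); 0 gives an empty raster.
#' @param duration raster duration (ms).
#' @param seed RNG seed.
#' @param L torus side length (mm).
#' @return A [spike_raster()].
#' @export
poisson_raster <- function(n_neurons, rate, duration, seed = 1, L = 1) {
  stopifnot(rate >= 0, duration > 0)
  co <- fixture_coords(n_neurons, L)
  spikes <- with_seed(seed, lapply(seq_len(n_neurons), function(i) {
    if (rate == 0) return(numeric(0))
    n_exp <- rate * duration / 1000
    tt <- cumsum(rexp(ceiling(n_exp + 6 * sqrt(n_exp) + 20),
                      rate = rate / 1000))
    while (length(tt) && tt[length(tt)] < duration)
      tt <- c(tt, tt[length(tt)] +
                cumsum(rexp(100, rate = rate / 1000)))
    tt[tt < duration]
  }))
  spike_raster(spikes, co$x, co$y, L, duration)
}

#' Phase-locked spike rasters with jitter and partial participation
#'
#' Every neuron follows a common clock at `f_osc` Hz: in each cycle it fires
#' with probability `participation_p`, at a phase drawn from a von Mises
#' distribution (mean at the cycle center, concentration `jitter_kappa`).
#' This emulates the sparse, irregular participation of single cells in a
#' fast population rhythm: with `participation_p < 1` the single-cell ISI
#' histogram is multipeaked at integer multiples of the cycle with a
#' geometric envelope, while the population oscillates at `f_osc`. The von
#' Mises jitter makes coherence targets available in closed form: the
#' expected MPC of a jittered train measured against an unjittered reference
#' is `I1(kappa) / I0(kappa)` (the von Mises resultant length), and between
#' two independently jittered trains its square.
#'
#' @param n_neurons number of neurons.
#' @param f_osc clock frequency (Hz).
#' @param participation_p per-cycle firing probability, in `[0, 1]`.
#' @param jitter_kappa von Mises concentration; `Inf` for no jitter. May be
#'   a vector (recycled over neurons), e.g. to keep a reference neuron
#'   jitter-free.
#' @param duration raster duration (ms).
#' @param seed RNG seed.
#' @param L torus side length (mm).
#' @return A [spike_raster()].
#' @export
locked_raster <- function(n_neurons, f_osc = 100, participation_p = 1,
                          jitter_kappa = Inf, duration = 1000, seed = 1,
                          L = 1) {
  stopifnot(participation_p >= 0, participation_p <= 1, f_osc > 0)
  period <- 1000 / f_osc
  n_cycles <- floor(duration / period)
  centers <- (seq_len(n_cycles) - 0.5) * period
  kappa <- rep_len(jitter_kappa, n_neurons)
  co <- fixture_coords(n_neurons, L)
  spikes <- with_seed(seed, lapply(seq_len(n_neurons), function(i) {
    fire <- runif(n_cycles) < participation_p
    th <- rvonmises0(sum(fire), kappa[i])
    tt <- sort(centers[fire] + th / (2 * pi) * period)
    tt <- tt[tt >= 0 & tt < duration]
    tt[c(TRUE, diff(tt) > 1e-9)]
  }))
  spike_raster(spikes, co$x, co$y, L, duration)
}

#' Sinusoid-plus-noise trace
#'
#' `A sin(2 pi f t / 1000 + phi0) + B` sampled every `bin` ms, plus white
#' Gaussian noise: the ground-truth input for validating the windowed
#' sinusoidal fits.
#'
#' @param A amplitude.
#' @param f frequency (Hz).
#' @param phi0 phase offset (radians).
#' @param B baseline.
#' @param noise_sd white noise SD.
#' @param duration trace duration (ms).
#' @param bin sampling interval (ms).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return data.frame with columns `t` (ms, starting at 0) and `value`.
#' @export
sinusoid_trace <- function(A, f, phi0 = 0, B = 0, noise_sd = 0,
                           duration = 1000, bin = 0.1, seed = 1) {
  stopifnot(bin > 0)
  tt <- seq(0, duration - bin / 2, by = bin)
  v <- A * sin(2 * pi * f * tt / 1000 + phi0) + B
  if (noise_sd > 0)
    v <- v + with_seed(seed, rnorm(length(tt), sd = noise_sd))
  data.frame(t = tt, value = v)
}
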