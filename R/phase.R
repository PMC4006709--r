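#' Windowed sinusoidal fits of a mean-field trace
#'
#' Splits a regularly sampled series into non-overlapping windows (20 ms by
#' default, roughly two oscillation cycles at ~100 Hz) and fits each window
#' independently with `A sin(omega t + phi0) + B`, `t` measured from the
#' window start. The fit uses variable projection: for any trial `omega` the
#' remaining parameters enter linearly and are solved in closed form, so the
#' optimization reduces to a 1-D search over `omega` (coarse 1 Hz grid over
#' 20-300 Hz initialized at the window's FFT argmax, then golden-section
#' refinement). Amplitudes are non-negative by construction (`A =
#' sqrt(a^2 + b^2)` with the sign folded into the phase), and the procedure
#' is deterministic. RMSE is reported per window for downstream selection.
#'
#' @param series numeric vector, regularly sampled.
#' @param bin sampling interval (ms).
#' @param window_ms window duration (ms).
#' @param fmin,fmax frequency search band (Hz).
#' @return data.frame of class `window_fits`: one row per window with
#'   `window`, `t_start`, `A`, `omega` (rad/ms), `phi0`, `B`, `rmse`,
#'   `f_hz`.
#' @examples
#' tr <- sinusoid_trace(A = 3, f = 100, B = 1, noise_sd = 0, duration = 200)
#' window_sine_fit(tr$value, bin = 0.1)
#' @export
window_sine_fit <- function(series, bin = 0.1, window_ms = 20,
                            fmin = 20, fmax = 300) {
  wlen <- round(window_ms / bin)
  if (wlen < 8) stop("window too short for the sampling bin")
  n_win <- length(series) %/% wlen
  if (n_win < 1) stop("series shorter than one window")
  tt <- (seq_len(wlen) - 1) * bin
  fit_one <- function(y) {
    ybar <- mean(y)
    rss_at <- function(om) {
      X <- cbind(sin(om * tt), cos(om * tt), 1)
      qr_ <- qr(X)
      res <- qr.resid(qr_, y)
      sum(res^2)
    }
    # FFT initialization, then coarse grid around it, then refine
    sp <- abs(fft(y - ybar))[2:(wlen %/% 2)]
    k0 <- which.max(sp)
    f_fft <- min(max(k0 / (wlen * bin) * 1000, fmin), fmax)
    f_grid <- seq(max(fmin, f_fft - 60), min(fmax, f_fft + 60), by = 1)
    if (length(f_grid) < 2) f_grid <- seq(fmin, fmax, by = 1)
    om_grid <- 2 * pi * f_grid / 1000
    rss <- vapply(om_grid, rss_at, numeric(1))
    i0 <- which.min(rss)
    lo <- om_grid[max(1, i0 - 1)]
    hi <- om_grid[min(length(om_grid), i0 + 1)]
    om <- optimize(rss_at, c(lo, hi), tol = 1e-10)$minimum
    X <- cbind(sin(om * tt), cos(om * tt), 1)
    cf <- qr.coef(qr(X), y)
    resid <- y - X %*% cf
    A <- sqrt(cf[1]^2 + cf[2]^2)
    phi0 <- atan2(cf[2], cf[1])
    c(A = A, omega = om, phi0 = phi0, B = cf[3],
      rmse = sqrt(mean(resid^2)))
  }
  rows <- t(vapply(seq_len(n_win), function(w) {
    fit_one(series[((w - 1) * wlen + 1):(w * wlen)])
  }, numeric(5)))
  out <- data.frame(window = seq_len(n_win),
                    t_start = (seq_len(n_win) - 1) * window_ms,
                    A = rows[, "A"], omega = rows[, "omega"],
                    phi0 = rows[, "phi0"], B = rows[, "B"],
                    rmse = rows[, "rmse"])
  out$f_hz <- out$omega / (2 * pi) * 1000
  class(out) <- c("window_fits", "data.frame")
  out
}

# First local minimum of a kernel-smoothed histogram beyond (or before) the
# main mode, used as an automated stand-in for by-eye inflection detection.
# Returns Inf / -Inf when the distribution is unimodal or degenerate.
hist_cutoff <- function(x, side = c("upper", "lower")) {
  side <- match.arg(side)
  if (length(x) < 5) return(if (side == "upper") Inf else -Inf)
  spread <- diff(range(x))
  if (spread <= 1e-10 * max(abs(x), 1))
    return(if (side == "upper") Inf else -Inf)
  d <- density(x, n = 512)
  im <- which.max(d$y)
  ymax <- d$y[im]
  if (side == "upper" && im >= 510) return(Inf)
  if (side == "lower" && im <= 3) return(-Inf)
  idx <- if (side == "upper") seq(im + 1, 511) else seq(im - 1, 2)
  for (i in idx) {
    lo_nb <- d$y[i - 1]; hi_nb <- d$y[i + 1]
    if (d$y[i] <= lo_nb && d$y[i] <= hi_nb && d$y[i] < 0.5 * ymax)
      return(d$x[i])
  }
  if (side == "upper") Inf else -Inf
}

#' Select well-fitted windows
#'
#' Rejects windows whose fit quality or frequency falls in the tail of the
#' empirical distribution across windows: for each variable, windows with
#' RMSE beyond the first minimum of a kernel-smoothed RMSE histogram past
#' the main mode are rejected; the fitted angular frequencies, pooled over
#' variables, are screened the same way on both sides. A window is accepted
#' only if it survives every criterion for every variable.
#'
#' @param fits a named list of `window_fits` (one per variable, same
#'   windows), e.g. `list(v = ..., i_syn = ..., i_int = ...)`, or a single
#'   `window_fits`.
#' @return Logical vector, one entry per window, with attribute
#'   `rejection_fraction`.
#' @export
select_windows <- function(fits) {
  if (inherits(fits, "window_fits")) fits <- list(fits)
  nw <- nrow(fits[[1]])
  accepted <- rep(TRUE, nw)
  for (f in fits) {
    stopifnot(nrow(f) == nw)
    cut <- hist_cutoff(f$rmse, "upper")
    accepted <- accepted & f$rmse <= cut
  }
  om <- unlist(lapply(fits, `[[`, "omega"), use.names = FALSE)
  lo <- hist_cutoff(om, "lower")
  hi <- hist_cutoff(om, "upper")
  for (f in fits) accepted <- accepted & f$omega >= lo & f$omega <= hi
  structure(accepted, rejection_fraction = mean(!accepted))
}

peak_time <- function(omega, phi0, t0 = 0) {
  # smallest t >= t0 with omega t + phi0 = pi/2 (mod 2 pi)
  delta <- (pi / 2 - phi0 - omega * t0) %% (2 * pi)
  t0 + delta / omega
}

#' Phase leads of the mean currents relative to the voltage oscillation
#'
#' For each accepted window, the time `t_v` of the first peak of the fitted
#' mean-voltage sinusoid is found, then the time `t_X` of the first peak of
#' each current's fit at or after `t_v`; the lead is
#' `dphi_X = omega_X (t_v - t_X)`, lying in `(-2 pi, 0]`. For reporting,
#' circular means are computed on the unit circle so the wrapping convention
#' is immaterial; `dphi mod 2 pi` gives the positive-branch value (~1 rad
#' for the synaptic current in these networks; exactly `pi` for the
#' intrinsic current of an IF network, whose intrinsic current is `-g v`).
#'
#' @param fits_v,fits_syn,fits_int `window_fits` for the mean membrane
#'   potential, mean synaptic current, and mean intrinsic current.
#' @param accepted logical window mask from [select_windows()]; default all.
#' @return data.frame of class `phase_records`: `window`, `dphi_syn`,
#'   `dphi_int` (radians in `(-2 pi, 0]`), `A_v`, `A_syn`, `A_int`.
#' @export
phase_leads <- function(fits_v, fits_syn, fits_int,
                        accepted = rep(TRUE, nrow(fits_v))) {
  idx <- which(accepted)
  rows <- lapply(idx, function(w) {
    t_v <- peak_time(fits_v$omega[w], fits_v$phi0[w], 0)
    lead <- function(f) {
      t_x <- peak_time(f$omega[w], f$phi0[w], t_v)
      d <- f$omega[w] * (t_v - t_x)
      if (d <= -2 * pi) d <- d %% (2 * pi) - 2 * pi
      d
    }
    data.frame(window = w, dphi_syn = lead(fits_syn),
               dphi_int = lead(fits_int), A_v = fits_v$A[w],
               A_syn = fits_syn$A[w], A_int = fits_int$A[w])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_records", "data.frame")
  out
}

#' Circular-linear correlation
#'
#' Correlation between a circular variable `theta` and a linear variable
#' `x`, computed from the Pearson correlations of `x` with `cos(theta)` and
#' `sin(theta)`:
#' \deqn{r = \sqrt{\frac{r_{xc}^2 + r_{xs}^2 - 2 r_{xc} r_{xs} r_{cs}}
#'       {1 - r_{cs}^2}}}
#' The p-value of the no-correlation null uses the large-sample
#' approximation `n r^2 ~ chi-square(2)`.
#'
#' @param theta angles (radians; any wrapping).
#' @param x linear variable, same length.
#' @return list with `r`, `p`, `n`.
#' @export
circ_linear_corr <- function(theta, x) {
  ok <- is.finite(theta) & is.finite(x)
  theta <- theta[ok]; x <- x[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 paired observations")
  ct <- cos(theta); st <- sin(theta)
  if (sd(x) == 0 || sd(ct) == 0 || sd(st) == 0)
    stop("degenerate variance in circular-linear correlation")
  rxc <- cor(x, ct); rxs <- cor(x, st); rcs <- cor(ct, st)
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  r <- sqrt(max(0, r2))
  list(r = r, p = pchisq(n * r^2, df = 2, lower.tail = FALSE), n = n)
}

circular_mean <- function(theta) Arg(mean(exp(1i * theta))) %% (2 * pi)

#' Full phase analysis of a network simulation
#'
#' Runs the windowed sinusoidal fits on the mean membrane potential, mean
#' synaptic current and mean intrinsic current of a simulation, applies the
#' window-rejection rule, extracts per-window phase leads and amplitudes,
#' and evaluates the circular-linear correlations between each phase
#' variable and the local oscillation amplitude `A_v` (the amplitude of the
#' voltage fit, a temporally local measure of synchrony).
#'
#' @param sim a `network_sim`.
#' @param window_ms window duration (ms).
#' @return list with `fits` (list of `window_fits`), `accepted`,
#'   `rejection_fraction`, `records` ([phase_leads()] output),
#'   `correlations` (data.frame: variable, r, p, n), `mean_dphi_syn`,
#'   `mean_dphi_int` (circular means, in `[0, 2 pi)`).
#' @export
analyze_phases <- function(sim, window_ms = 20) {
  tr <- sim$trace
  fits <- list(v = window_sine_fit(tr$v, bin = sim$trace_bin,
                                   window_ms = window_ms),
               i_syn = window_sine_fit(tr$i_syn, bin = sim$trace_bin,
                                       window_ms = window_ms),
               i_int = window_sine_fit(tr$i_int, bin = sim$trace_bin,
                                       window_ms = window_ms))
  acc <- select_windows(fits)
  rec <- phase_leads(fits$v, fits$i_syn, fits$i_int, accepted = acc)
  safe_cl <- function(theta, x) {
    # an IF network has dphi_int fixed at -pi exactly (I_int = -g v), which
    # makes this correlation structurally degenerate; report NA
    tryCatch(circ_linear_corr(theta, x),
             error = function(e) list(r = NA_real_, p = NA_real_,
                                      n = length(x)))
  }
  corr <- rbind(
    data.frame(variable = "dphi_syn_vs_Av",
               as.data.frame(safe_cl(rec$dphi_syn, rec$A_v))),
    data.frame(variable = "dphi_int_vs_Av",
               as.data.frame(safe_cl(rec$dphi_int, rec$A_v))),
    data.frame(variable = "dphi_mismatch_vs_Av",
               as.data.frame(safe_cl(rec$dphi_syn - rec$dphi_int,
                                     rec$A_v))))
  list(fits = fits, accepted = as.logical(acc),
       rejection_fraction = attr(acc, "rejection_fraction"),
       records = rec, correlations = corr,
       mean_dphi_syn = circular_mean(rec$dphi_syn),
       mean_dphi_int = circular_mean(rec$dphi_int))
}

# Oscillation phase (radians) of each sample time under the per-window
# voltage fits; NA outside accepted windows. Phase pi/2 is the fitted peak,
# 3 pi/2 the trough.
sample_phases <- function(times, fits_v, accepted, window_ms = 20) {
  w <- floor(times / window_ms) + 1L
  ok <- w >= 1L & w <= nrow(fits_v)
  ph <- rep(NA_real_, length(times))
  wi <- w[ok]
  ph[ok] <- (fits_v$omega[wi] * (times[ok] - fits_v$t_start[wi]) +
               fits_v$phi0[wi]) %% (2 * pi)
  ph[!is.na(ph) & !accepted[pmin(pmax(w, 1L), length(accepted))]] <- NA
  ph
}

#' Phase-conditioned probability density of a sampled quantity
#'
#' Gaussian-kernel density of pooled samples (typically per-neuron intrinsic
#' currents), either unconditional or restricted to samples whose
#' oscillation phase lies within `half_width` radians of the fitted peak or
#' trough of the mean-voltage oscillation. Samples during refractory
#' periods, and samples in rejected windows, are excluded.
#'
#' @param values numeric vector of samples.
#' @param times sample times (ms), same length.
#' @param fits_v `window_fits` of the mean membrane potential.
#' @param accepted logical window mask from [select_windows()].
#' @param condition `"all"`, `"peak"` or `"trough"`.
#' @param half_width phase half-width of the conditioning band (radians).
#' @param refractory optional logical vector marking samples to drop.
#' @param window_ms window duration used for the fits (ms).
#' @param ... passed to [stats::density()].
#' @return A `density` object with attribute `n_kept`.
#' @export
phase_conditioned_pdf <- function(values, times, fits_v, accepted,
                                  condition = c("all", "peak", "trough"),
                                  half_width = pi / 8, refractory = NULL,
                                  window_ms = 20, ...) {
  condition <- match.arg(condition)
  keep <- rep(TRUE, length(values))
  if (!is.null(refractory)) keep <- keep & !refractory
  ph <- sample_phases(times, fits_v, accepted, window_ms)
  keep <- keep & !is.na(ph)
  if (condition != "all") {
    target <- if (condition == "peak") pi / 2 else 3 * pi / 2
    dist <- abs((ph - target + pi) %% (2 * pi) - pi)
    keep <- keep & dist <= half_width
  }
  if (!any(keep)) stop("no samples satisfy the conditioning")
  d <- density(values[keep], ...)
  attr(d, "n_kept") <- sum(keep)
  d
}

# Product-Gaussian-kernel 2-D KDE evaluated on a regular grid, plus its
# marginals computed with the same kernels and data, so that the deviation
# from independence integrates to ~0 by construction.
kde2_product <- function(a, b, hx, hy, n_grid = 128, n_max = 20000,
                         seed = 1) {
  n <- length(a)
  if (n > n_max) {
    idx <- with_seed(seed, sample.int(n, n_max))
    a <- a[idx]; b <- b[idx]; n <- n_max
  }
  gx <- seq(min(a) - 3 * hx, max(a) + 3 * hx, length.out = n_grid)
  gy <- seq(min(b) - 3 * hy, max(b) + 3 * hy, length.out = n_grid)
  Kx <- dnorm(outer(gx, a, "-") / hx) / hx
  Ky <- dnorm(outer(gy, b, "-") / hy) / hy
  joint <- (Kx %*% t(Ky)) / n
  list(x = gx, y = gy, joint = joint,
       px = rowMeans(Kx), py = rowMeans(Ky))
}

#' Deviation from independence of paired samples
#'
#' Estimates the bivariate density `p(x, y)` of paired samples (intrinsic
#' currents of adjacent neurons) with symmetric Gaussian kernels, and the
#' product of its marginals, and returns
#' `D(x, y) = p(x, y) - p(x) p(y)`, which integrates to zero. Positive
#' diagonal structure indicates coherent co-fluctuation beyond what the
#' marginals imply; conditioning the samples on the oscillation phase before
#' calling this function removes the common-rhythm contribution.
#'
#' @param samples_a,samples_b paired samples.
#' @param bw kernel SD used on both axes (symmetric kernels); default the
#'   mean of the two Silverman bandwidths.
#' @param n_grid evaluation grid size per axis.
#' @param n_max subsample cap for the KDE (deterministic given `seed`).
#' @param seed subsampling seed.
#' @return list of class `indep_deviation`: `x`, `y`, `D` (matrix),
#'   `joint`, `px`, `py`, `bw`.
#' @export
deviation_from_independence <- function(samples_a, samples_b, bw = NULL,
                                        n_grid = 128, n_max = 20000,
                                        seed = 1) {
  stopifnot(length(samples_a) == length(samples_b))
  if (is.null(bw)) bw <- mean(c(bw.nrd0(samples_a), bw.nrd0(samples_b)))
  k <- kde2_product(samples_a, samples_b, bw, bw, n_grid, n_max, seed)
  D <- k$joint - outer(k$px, k$py)
  structure(list(x = k$x, y = k$y, D = D, joint = k$joint,
                 px = k$px, py = k$py, bw = bw),
            class = "indep_deviation")
}

#' Bivariate density of the mean and SD of the membrane potential
#'
#' Kernel density of the per-time-bin (mean, SD) of the membrane potential
#' across neurons, the plane in which strongly synchronized networks trace a
#' characteristic loop: the two axes have very different scales, so per-axis
#' Silverman bandwidths are used (a product-kernel stand-in for adaptive
#' estimators).
#'
#' @param mean_v per-bin cross-neuron mean of `v` (the `v` column of a
#'   simulation trace).
#' @param sd_v per-bin cross-neuron SD of `v` (the `sd_v` column).
#' @param n_grid grid size per axis.
#' @param n_max subsample cap.
#' @param seed subsampling seed.
#' @return list with `x` (mean grid), `y` (SD grid), `z` (density matrix),
#'   `bw` (the two bandwidths).
#' @export
mean_sd_density <- function(mean_v, sd_v, n_grid = 128, n_max = 20000,
                            seed = 1) {
  stopifnot(length(mean_v) == length(sd_v))
  hx <- bw.nrd0(mean_v); hy <- bw.nrd0(sd_v)
  if (hx <= 0 || hy <= 0) {  # degenerate axis: fall back to a point mass
    hx <- max(hx, 1e-6); hy <- max(hy, 1e-6)
  }
  k <- kde2_product(mean_v, sd_v, hx, hy, n_grid, n_max, seed)
  list(x = k$x, y = k$y, z = k$joint, bw = c(hx, hy))
}

#' Pooled per-neuron intrinsic-current samples of a simulation
#'
#' Flattens the recorded per-neuron intrinsic-current matrices of a
#' [simulate_network()] run (with `record_neurons` set) into pooled vectors
#' of values, sample times (aligned to the window-fit time base) and
#' refractory flags, ready for [phase_conditioned_pdf()] and
#' [deviation_from_independence()].
#'
#' @param sim a `network_sim` with recorded neurons.
#' @param neurons indices *within the recorded set* to pool (default all).
#' @return list with `values`, `times`, `refractory`.
#' @export
intrinsic_current_samples <- function(sim, neurons = NULL) {
  if (length(sim$rec_neurons) == 0)
    stop("simulation was run without record_neurons")
  cols <- if (is.null(neurons)) seq_along(sim$rec_neurons) else neurons
  nt <- nrow(sim$rec_iint)
  tt <- sim$trace$t - sim$trace_bin  # local time base of the window fits
  list(values = as.numeric(sim$rec_iint[, cols]),
       times = rep(tt, times = length(cols)),
       refractory = as.logical(sim$rec_refractory[, cols]))
}
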