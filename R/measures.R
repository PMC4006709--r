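#' Single-cell spiking statistics
#'
#' Firing rate as the inverse of the mean inter-spike interval, and the ISI
#' coefficient of variation (sample SD with n-1 denominator over the mean).
#' CV is 0 for a clock-like train and about 1 for Poisson firing.
#'
#' @param spikes strictly increasing spike times (ms).
#' @return Named numeric vector `c(rate, cv)`, rate in Hz.
#' @examples
#' isi_stats(seq(0, 1000, by = 10))  # 100 Hz, cv 0
#' @export
isi_stats <- function(spikes) {
  if (length(spikes) < 3) stop("need at least 3 spikes for ISI statistics")
  isi <- diff(spikes)
  c(rate = 1000 / mean(isi), cv = sd(isi) / mean(isi))
}

#' Mean Phase Coherence of a pair of spike trains
#'
#' Each spike of train `a` falling inside an inter-spike interval of train
#' `b` is assigned the phase `2 pi (t_a - t_b^prev) / (t_b^next - t_b^prev)`;
#' the MPC is the complex resultant `mean(exp(1i * phase))` over the `S`
#' such spikes. Its modulus is at most 1; the real part is positive for
#' in-phase and negative for anti-phase locking. A spike of `a` exactly
#' coincident with a spike of `b` is assigned phase 0 of the following
#' interval; spikes outside `b`'s span are not counted.
#'
#' @param spikes_a,spikes_b strictly increasing spike times (ms); `b` needs
#'   at least 2 spikes.
#' @return Complex scalar with attribute `S` (number of counted spikes);
#'   `NA` with `S = 0` when no spike of `a` falls within `b`'s intervals.
#' @export
mpc_pair <- function(spikes_a, spikes_b) {
  if (length(spikes_b) < 2)
    return(structure(NA_complex_, S = 0L))
  idx <- findInterval(spikes_a, spikes_b)
  keep <- idx >= 1L & idx < length(spikes_b)
  S <- sum(keep)
  if (S == 0L) return(structure(NA_complex_, S = 0L))
  i <- idx[keep]
  ph <- (spikes_a[keep] - spikes_b[i]) / (spikes_b[i + 1L] - spikes_b[i])
  structure(mean(exp(2i * pi * ph)), S = S)
}

# Ordered neuron pairs separated by m grid steps purely along x or y.
# Restricting to axial separations gives every admissible distance the same
# number of pairs (up to the antipodal class, where +m and -m coincide).
axial_pairs <- function(n_side) {
  n <- n_side
  id <- 0:(n * n - 1)
  row <- id %/% n
  col <- id %% n
  lapply(seq_len(n %/% 2), function(m) {
    offs <- if (2 * m == n) list(c(m, 0), c(0, m))
            else list(c(m, 0), c(-m, 0), c(0, m), c(0, -m))
    do.call(rbind, lapply(offs, function(o) {
      cbind(i = id, j = ((row + o[2]) %% n) * n + ((col + o[1]) %% n))
    }))
  })
}

#' Distance-resolved and global Mean Phase Coherence
#'
#' Exploiting the toroidal symmetry, pairwise MPC values are averaged over
#' ordered neuron pairs separated by the same distance; only distances that
#' are multiples of the grid spacing along the x or y direction are used, so
#' that every distance class contains the same number of pairs. The average
#' over a class is real up to estimation error; its real part is reported.
#' The global coherence is the unweighted mean of the per-distance averages
#' (a pair-weighted global mean is attached as an attribute).
#'
#' @param raster a [spike_raster()] whose neurons sit on a square grid.
#' @return `mpc_by_distance()`: data.frame with `distance_mm`, `m` (grid
#'   steps), `r_mpc`, `n_pairs`, `mean_S`. `mpc_global()`: scalar, with
#'   attributes `pair_weighted` and `by_distance`.
#' @export
mpc_by_distance <- function(raster) {
  N <- n_neurons(raster)
  n <- round(sqrt(N))
  if (n * n != N) stop("raster does not sit on a square grid")
  spacing <- raster$L / n
  classes <- axial_pairs(n)
  rows <- lapply(seq_along(classes), function(m) {
    pr <- classes[[m]]
    vals <- complex(length(pr[, 1]))
    Ss <- integer(length(vals))
    for (q in seq_len(nrow(pr))) {
      v <- mpc_pair(raster$spikes[[pr[q, 1] + 1L]],
                    raster$spikes[[pr[q, 2] + 1L]])
      vals[q] <- v
      Ss[q] <- attr(v, "S")
    }
    ok <- !is.na(vals)
    data.frame(distance_mm = m * spacing, m = m,
               r_mpc = Re(mean(vals[ok])),
               n_pairs = sum(ok), mean_S = mean(Ss[ok]))
  })
  do.call(rbind, rows)
}

#' @rdname mpc_by_distance
#' @export
mpc_global <- function(raster) {
  bd <- mpc_by_distance(raster)
  g <- mean(bd$r_mpc)
  structure(g,
            pair_weighted = sum(bd$r_mpc * bd$n_pairs) / sum(bd$n_pairs),
            by_distance = bd)
}

#' Population rate histogram
#'
#' Counts of all spikes in the raster per time bin; the collective activity
#' whose spectrum defines the network frequency.
#'
#' @param raster a [spike_raster()].
#' @param bin bin width (ms); default 0.01 ms (one integration step).
#' @return Integer vector of counts with attribute `bin_ms`; sums to the
#'   total number of spikes inside `[0, duration)`.
#' @export
population_rate <- function(raster, bin = 0.01) {
  stopifnot(bin > 0)
  nb <- ceiling(raster$duration / bin)
  tt <- unlist(raster$spikes, use.names = FALSE)
  counts <- if (length(tt)) tabulate(pmin(floor(tt / bin) + 1L, nb), nb)
            else integer(nb)
  structure(counts, bin_ms = bin)
}

welch_psd <- function(x, bin_ms, seg_ms = 1000) {
  n <- length(x)
  x <- x - mean(x)
  L <- min(n, max(32, round(seg_ms / bin_ms)))
  step <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))  # Hann
  norm <- sum(win^2)
  half <- floor(L / 2) + 1
  p <- numeric(half)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg))^2 / norm
    p <- p + sp[seq_len(half)]
  }
  p <- p / length(starts)
  f <- (seq_len(half) - 1) / (L * bin_ms) * 1000  # Hz
  data.frame(f = f, power = p)
}

#' Network oscillation frequency from the population-rate spectrum
#'
#' Estimates the power spectrum of the mean-subtracted population rate
#' (Welch periodogram: ~1 s Hann-tapered segments, 50% overlap) and fits a
#' Gaussian to the dominant peak region, +/- `fit_halfwidth` Hz around the
#' spectral argmax within `[fmin, fmax]`; the fitted center is the network
#' frequency. If the candidate peak does not rise above the noise floor (at
#' least `noise_factor` times the median in-band power) the series is
#' flagged as non-oscillating and the frequency is `NA`.
#'
#' @param pr population-rate counts (from [population_rate()]) or any
#'   regularly sampled series.
#' @param bin_ms sampling bin (ms); taken from the `bin_ms` attribute when
#'   present.
#' @param fmin,fmax search band (Hz).
#' @param fit_halfwidth half-width of the Gaussian fit region (Hz).
#' @param noise_factor peak-to-median power ratio required to declare an
#'   oscillation.
#' @param seg_ms Welch segment length (ms).
#' @return list of class `network_frequency`: `frequency` (Hz or `NA`),
#'   `oscillating`, `peak_power`, `spectrum` (data.frame `f`, `power`).
#' @export
network_frequency <- function(pr, bin_ms = attr(pr, "bin_ms"),
                              fmin = 20, fmax = 300, fit_halfwidth = 20,
                              noise_factor = 5, seg_ms = 1000) {
  if (is.null(bin_ms)) stop("bin_ms must be supplied")
  spec <- welch_psd(as.numeric(pr), bin_ms, seg_ms)
  band <- spec[spec$f >= fmin & spec$f <= fmax, ]
  if (nrow(band) < 5) stop("series too short for spectral estimation")
  ipk <- which.max(band$power)
  oscillating <- band$power[ipk] >= noise_factor * median(band$power)
  out <- list(frequency = NA_real_, oscillating = oscillating,
              peak_power = band$power[ipk], spectrum = spec)
  class(out) <- "network_frequency"
  if (!oscillating) return(out)
  f0 <- band$f[ipk]
  reg <- band[abs(band$f - f0) <= fit_halfwidth, ]
  fit <- tryCatch({
    m <- nls(power ~ a * exp(-(f - mu)^2 / (2 * s2)), data = reg,
             start = list(a = band$power[ipk], mu = f0,
                          s2 = (fit_halfwidth / 4)^2),
             control = stats::nls.control(maxiter = 200))
    coef(m)[["mu"]]
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  if (is.finite(fit) && abs(fit - f0) > fit_halfwidth) fit <- NA_real_
  if (!is.finite(fit)) {
    # log-parabola fallback: a Gaussian is a parabola in log power
    top <- reg[reg$power > 0.2 * max(reg$power), ]
    cf <- stats::lm(log(power) ~ f + I(f^2), data = top)$coefficients
    fit <- if (cf[[3]] < 0) -cf[[2]] / (2 * cf[[3]]) else f0
  }
  out$frequency <- as.numeric(fit)
  out
}

#' @export
print.network_frequency <- function(x, ...) {
  if (x$oscillating)
    cat(sprintf("<network frequency>  %.2f Hz (peak power %.3g)\n",
                x$frequency, x$peak_power))
  else cat("<network frequency>  no oscillation above the noise floor\n")
  invisible(x)
}

#' Average Pearson correlation versus distance
#'
#' Mean Pearson correlation between per-neuron time series (synaptic
#' currents, membrane potentials, ...) over the same axial distance classes
#' used for the MPC. Zero-variance series are excluded.
#'
#' @param traces numeric matrix, time samples in rows, one column per neuron
#'   in grid order (0-based id = column - 1).
#' @param L torus side length (mm).
#' @return data.frame with `distance_mm`, `m`, `r`, `n_pairs`.
#' @export
correlation_by_distance <- function(traces, L = 1) {
  N <- ncol(traces)
  n <- round(sqrt(N))
  if (n * n != N) stop("columns do not form a square grid")
  spacing <- L / n
  cc <- suppressWarnings(cor(traces))
  classes <- axial_pairs(n)
  do.call(rbind, lapply(seq_along(classes), function(m) {
    pr <- classes[[m]]
    vals <- cc[cbind(pr[, 1] + 1L, pr[, 2] + 1L)]
    data.frame(distance_mm = m * spacing, m = m,
               r = mean(vals, na.rm = TRUE),
               n_pairs = sum(!is.na(vals)))
  }))
}

#' Summary statistics of a network simulation
#'
#' Per-neuron rates and ISI CVs (neurons with fewer than 3 spikes are
#' skipped), the Gaussian-fit network frequency, and the global Mean Phase
#' Coherence, bundled for reporting.
#'
#' @param sim a `network_sim` from [simulate_network()].
#' @param mpc include the (relatively slow) MPC computation.
#' @return list with `rate_mean`, `rate_sd`, `isi_cv_mean`, `f_net_hz`,
#'   `oscillating`, `r_mpc_global`, `r_mpc_by_distance`.
#' @export
network_measures <- function(sim, mpc = TRUE) {
  st <- lapply(sim$raster$spikes,
               function(s) if (length(s) >= 3) isi_stats(s) else NULL)
  st <- do.call(rbind, st[!vapply(st, is.null, logical(1))])
  nf <- network_frequency(sim$pop_counts, bin_ms = sim$rate_bin)
  out <- list(rate_mean = mean(st[, "rate"]), rate_sd = sd(st[, "rate"]),
              isi_cv_mean = mean(st[, "cv"]),
              f_net_hz = nf$frequency, oscillating = nf$oscillating,
              r_mpc_global = NA_real_, r_mpc_by_distance = NULL)
  if (mpc) {
    g <- mpc_global(sim$raster)
    out$r_mpc_global <- as.numeric(g)
    out$r_mpc_by_distance <- attr(g, "by_distance")
  }
  out
}
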