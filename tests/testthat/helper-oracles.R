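# Independent brute-force oracles, deliberately naive.

# MPC by explicit per-spike search over b's intervals.
mpc_oracle <- function(a, b) {
  vals <- complex(0)
  for (t in a) {
    prev <- b[b <= t]
    nxt <- b[b > t]
    if (length(prev) == 0 || length(nxt) == 0) next
    p <- max(prev); n <- min(nxt)
    vals <- c(vals, exp(2i * pi * (t - p) / (n - p)))
  }
  if (length(vals) == 0) return(NA_complex_)
  mean(vals)
}

# circular-linear correlation from its defining Pearson correlations
circ_linear_oracle <- function(theta, x) {
  rxc <- cor(x, cos(theta)); rxs <- cor(x, sin(theta))
  rcs <- cor(cos(theta), sin(theta))
  sqrt((rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2))
}

# von Mises resultant length
vm_resultant <- function(kappa) besselI(kappa, 1) / besselI(kappa, 0)

# trapezoid rule on a regular grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

grid2_integral <- function(x, y, z) {
  dx <- mean(diff(x)); dy <- mean(diff(y))
  sum(z) * dx * dy
}

canonical_bg <- function() background_params()
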