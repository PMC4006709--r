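---
title: "Models, measures and design choices in ingnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, measures and design choices in ingnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ingnet)
```

## The scientific problem

Fast-spiking inhibitory interneurons generate high-frequency (gamma and
faster) population rhythms through mutual inhibition, even while each
individual cell fires irregularly and skips most cycles (the
fluctuation-driven regime). Some interneuron classes additionally show
*intrinsic subthreshold oscillations* — damped voltage resonance in the
10–50 Hz band. `ingnet` simulates all-to-all inhibitory networks of two
minimal models that differ only in this one property, and provides the
measurement suite needed to quantify how intrinsic resonance reshapes the
collective rhythm.

## Models

### Neurons

Voltage is the deviation from the leak reversal potential (0 mV). The IF
neuron is a leaky integrator,
$$C\dot v = -gv + I_{\mathrm{syn}} + I_{\mathrm{bg}},$$
and the GIF neuron adds a restorative recovery variable $w$,
$$C\dot v = -gv - g_1 w + I_{\mathrm{syn}} + I_{\mathrm{bg}},\qquad
\tau_1\dot w = v - w,$$
the linear caricature of a resonant current. With the canonical constants
($C=10$ nF, $g=1\ \mu$S, $g_1=4\ \mu$S, $\tau_1=10$ ms) both models have a
10 ms membrane time constant and the GIF's eigenvalues
$\lambda = -0.1 \pm 0.2i\ \mathrm{ms}^{-1}$ give intrinsic oscillations at
$\approx 32$ Hz (`linearize()`). Spikes are threshold–reset: crossing
$v_{th} = 6.3$ mV emits a spike, $v$ jumps to $v_{reset}$ and is clamped
for $\tau_{ref} = 3$ ms while $w$ keeps relaxing (toward the clamped
voltage); $w$ is *not* reset, which is standard for two-variable linear
models.

**The sign of `v_reset`.** The source material for this parameter set
prints a reset magnitude of 3 mV while the surrounding text describes the
reset as lying below the leak reversal, leaving the sign ambiguous. The two
candidates are empirically distinguishable: with $v_{reset} = +3$ mV the
isolated IF and GIF reproduce the reference background-driven statistics
almost exactly (rates 89.6 / 73.6 Hz against 90.3 / 73.7; ISI CVs 0.833 /
0.803 against 0.81 / 0.78, 50 s runs), whereas $-3$ mV yields 75 / 77 Hz —
the wrong magnitude *and* the wrong ordering between models. The package
therefore defaults to $v_{reset} = +3$ mV — a value sitting between the
canonical resting potentials (2.5 mV IF, 1.25 mV GIF) and threshold — with
the choice justified purely by the quantitative match of four independent
statistics. It is a single configurable number (`if_neuron(v_reset = )`),
and the deviation from the textual reading is recorded.

### Background input

Each neuron receives two private conductances — excitatory
($g_{e0}=0.5\ \mu$S, $\sigma_e=0.6\ \mu$S, $E_e=70$ mV) and inhibitory
(tied by ratios $k=5$, $\sigma$-ratio $2.5$, $E_i=-10$ mV), both with 1 ms
correlation time — modelled as *rectified* Ornstein–Uhlenbeck processes.
The latent OU state is advanced once per step with the exact transition
$$g' = g_0 + (g-g_0)e^{-\Delta t/\tau} +
\sigma\sqrt{1-e^{-2\Delta t/\tau}}\,z,$$
and the rectification $\max(g,0)$ is applied only where the conductance
multiplies a driving force. Clipping at the point of use (rather than
clipping the stored state) preserves the exactness of the OU update; for
the canonical parameters the excitatory state is negative $<1\%$ of the
time and the inhibitory state $\approx 5\%$, so the distinction is minor
but it is the one the exact-update scheme supports. Every neuron's two
processes draw from independent sub-streams derived from the master seed
(splitmix-seeded Mersenne Twister engines), making runs bit-reproducible
and spatially independent by construction.

### Network

$N = 400$ neurons on a $20\times20$ torus of side $L = 1$ mm, all-to-all
identical inhibitory synapses. Distance enters only through conduction
delays $d(i,j)/s + \delta_{syn}$ with $s = 0.141$ mm/ms and
$\delta_{syn} = 1$ ms, rounded to whole integration steps and served
through a ring buffer. A presynaptic spike increments the target's synaptic
conductance by $\hat g = 0.25\ \mu$S after its delay; the summed
conductance decays exponentially with $\tau_{syn} = 1$ ms (a value chosen
to match fast GABA-A kinetics and the background inhibitory time constant;
the printed source is ambiguous here, and the constant is configurable).
The recurrent reversal is $-10$ mV (hyperpolarizing) or $+4$ mV (shunting
variant). $L = 1$ mm keeps the longest delay ($\approx 6$ ms) below the
$\approx 10$ ms period of the collective rhythm, which is what makes the
delay topology dynamically relevant.

### Integration

A fixed-step 7-stage sixth-order Runge–Kutta advances $(v, w)$ with
$\Delta t = 0.01$ ms; all conductances are held constant within a step, and
threshold, reset and refractoriness are evaluated once per step. Because
the subthreshold system is linear and the inputs are piecewise constant,
the one-step RK map reproduces the matrix exponential through order
$(\Delta t)^6$; at $\Delta t/\tau_{m} = 10^{-3}$ integration error is
negligible against the Monte-Carlo error of any measured statistic, and the
once-per-step event handling (not the tableau) is the binding
approximation. Initial conditions are $v = w = 0$ with conductances at
their means; the first 2 s are discarded, which dwarfs every relaxation
time in the model, so the choice of initial state is immaterial to reported
statistics.

## Measures

* **Single-cell statistics** — rate $= 1/\overline{\mathrm{ISI}}$, ISI CV
  (sample SD / mean). In the canonical networks single cells fire at
  $\approx 23$–27 Hz while the population oscillates at $\approx 103$ Hz:
  the mean ISI is $\approx 4$ population periods.
* **Mean Phase Coherence** — each spike of neuron A falling in an ISI of
  neuron B contributes $e^{2\pi i (t_a - t_b^{prev})/(t_b^{next} -
  t_b^{prev})}$; pairwise values are averaged over ordered pairs at equal
  torus distance (axial separations only, so distance classes have equal
  pair counts), and the global index is the unweighted mean over distance
  classes. A spike exactly coincident with a B spike takes phase 0 of the
  following interval (a measure-zero tie needing a deterministic rule).
  The pair-weighted global mean is also attached, since the antipodal
  distance class has half the pairs of the others.
* **Network frequency** — Welch periodogram of the mean-subtracted
  population rate (1 s Hann segments, 50% overlap) and a Gaussian fitted
  over $\pm20$ Hz around the in-band (20–300 Hz) argmax; the fitted center
  is reported. The Gaussian-peak extraction is the defined quantity; the
  Welch estimator replaces a multitaper estimator, a substitution that
  moves the peak far less than the fit tolerance at these signal-to-noise
  ratios. A peak under 5× the median in-band power is flagged "no
  oscillation" (with ≥5 averaged segments the max-to-median ratio of a
  flat spectrum stays well below this).
* **Windowed sinusoidal fits** — mean-field traces (0.1 ms bins) are cut
  into non-overlapping 20 ms windows (~2 cycles) and each window of each
  variable ($\bar v$, $\bar I_{syn}$, $\bar I_{int}$) is fitted with
  $A\sin(\omega t + \varphi_0) + B$ by variable projection: the linear
  parameters are profiled out and $\omega$ is found by a deterministic
  1 Hz grid search plus golden-section refinement, seeded at the window's
  FFT argmax. No random restarts: a window whose fit is poor is simply
  rejected downstream.
* **Window rejection** — the visual-inspection step of the original
  procedure is automated as: reject windows whose RMSE (per variable) lies
  beyond the first local minimum of a kernel-smoothed histogram past its
  main mode, or whose $\omega$ (pooled over variables) falls outside the
  analogous two-sided cutoffs. The rejection fraction is reported; on
  canonical networks it falls in the 0–9% range. The surrogate is
  documented as such, not asserted to be equivalent to by-eye selection.
* **Phase leads** — within each accepted window,
  $\Delta\varphi_X = \omega_X(t_v - t_X)$ where $t_v$ is the first peak of
  the voltage fit and $t_X$ the first peak of current $X$ at or after
  $t_v$, so $\Delta\varphi_X \in (-2\pi, 0]$. Circular means are taken on
  the unit circle, making the wrapping convention immaterial; the
  positive-branch value ($\Delta\varphi \bmod 2\pi$) is what reported
  means like "$\approx 1$ rad" refer to. For IF networks
  $\Delta\varphi_{int} \equiv \pi$ identically ($I_{int} = -gv$), so its
  circular-linear correlation with amplitude is structurally degenerate
  and reported as `NA` rather than a noise-driven number.
* **Circular–linear correlation** — the Zar/CircStat formula from the
  Pearson correlations of the linear variable with $\cos\theta$ and
  $\sin\theta$; p-values from the $nr^2 \sim \chi^2_2$ approximation.
* **Phase-conditioned densities** — Gaussian-kernel densities of pooled
  per-neuron intrinsic currents, unconditional or restricted to samples
  within $\pi/8$ rad of the fitted peak/trough of the mean-voltage
  oscillation (the conditioning half-width is not stated in the source;
  $\pi/8$ isolates the extrema while keeping $1/8$ of samples, and is
  configurable). Refractory samples are excluded. The bivariate deviation
  from independence $D(x,y) = \hat p(x,y) - \hat p(x)\hat p(y)$ uses
  symmetric Gaussian product kernels with a common bandwidth, with the
  marginals computed from the same kernels and data so $D$ integrates to
  zero by construction. The mean/SD-of-voltage density uses per-axis
  Silverman bandwidths in place of an adaptive-diffusion estimator — a
  dialect substitution flagged because only qualitative claims rest on it.

## Calibration ("r-matched" models)

`match_rate_threshold()` adjusts $v_{th}$ of an isolated neuron until its
background-driven rate matches a target within 1%. The rate–threshold map
is made deterministic by re-using one frozen noise realization across all
bisection iterates (common random numbers); a final check re-simulates at
an independent seed. Default 100 s per iterate puts the rate's standard
error near the 1% tolerance; the acceptance pipeline uses 50 s, which
doubles the variance but stays well inside the ±0.2 mV band that matters
for the calibrated thresholds (the local sensitivity is ≈ 14 Hz/mV).

## Synthetic fixtures: what a green test establishes

The generator module states a small world with known ground truth:

* `poisson_raster()` — independent homogeneous Poisson trains: the null
  for every coherence measure (uniform phases, CV 1).
* `locked_raster()` — a global clock at $f_{osc}$ with per-cycle
  participation probability $p$ and von Mises phase jitter $\kappa$. Von
  Mises jitter is a fixture choice (not a modelling claim) made because
  its resultant length $I_1(\kappa)/I_0(\kappa)$ gives closed-form MPC
  targets: measured against an unjittered reference train the expected MPC
  is exactly the resultant, and between two independently jittered trains
  its square (the phase read off within the reference ISI is, to first
  order in the jitter, the *difference* of the two jitters). With $p<1$
  the single-cell ISI histogram is multipeaked at multiples of the cycle
  with a decaying envelope — the signature of sparse participation in a
  fast rhythm.
* `sinusoid_trace()` — sinusoid plus white noise for the fit machinery.

These fixtures emulate the statistical structure the measures assume —
they do not emulate conductance dynamics, delays, or rate–synchrony
feedback. A green measure test therefore validates the *measurement code*,
not the simulator; the simulator is validated separately against its own
oracles (noiseless fixed points, uncoupled-network equivalence with
isolated neurons, eigenvalue cross-checks) and against the reference
statistics in the acceptance suite.

## Numerical and design choices

* **Delays** rounded to the nearest step; self-connections excluded (a
  zero-distance delay is ill-defined and a cell inhibiting itself within
  the rhythm adds nothing to the questions addressed).
* **Simulated durations.** The source does not state total per-condition
  durations; acceptance-scale network runs use 2 s discard + 3 s measured
  (≈300 oscillation cycles, ≈150 fit windows), which makes the scaled-down
  stochastic targets reproducible to a few percent. Isolated-neuron runs
  use 50 s (≈4000 spikes; rate SE ≈ 1.5%).
* **Window boundary convention.** Trace samples are taken at the end of
  each bin; window-local time starts at the window's first sample. All
  variables share the convention, so phase *differences* are unaffected.
* **Global MPC.** Whether the global index averages distance classes or
  pairs is ambiguous in the source; the distance-class average is primary
  (it matches the equal-pair-count construction) and the pair-weighted
  value is attached as an attribute.
* **Degenerate inputs** — empty conditioning sets, too-few spikes,
  unreachable calibration targets, non-finite state — raise errors rather
  than returning silent values.

## Known limitations

* Only homogeneous all-to-all networks on the torus: no sparse or
  heterogeneous connectivity, gap junctions, or excitatory populations.
* The background is spatially independent by construction; spatially
  correlated drive is out of scope.
* The window-rejection rule is an automated surrogate for a partly visual
  procedure; its rejection fraction is logged so it can be audited.
* Full-length parameter sweeps (coupling × $k$ grids, shunting sweeps) are
  supported through the config pipeline but are hours of compute; the test
  suite covers single-point spot checks only.
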