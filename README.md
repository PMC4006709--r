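# ingnet

Simulation and analysis of high-frequency oscillations in inhibitory
interneuron networks, for computational neuroscientists studying
interneuron network gamma (ING) and the role of intrinsic subthreshold
resonance in collective rhythmogenesis.

## What it does

`ingnet` simulates all-to-all networks of N inhibitory neurons on a 2-D
torus, coupled by delayed conductance-based synapses and driven by private
rectified Ornstein–Uhlenbeck background conductances. Two neuron models are
provided, differing in one property only:

- **IF** (integrate-and-fire): passive subthreshold dynamics,
  `C v' = -g v + I_syn + I_bg`;
- **GIF** (generalized integrate-and-fire): adds a restorative recovery
  variable, `C v' = -g v - g1 w + I_syn + I_bg`, `tau1 w' = v - w`, giving
  damped subthreshold oscillations at ~32 Hz for the canonical parameters.

In the fluctuation-driven regime both networks develop a ~103 Hz collective
rhythm while single cells fire irregularly at ~23–27 Hz (one spike per ~4
cycles); the GIF network synchronizes about twice as strongly because
post-inhibitory rebound from its recovery variable depolarizes all cells
coherently at the end of each inhibitory volley.

The measurement suite implements: single-cell rate and ISI CV; the Mean
Phase Coherence (complex resultant of spike phases within another neuron's
inter-spike intervals, averaged over equal-distance pairs on the torus);
population-rate power spectra with Gaussian-fit peak frequency; windowed
(20 ms) sinusoidal fits of mean-field traces with automated window
rejection; phase leads of synaptic and intrinsic currents relative to the
voltage oscillation; circular–linear correlation (Zar convention);
phase-conditioned kernel densities and bivariate deviation-from-independence
fields; and firing-rate threshold calibration ("r-matched" models).

## Worked example

```r
library(ingnet)

# closed-form linear analysis of the canonical GIF
linearize(gif_neuron())
#> <linear analysis>  v_rest=0 mV  tau_eff=10 ms  f_eff=31.83 Hz
#>   eigenvalues (1/ms): -0.1+0.2i -0.1-0.2i

# canonical GIF network: 2 s discard + 3 s measured, 20x20 torus
sim <- simulate_network(gif_neuron(), background_params(),
                        network_config(seed = 11))
ms <- network_measures(sim)
str(ms[c("rate_mean", "isi_cv_mean", "f_net_hz", "r_mpc_global")])
#> $ rate_mean   : num 27.5
#> $ isi_cv_mean : num 0.819
#> $ f_net_hz    : num 104
#> $ r_mpc_global: num 0.0262
```

Single cells fire at ~27 Hz with near-Poisson irregularity while the
population rate oscillates at ~103.6 Hz; the global Mean Phase Coherence
(~0.026) is about twice that of the equivalent IF network (~0.012),
quantifying the synchronization advantage conferred by subthreshold
resonance. The phase machinery on the same run:

```r
pa <- analyze_phases(simulate_network(if_neuron(), background_params(),
                                      network_config(seed = 11)))
pa$rejection_fraction      # 0.073 (windows dropped by the RMSE/omega rule)
pa$mean_dphi_syn           # 1.02 rad: synaptic current lags the voltage peak
subset(pa$correlations, variable == "dphi_syn_vs_Av")
#>         variable     r        p   n
#>   dphi_syn_vs_Av 0.454 5.96e-07 139
```

The circular–linear correlation says the synaptic-current phase advances in
windows of stronger oscillation (larger voltage-fit amplitude `A_v`).

A command-line interface wraps the same operations
(`inst/cli/ingnet linear-analysis --model gif`, `... reproduce --preset
table2 --out dir`); see `?ing_cli`.

## Layout

- `R/`, `src/engine.cpp` — API and the compiled network integrator
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/ingnet-methods.Rmd` — models, measures, numerical choices
- `scripts/acceptance.R` — the acceptance report generator
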