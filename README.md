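# striatnet

Simulation and single-unit inference for the striatal medium-spiny-neuron
(MSN) network.

MSNs — over 90% of striatal neurons — inhibit one another through sparse
GABAergic collaterals and, in vivo, fire in slow coherent bursts that are
degraded in Huntington's-disease (HD) model mice. `striatnet` implements
the full computational loop for studying that system from single-unit
spike trains alone:

* **Network simulator.** Deterministic conductance-based networks of
  single-compartment MSNs (leak + inward-rectifier K⁺ + exponential spike
  initiation + a slow regenerative gate; rest at −90 mV, rheobase
  conductance 0.0438, seconds-long latency near threshold, up/down-state
  geometry). Cells are wired randomly (connection probability 0.2; 2500
  cells at reference scale, in-degree ≈ 500 ± 20) and driven by two
  parameters: feedforward excitation `g_E` (per-cell conductances
  `U[0.04381, 0.04381 + 0.002 g_E]`, cation reversal 0 mV) and recurrent
  inhibition `g_I` (per-edge conductances `U[0.001 g_I, 0.001 g_I + 0.001]`,
  chloride reversal −80 mV, presynaptic gating
  `ds/dt = 2 H(V_pre)(1 − s) − B s`, `B ~ U[0.08, 0.09]`).
* **Fifteen-feature ISI battery.** Per 200-s spike-train segment: serial
  autocorrelations ρ(1), ρ(2); mean ISI, CV, rescaled skew, rate; four
  local-CV quintiles; ML gamma (closed form), lognormal and
  inverse-Gaussian parameters. Plus censorship-corrected cumulative ISI
  distributions `Q(n)` (weights `T/(T − I)`), Kolmogorov–Smirnov distances
  to four fitted families, and Morlet-wavelet spike-count power spectra.
* **KL estimator.** Recovers `(g_E, g_I)` for any dataset by comparing
  median-split joint feature distributions (random subsets of 7 of the 15
  features, 2⁷ bins, medians always from the data side) against a library
  of simulations:
  `K = Σ P_D ln(P_D/(P_M + 1e−7))`, soft-minimum grid weights
  `α ∝ K^−3`, and 30 subsets combined by inverse-error weights into
  `gE*, gI*` with weighted standard errors. Validated end to end by
  half-split recovery on a simulated grid, including the
  errors-in-both-coordinates regression of `gE*` on `gI*`.
* **Population diagnostics and surrogates.** Rate-correlation eigenvalue
  entropy, K-means raster ordering, active-cell accounting,
  balance-rescaled rates `r·g_I/g_E`; Markov-modulated-Poisson surrogate
  sessions with bursty (wild-type-like) and near-Poisson (HD-like)
  presets; 200-s segmentation, the overlapping `10·T_R/200` sampling
  convention, and age-interval dataset construction.

## Worked example

```r
library(striatnet)

# network wiring at full scale
net <- build_network(network_config(n_cells = 2500, p_connect = 0.2,
                                    g_E = 50, g_I = 33, seed = 1))
deg <- in_degrees(net)
cat(sprintf("in-degree mean %.1f, SD %.1f\n", mean(deg), sd(deg)))
#> in-degree mean 499.6, SD 20.3

# single-synapse IPSP at the wild-type-like inhibition level
p <- ipsp_probe(33)
cat(sprintf("IPSP: %.2f mV amplitude, %.1f ms half-decay, %.0f uV.s area\n",
            p$amplitude, p$half_decay, p$area))
#> IPSP: 1.82 mV amplitude, 19.9 ms half-decay, 71 uV.s area

# bursty surrogate session -> 15-feature battery
session <- mmpp_preset("wt", n_cells = 20, duration = 1800, seed = 8)
segs <- filter_segments(split_session(session, "nonoverlapping"),
                        mode = "experimental")$kept
feats <- feature_table(segs)
cat(sprintf("%d usable 200-s segments\n", nrow(feats)))
#> 180 usable 200-s segments
round(colMeans(feats[, c("cv", "rho1", "lcv5", "sigma_ln")]), 2)
#>       cv     rho1     lcv5 sigma_ln
#>     1.74     0.24     0.24     1.73
```

The segments are burstier than Poisson (CV 1.74), with positive serial ISI
correlation (ρ(1) = 0.24) and an excess of large local-CV values — the
wild-type-like phenotype. Fitting such a dataset against a simulated
library is `run_sweep()` (grid → features) followed by `run_fit()`
(filters → features → KL estimate with accounting), and the estimator's
own validation is `recovery_experiment()` on `library_split_halves()` of a
simulated grid.

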