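---
title: "Methods: simulating and fitting the striatal MSN network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and fitting the striatal MSN network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Medium spiny neurons (MSNs) make up over 90% of the striatum and inhibit
each other through sparse GABAergic collaterals. In vivo they fire in
irregular, coherent bursts even though isolated MSNs are not intrinsic
bursters, and this burst structure is degraded in Huntington's-disease (HD)
model mice. `striatnet` implements a complete computational loop for asking
what changes in the underlying circuit could produce such changes in
single-unit spiking:

1. a deterministic simulator of recurrent inhibitory MSN networks with two
   free parameters - net feedforward excitation `g_E` and recurrent
   collateral inhibition `g_I`;
2. a battery of fifteen inter-spike-interval (ISI) statistics ("features")
   computed per 200-s spike-train segment;
3. an estimator that recovers `(g_E, g_I)` for any spike-train dataset by
   Kullback-Leibler (KL) matching of median-split joint feature
   distributions against a library of simulations;
4. population diagnostics (rate-correlation eigenvalue entropy, K-means
   raster ordering) and surrogate-data generators so the whole pipeline is
   testable without any recordings.

## The network model

Each of `n_cells` (2500 by convention) cells receives a constant excitatory
conductance drawn once per simulation,
`G_ex ~ U[0.04381, 0.04381 + 0.002 g_E]` (reversal 0 mV), and inhibitory
input through directed random collaterals (each ordered pair connected with
probability 0.2, so in-degrees are binomial with mean about 500 and SD
about 20 at full size). Each synapse has maximal conductance
`G_syn ~ U[0.001 g_I, 0.001 g_I + 0.001]` (chloride reversal -80 mV) gated
by a presynaptic variable `ds/dt = 2 H(V_pre)(1 - s) - B s` with
`B ~ U[0.08, 0.09]` per presynaptic cell; `H` is 1 during the presynaptic
spike overshoot (membrane above 0 mV) and 0 otherwise. Simulations are
fully deterministic given the seed: all variability is generated by the
recurrent dynamics. One seed per `g_I` level is shared across `g_E` levels,
so simulations at one inhibition level differ only in the excitation
scaling.

### The reference cell model

The single-compartment MSN membrane (see `msn_cell_model()`) works in
per-capacitance units and combines

* a weak linear leak toward the -90 mV leak reversal,
* a Boltzmann-gated inward-rectifier (Kir-like) potassium conductance that
  dominates below about -70 mV and makes the hyperpolarized *down* state
  strongly stable,
* an exponential spike-initiation current (knee at -45 mV, sharpness 3 mV),
* and a slow gate `u` (relaxation 500 ms) with regenerative voltage
  coupling (`b_u < 0`), the counterpart of the slowly inactivating
  potassium currents that give MSNs their seconds-long latency to first
  spike.

The steady-state current-voltage curve has two barriers: the Kir hump near
-72 mV separating the down state from a *depolarized subthreshold "up"
state* near -50 mV, and a second, higher barrier near the spike knee whose
height defines the rheobase. The calibrated defaults place the rheobase
excitatory conductance at 0.0438, so the base of the `G_ex` draw sits
exactly at firing threshold and every simulated cell is driven above it.
The up/down geometry reproduces the defining MSN properties: rest at
-90 mV, a ~40 mV step to the up state, first-spike latencies of seconds
just above rheobase, tonic (never intrinsically bursting) firing that
reaches ~40-75 Hz at the strongest drives explored, and - the quantitative
anchor used for acceptance - an IPSP of 1.8 mV amplitude and 20 ms
half-decay (area ~70 microvolt-seconds, within the 30-100 physiological
band) in a just-subthreshold cell at `g_I = 33`:

```{r}
library(striatnet)
ipsp_probe(33)[c("amplitude", "half_decay", "area")]
rheobase_conductance()
```

The membrane is integrated with fixed-step RK4 (default `dt` 0.05 ms;
sweeps and tests use 0.1 ms, validated by the convergence tests), the
gating by its exact per-step exponential solution, and spikes are
stereotyped: upward crossing of 0 mV, a 0.3 ms overshoot plateau at
+30 mV during which `H = 1` (the above-zero portion of an action
potential), reset to -55 mV inside the up-state basin, and a 2 ms total
lockout. The spike-initiation current is capped at 500 mV/ms so the
upstroke resolves over a few steps at any step size. The per-cell total
inhibitory conductance is re-aggregated every `syn_every` membrane steps
(1 by default, 5 in sweeps; the synaptic time constant is ~12 ms, so
0.5 ms aggregation is far inside the resolved regime).

Because the reference-scale network (2500 cells, in-degree 500, 200 s) costs
hours of CPU, scaled configurations are first-class: `syn_scale`
multiplies every synaptic conductance and defaults to
`(2500 x 0.2)/(n_cells x p_connect)` so that the expected total recurrent
conductance per cell matches the full-size reference. Scaled networks have
proportionally larger input shot noise, which smooths the
frozen-regime/active-regime transition; the test suite therefore checks
orderings and transition signatures rather than absolute values.

### What the model does and does not reproduce

At the reference in-degree the simulator reproduces, as `g_I` grows at
fixed `g_E`: monotonically decreasing population rates with approximately
constant balance-rescaled rate `r g_I / g_E`; a frozen regime at low `g_I`
(regular winners, ML lognormal shape below 1) giving way to an active
fluctuating regime (shape above 1, interspike irregularity above Poisson);
an interior minimum of the active-cell count near the transition; ISI CVs
in the 1.0-1.5 range with positive serial correlations in the active
regime; and higher CV and rate at the wild-type-like setting
`(g_E = 50, g_I = 33)` than at the HD-like setting `(g_E = 40, g_I = 41)`.
Mean rates at the best-fit settings are of order 2-5 Hz in scaled runs
(the full-size reference values are about 7 Hz and 3 Hz).

Three quantitative features of the full-size model are *not* reproduced by
this transcription and are left as documented limitations rather than
tuned around: the ISI CV grows monotonically with `g_I` over the standard
grid instead of peaking near the transition at ~1.7; the explained-
variance entropy of the rate-correlation spectrum does not show a clear
interior minimum; and the gamma family is the best-fitting ISI
distribution at every grid point - the gamma-vs-lognormal margin narrows
toward low `g_I`, but a lognormal-best regime (the wild-type half of the
lognormal-to-gamma flip) never appears. The coherent low-dimensional
assembly fluctuations that produce these effects in the full-size model
with its detailed cell dynamics are weaker here, and scaled-down networks
replace them with cell-autonomous switching driven by synaptic shot
noise. The acceptance tests that encode these three properties are
expected to fail and are kept failing deliberately; every other property
above is asserted green.

## The fifteen-feature battery

For every segment with at least 11 spikes (at least 10 ISIs), in canonical
order: the first two serial ISI autocorrelations `rho(1), rho(2)`; mean
ISI; ISI CV; rescaled skew `S/CV`; firing rate (count over window); four
of the five local-CV quintiles (`LCV(3)` is excluded from the battery, as
in the reference analysis); the closed-form ML gamma parameters (log scale
and shape); the exact ML lognormal parameters; and the exact ML
inverse-Gaussian shape. Implementation choices where the source formulas
are ambiguous:

* `rho(n)` subtracts the squared mean (`mu^2`), the dimensionally
  consistent reading, confirmed by the alternating-sequence limit of -1.
* LCV bins are the half-open partition `[j/5, (j+1)/5)` with the last bin
  closed, so the five quintiles always sum to exactly 1; a local CV of
  exactly 0.5 falls in the third bin.
* The gamma-shape closed form carries its square root,
  `(3 - z + sqrt((3-z)^2 + 24 z))/(12 z)` with `z = ln(mean) - mean(ln)`.
* Degenerate inputs (constant ISIs) flag the segment rather than emitting
  infinities.

The censorship-corrected cumulative ISI distribution reweights every
observed interval by `T/(T - I)` - the inverse probability that an
interval of that length fits in the finite window - before forming the
survival function `Q(n)` on a lattice of width 0.01 s (display) or 1e-4 s
(fits). Kolmogorov-Smirnov distances to the fitted exponential, gamma,
lognormal and inverse-Gaussian families are `max_n |1 - D(n) - Q(n)|`
evaluated from `n = 1` to the last bin with `Q > 1e-8`; because `Q` is
piecewise constant and `D` monotone, only bins where `Q` changes need
evaluating. Spike-count power spectra use complex Morlet wavelets on the
ladder `2^(k/8)/64` Hz (capped at the 125 Hz Nyquist of the 4 ms count
series), temporal SD `6/(2 pi f)`, support truncated at three SDs and
edges discarded, normalized by the mean rate so Poisson trains are flat at
1.

## The KL estimator

Model estimation never compares feature values directly; it compares
*joint occupancy patterns*. Given an experimental dataset the per-feature
medians are computed once; every observation (data or model) is then
reduced to the binary pattern of "above/below the data's median" over a
random subset of 7 of the 15 features, giving 128-bin joint distributions.
The distance of model `M` from data `D` is
`K = sum P_D ln(P_D / (P_M + 1e-7))`, and a soft minimum over the
simulation grid, `alpha_m = K_m^-3 / sum K^-3` (K clipped below at 1e-6),
yields a weighted parameter estimate and weighted standard error per
subset. Thirty independent subsets are combined with inverse-error weights
`phi_R` into the final `(gE*, gI*)` and errors; one weight set per subset
serves both parameters. Estimates are always inside the grid's convex hull
- which also produces the known edge biases: truth at the grid maximum is
pulled down, truth at the minimum pulled up.

The estimator is validated end to end by the half-split recovery
experiment (`recovery_experiment()`): every grid simulation is cut into
two non-overlapping halves, first halves play the data, second halves the
library, and the recovered parameters are compared with the truth; the
per-`g_E` regression of `gE*` on `gI*` (with errors in both coordinates)
checks that the two estimates are not confounded.

Age-trend analyses use the same errors-in-both-coordinates straight-line
fit: an effective-variance chi-square,
`sum (y - a - b x)^2 / (sy^2 + b^2 sx^2)`, iterated to convergence, with
the slope standard error from the converged weighted-least-squares
curvature and a two-tailed t-test on `slope/SE` with `n - 2` degrees of
freedom. With vanishing x-errors this reduces exactly to weighted ordinary
least squares, and its p-values are uniform under the null (both are
tested).

## Surrogate data

Because the recordings behind the reference analysis are archival and not
deposited, the package generates its own "experimental-style" data on two
routes, clearly separated:

* **Model surrogates** - network simulations themselves (the only route
  used for estimator validation, as in the half-split recovery).
* **MMPP surrogates** - two-state Markov-modulated Poisson trains for fast
  tests of the feature/fitting stack. The wild-type preset (5 Hz bursts of
  mean 2 s over a 0.4 Hz background with 10 s mean gaps) yields CVs around
  1.7 with positive serial ISI correlation; the disease-like preset
  (2 Hz bursts, 0.7 Hz background, 4 s gaps) yields CVs near 1.1;
  sessions default to the 1200/1800/3600-s durations of the standard
  cohorts. MMPP results exercise the pipeline but are never presented as
  model validation.

Dataset construction mirrors the reference conventions: sessions are cut
into non-overlapping 200-s segments for description (segments with fewer
than 11 spikes dropped; whole cells with session rate above 10 Hz or ISI
skew above 60 dropped in experimental mode), or into `10 T_R / 200`
randomly placed, potentially overlapping segments for fitting; age-interval
datasets with fewer than 10 non-overlapping (100 overlapping) segments are
flagged excluded.

## Problem sizes used in the tests

The packaged tests and the acceptance script run everything at sizes a
laptop handles in minutes, chosen once: wiring statistics at the full
2500 cells; the IPSP and rheobase probes on 1-2 cells; regime-structure
sweeps and the wild-type/HD screen on 500-cell networks (in-degree 100,
`syn_scale` 5) simulated for 40-50 s at `dt` 0.1 ms; the recovery
experiment on a reduced 3 x 5 grid of such simulations split into 20-s
halves. The methods themselves are size-agnostic; `run_config()` defaults
to the full-size grid.

## Known limitations

* The cited biophysical MSN model is specified in this package by its
  validated anchors, not by transcribing channel equations; the reference
  membrane is a deliberately compact dynamical equivalent (leak + Kir +
  exponential spike initiation + one slow regenerative gate).
* The coherent critical-regime phenomena (CV peak near the transition,
  entropy minimum, low-dimensional assemblies) are under-expressed, as
  described above.
* No D1/D2 cell-type distinction, no spatial structure, no synaptic
  plasticity, no time-varying cortical drive - all outside the model's
  scope by design.
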