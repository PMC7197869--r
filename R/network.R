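#' Reference MSN cell model
#'
#' Parameters of the single-compartment medium-spiny-neuron model used by the
#' network simulator, in per-capacitance units (conductances in 1/ms,
#' voltages in mV). The membrane combines a weak linear leak toward the leak
#' reversal `v_r = -90` mV, a Boltzmann-gated inward-rectifier (Kir-like)
#' potassium conductance that dominates below its half-deactivation voltage
#' and makes the hyperpolarized "down" state strongly stable, an exponential
#' spike-initiation current with threshold knee `v_t` and sharpness
#' `delta_t`, and a slow gate `u`:
#' \deqn{\dot V = -k (V - v_r) - g_{kir}\, m(V)(V - v_r) - u +
#'   g_{sp} \Delta_T e^{(V - v_t)/\Delta_T} - I_{syn} - I_{ex},}
#' \deqn{\dot u = a_u (b_u (V - v_r) - u), \qquad
#'   m(V) = 1/(1 + e^{(V - v_{kir})/k_{kir}}).}
#' With `b_u < 0` the slow gate is regenerative: sustained depolarization
#' slowly recruits inward current, the counterpart of the slowly
#' inactivating potassium currents that give striatal projection neurons
#' their seconds-long latency to first spike and up-state persistence.
#' Spikes are stereotyped: on an upward crossing of 0 mV the membrane is
#' held at `v_peak` for `t_spike` ms (during which the presynaptic gating
#' Heaviside is 1), then reset to `v_reset` with `u <- u + d_u` and clamped
#' for the remainder of a `t_lockout` ms lockout.
#'
#' The defaults are calibrated once against the package's striatal MSN
#' anchors: resting potential at the -90 mV leak reversal; rheobase
#' excitatory conductance 0.0438 (the Kir hump is the threshold barrier);
#' first-spike latency of seconds just above rheobase; tonic (never
#' intrinsically bursting) firing up to ~75 Hz at the strongest feedforward
#' drives explored; and an IPSP of about 1.8 mV amplitude, 20 ms
#' half-decay in a just-subthreshold cell at inhibition level 33 (see
#' [ipsp_probe()]).
#'
#' Alternative cell models can be supplied anywhere a `cell` argument is
#' accepted, as a list with the same fields.
#'
#' @param k Linear leak conductance.
#' @param v_r Resting (leak and potassium reversal) potential, mV.
#' @param v_t Spike-initiation threshold knee, mV.
#' @param a_u Slow-gate relaxation rate, 1/ms.
#' @param b_u Slow-gate voltage coupling; negative values are regenerative.
#' @param d_u Spike-triggered slow-gate increment.
#' @param v_peak Overshoot plateau potential, mV.
#' @param v_reset Post-spike reset potential, mV.
#' @param t_spike Overshoot duration, ms.
#' @param t_lockout Total refractory lockout from spike onset, ms.
#' @param g_kir Inward-rectifier maximal conductance.
#' @param v_kir Inward-rectifier half-deactivation voltage, mV.
#' @param k_kir Inward-rectifier slope factor, mV.
#' @param g_sp Spike-initiation current strength.
#' @param delta_t Spike-initiation sharpness, mV.
#' @return Named list of cell-model parameters (class `msn_cell_model`).
#' @export
msn_cell_model <- function(k = 0.10, v_r = -90, v_t = -45,
                           a_u = 0.002, b_u = -0.0497, d_u = 0.2,
                           v_peak = 30, v_reset = -55,
                           t_spike = 0.3, t_lockout = 2,
                           g_kir = 0.1383, v_kir = -70, k_kir = 6,
                           g_sp = 0.15, delta_t = 3) {
  structure(list(k = k, v_r = v_r, v_t = v_t, a_u = a_u, b_u = b_u,
                 d_u = d_u, v_peak = v_peak, v_reset = v_reset,
                 t_spike = t_spike, t_lockout = t_lockout,
                 g_kir = g_kir, v_kir = v_kir, k_kir = k_kir,
                 g_sp = g_sp, delta_t = delta_t),
            class = "msn_cell_model")
}

#' Network simulation configuration
#'
#' @param n_cells Number of cells (default 2500).
#' @param p_connect Connection probability for each ordered cell pair
#'   (default 0.2); in-degrees are binomial(`n_cells - 1`, `p_connect`).
#' @param g_E Feedforward excitation level (dimensionless; per-cell
#'   excitatory conductances are drawn uniformly from
#'   `[0.04381, 0.04381 + 0.002 g_E]`).
#' @param g_I Recurrent inhibition level (dimensionless; per-edge synaptic
#'   conductances are drawn uniformly from `[0.001 g_I, 0.001 g_I + 0.001]`).
#' @param duration Simulated (recorded) time, seconds.
#' @param dt Integration step, ms.
#' @param seed Integer seed for all structural and conductance draws.
#' @param transient Initial simulated time discarded before recording,
#'   seconds.
#' @param syn_every Membrane steps between re-aggregations of the per-cell
#'   total inhibitory conductance (1 = every step).
#' @param syn_scale Multiplier applied to every synaptic conductance. Scaled
#'   networks with fewer cells use `(2500 * 0.2) / (n_cells * p_connect)` so
#'   the expected total recurrent conductance per cell matches the
#'   2500-cell reference and the frozen-to-active transition stays at a
#'   comparable `g_I`.
#' @param cell Cell-model parameter list (see [msn_cell_model()]).
#' @return A `network_config` list.
#' @export
network_config <- function(n_cells = 2500, p_connect = 0.2,
                           g_E = 50, g_I = 33,
                           duration = 200, dt = 0.05, seed = 1,
                           transient = 2, syn_every = 1, syn_scale = 1,
                           cell = msn_cell_model()) {
  if (n_cells < 2) stop("invalid config: n_cells must be at least 2")
  if (p_connect <= 0 || p_connect >= 1)
    stop("invalid config: p_connect must be in (0, 1)")
  if (g_E < 0 || g_I < 0) stop("invalid config: g_E and g_I must be >= 0")
  if (duration <= 0 || dt <= 0) stop("invalid config: duration and dt must be > 0")
  structure(list(n_cells = as.integer(n_cells), p_connect = p_connect,
                 g_E = g_E, g_I = g_I, duration = duration, dt = dt,
                 seed = as.integer(seed), transient = transient,
                 syn_every = as.integer(syn_every), syn_scale = syn_scale,
                 cell = cell),
            class = "network_config")
}

# reversal potentials and gating opening rate (fixed model constants)
V_CL <- -80      # chloride reversal, mV
V_CAT <- 0       # cation reversal, mV
A_GATE <- 2      # gating opening rate during the presynaptic overshoot, 1/ms
GEX_BASE <- 0.04381  # base (threshold) excitatory conductance

#' Build a random network realization
#'
#' Draws the directed adjacency (every ordered pair `i != j` is an edge
#' independently with probability `p_connect`), per-edge maximal synaptic
#' conductances `G_syn ~ U[0.001 g_I, 0.001 g_I + 0.001]`, per-presynaptic
#' gating decay rates `B ~ U[0.08, 0.09]`, and the per-cell uniform variates
#' behind the excitatory conductances
#' `G_ex = 0.04381 + 0.002 g_E U`. The uniform variates are stored so that
#' simulations at the same `g_I` (same seed) but different `g_E` share every
#' draw except the excitation scaling.
#'
#' @param config A [network_config()].
#' @return A `network_realization`: CSR adjacency (`pre_ptr`, `targets`),
#'   per-edge `g_syn`, per-cell `b_decay`, `u_ex`, `g_ex`, and the seed.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  n <- config$n_cells
  set.seed(config$seed)
  tgt <- vector("list", n)
  for (j in seq_len(n)) {
    hit <- which(stats::runif(n) < config$p_connect)
    tgt[[j]] <- hit[hit != j]
  }
  deg <- lengths(tgt)
  pre_ptr <- c(0L, cumsum(deg))
  targets <- unlist(tgt, use.names = FALSE) - 1L   # 0-based for the integrator
  if (is.null(targets)) targets <- integer(0)
  g_syn <- 0.001 * config$g_I + 0.001 * stats::runif(length(targets))
  b_decay <- 0.08 + 0.01 * stats::runif(n)
  u_ex <- stats::runif(n)
  structure(list(pre_ptr = pre_ptr, targets = targets, g_syn = g_syn,
                 b_decay = b_decay, u_ex = u_ex,
                 g_ex = GEX_BASE + 0.002 * config$g_E * u_ex,
                 seed = config$seed, n_cells = n),
            class = "network_realization")
}

#' In-degree distribution of a realization
#' @param realization A `network_realization`.
#' @return Integer vector of in-degrees (incoming edges per cell).
#' @export
in_degrees <- function(realization) {
  tabulate(realization$targets + 1L, nbins = realization$n_cells)
}

#' One step of the synaptic gating variable
#'
#' Advances `ds/dt = a H (1 - s) - B s` by its exact solution over a step of
#' length `dt`, with the Heaviside `H` frozen at 1 when the presynaptic
#' membrane is above 0 mV (spike overshoot) and 0 otherwise. With `H = 1`
#' held, `s` relaxes toward the fixed point `a / (a + B)`.
#'
#' @param s Gating value in `[0, 1]`.
#' @param v_pre Presynaptic membrane potential, mV.
#' @param b Decay rate, 1/ms.
#' @param dt Step, ms.
#' @param a Opening rate (default 2 /ms).
#' @return Updated gating value, guaranteed in `[0, 1]`.
#' @export
gating_step <- function(s, v_pre, b, dt, a = A_GATE) {
  if (s < 0 || s > 1) stop("gating value must be in [0, 1]")
  if (v_pre > 0) {
    sinf <- a / (a + b)
    sinf + (s - sinf) * exp(-(a + b) * dt)
  } else {
    s * exp(-b * dt)
  }
}

#' Inhibitory synaptic current
#'
#' `G_syn * s * (V_post - V_Cl)` with the chloride reversal at -80 mV; the
#' current is subtracted from the membrane derivative, so it hyperpolarizes
#' any cell above -80 mV.
#'
#' @param v_post Postsynaptic potential, mV.
#' @param s Gating value.
#' @param g_syn Maximal synaptic conductance.
#' @return Current in model (per-capacitance) units.
#' @export
inhibitory_current <- function(v_post, s, g_syn) g_syn * s * (v_post - V_CL)

#' Feedforward excitatory current
#'
#' `G_ex * (V_post - V_cat)` with the cation reversal at 0 mV; subtracted
#' from the membrane derivative, so it depolarizes any cell below 0 mV.
#' `G_ex` is constant for the duration of a simulation.
#'
#' @param v_post Postsynaptic potential, mV.
#' @param g_ex Excitatory conductance.
#' @return Current in model units.
#' @export
excitatory_current <- function(v_post, g_ex) g_ex * (v_post - V_CAT)

#' Simulate a network realization
#'
#' Integrates every cell's membrane and adaptation dynamics together with
#' the synaptic gating of all presynaptic cells, under constant feedforward
#' excitation. All cells start from the isolated resting state (`v_r`, zero
#' adaptation, closed synapses) and the first `transient` seconds are
#' discarded. The run is fully deterministic given the realization and `dt`.
#'
#' @param realization A [build_network()] result.
#' @param config The matching [network_config()]. Its `g_E` may differ from
#'   the one the realization was built with: the stored uniform variates are
#'   rescaled, so runs at one `g_I` share all draws across `g_E` levels.
#' @param record_cells Optional integer vector of cell indices (1-based)
#'   whose membrane potential is recorded.
#' @param record_stride Steps between voltage samples.
#' @return A `simulation_result`: `spike_times` (per-cell lists of spike
#'   times in seconds within `[0, duration]`), optionally `v` and `v_dt`
#'   (ms), plus the config.
#' @export
simulate_network <- function(realization, config,
                             record_cells = integer(0), record_stride = 20L) {
  stopifnot(inherits(realization, "network_realization"),
            inherits(config, "network_config"))
  g_ex <- GEX_BASE + 0.002 * config$g_E * realization$u_ex
  res <- simulate_network_cpp(
    n = realization$n_cells,
    pre_ptr = realization$pre_ptr,
    targets = realization$targets,
    w_edge = realization$g_syn * config$syn_scale,
    B = realization$b_decay,
    gex = g_ex,
    cell = unclass(config$cell),
    duration_ms = config$duration * 1000,
    dt = config$dt,
    syn_every = config$syn_every,
    transient_ms = config$transient * 1000,
    v_cl = V_CL, v_cat = V_CAT, a_gate = A_GATE,
    record_cells = as.integer(record_cells) - 1L,
    record_stride = as.integer(record_stride))
  structure(list(spike_times = res$spike_times,
                 v = res$v, v_dt = res$v_dt,
                 config = config, seed = realization$seed),
            class = "simulation_result")
}

#' Simulate one isolated cell
#'
#' Single cell with no synaptic input, driven by a constant excitatory
#' conductance. Used by the rheobase search and cell-model validation.
#'
#' @param g_ex Excitatory conductance.
#' @param duration Seconds.
#' @param dt Step, ms.
#' @param cell Cell model.
#' @param record Logical; record the membrane trace.
#' @return List with `spike_times` (seconds) and optionally `v`, `v_dt`.
#' @export
simulate_single_cell <- function(g_ex, duration = 10, dt = 0.05,
                                 cell = msn_cell_model(), record = FALSE) {
  res <- simulate_network_cpp(
    n = 1L, pre_ptr = c(0L, 0L), targets = integer(0),
    w_edge = numeric(0), B = 0.085, gex = g_ex, cell = unclass(cell),
    duration_ms = duration * 1000, dt = dt, syn_every = 1000L,
    transient_ms = 0, v_cl = V_CL, v_cat = V_CAT, a_gate = A_GATE,
    record_cells = if (record) 0L else integer(0), record_stride = 4L)
  list(spike_times = res$spike_times[[1]], v = res$v, v_dt = res$v_dt)
}

#' Steady-state rheobase of the cell model
#'
#' The excitatory conductance at which the quiescent fixed point of the
#' steady-state current balance disappears: the largest value of
#' (restoring current)/(-V) over the subthreshold voltage range, with the
#' slow gate at its steady state. Agrees with the dynamical bisection
#' [rheobase_conductance()] when the slow gate is slaved adiabatically.
#'
#' @param cell Cell model.
#' @return Threshold conductance.
#' @export
rheobase_analytic <- function(cell = msn_cell_model()) {
  v <- seq(cell$v_r + 1e-3, -1, by = 0.01)
  kir <- cell$g_kir / (1 + exp((v - cell$v_kir) / cell$k_kir)) * (v - cell$v_r)
  spk <- cell$g_sp * cell$delta_t * exp(pmin((v - cell$v_t) / cell$delta_t, 40))
  restoring <- cell$k * (v - cell$v_r) + kir + cell$b_u * (v - cell$v_r) - spk
  max(restoring / (-v))
}

#' Firing-threshold (rheobase) excitatory conductance
#'
#' Bisects the constant excitatory conductance of an isolated cell for the
#' smallest value producing sustained spiking. Near threshold the model's
#' saddle-node bifurcation gives arbitrarily long first-spike latencies, so
#' the probe window must be generous.
#'
#' @param cell Cell model.
#' @param dt Step, ms.
#' @param tol Bisection tolerance on the conductance (default 1e-5).
#' @param window Probe duration per bisection step, seconds.
#' @return The threshold conductance.
#' @export
rheobase_conductance <- function(cell = msn_cell_model(), dt = 0.05,
                                 tol = 1e-5, window = 12) {
  lo <- 0.02; hi <- 0.09
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    n_sp <- length(simulate_single_cell(mid, duration = window, dt = dt,
                                        cell = cell)$spike_times)
    if (n_sp >= 2L) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Two-cell IPSP probe
#'
#' Measures the inhibitory postsynaptic potential produced through one
#' synapse at inhibition level `g_I`. The presynaptic cell is driven just
#' above rheobase, so its Type-I firing is slow and its spikes (and hence
#' the IPSPs) are isolated. The postsynaptic cell is held just below firing
#' threshold by its constant excitatory conductance: it settles into the
#' model's depolarized subthreshold "up" state near -50 mV, the
#' high-resistance operating point at which striatal IPSPs are
#' physiologically characterized. The synaptic conductance is the mean of
#' the `g_I`-level draw interval, `0.001 g_I + 0.0005`, with gating decay at
#' the mid-range `B = 0.085`.
#'
#' @param g_I Inhibition level (>= 0).
#' @param post_frac Postsynaptic drive as a fraction of rheobase (just
#'   below 1).
#' @param pre_excess Presynaptic drive in excess of rheobase.
#' @param cell Cell model.
#' @param dt Step, ms.
#' @return List with `amplitude` (mV), `half_decay` (ms), `area`
#'   (microvolt-seconds), the postsynaptic trace (`v`, sampled at `v_dt`
#'   ms), and the presynaptic spike times (ms).
#' @export
ipsp_probe <- function(g_I, post_frac = 0.97, pre_excess = 1.5e-3,
                       cell = msn_cell_model(), dt = 0.05) {
  if (g_I < 0) stop("g_I must be >= 0")
  rheo <- rheobase_analytic(cell)
  g_syn <- if (g_I > 0) 0.001 * g_I + 0.0005 else 0
  res <- simulate_network_cpp(
    n = 2L, pre_ptr = c(0L, 1L, 1L), targets = 1L,
    w_edge = g_syn, B = c(0.085, 0.085),
    gex = c(rheo + pre_excess, post_frac * rheo), cell = unclass(cell),
    duration_ms = 9000, dt = dt, syn_every = 1L, transient_ms = 0,
    v_cl = V_CL, v_cat = V_CAT, a_gate = A_GATE,
    record_cells = c(0L, 1L), record_stride = 1L)
  v_post <- res$v[, 2]
  if (any(v_post > 0)) stop("invalid probe: postsynaptic cell fired")
  pre_sp <- res$spike_times[[1]] * 1000          # ms
  if (g_I == 0) {
    return(list(amplitude = 0, half_decay = NA_real_, area = 0,
                v = v_post, v_dt = res$v_dt, pre_spikes = pre_sp))
  }
  if (length(pre_sp) < 2L) stop("invalid probe: presynaptic cell too slow")
  # last presynaptic spike after the up-state settling transient with a
  # quiet window long enough for the IPSP to complete
  ok <- which(diff(c(pre_sp, 9000)) > 350 & pre_sp > 4000 & pre_sp < 8500)
  if (!length(ok)) stop("invalid probe: no isolated IPSP window")
  t0 <- pre_sp[max(ok)]
  idx <- function(t_ms) pmax(1L, pmin(length(v_post),
                                      round(t_ms / res$v_dt) + 1L))
  base <- mean(v_post[idx(t0 - 20):idx(t0 - 1)])
  win <- idx(t0):idx(t0 + 349)
  vmin_i <- win[which.min(v_post[win])]
  amplitude <- base - v_post[vmin_i]
  after <- vmin_i:idx(t0 + 349)
  rec <- after[v_post[after] >= v_post[vmin_i] + amplitude / 2]
  half_decay <- if (length(rec)) (rec[1] - vmin_i) * res$v_dt else NA_real_
  area <- sum(pmax(base - v_post[win], 0)) * res$v_dt  # mV ms = microvolt s
  list(amplitude = amplitude, half_decay = half_decay, area = area,
       v = v_post, v_dt = res$v_dt, pre_spikes = pre_sp, t_probe = t0)
}
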