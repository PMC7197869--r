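# Network construction, synaptic primitives, and simulator contracts.

test_that("network wiring matches binomial in-degree moments", {
  cfg <- network_config(n_cells = 2500, p_connect = 0.2, g_E = 50, g_I = 33,
                        seed = 7)
  net <- build_network(cfg)
  deg <- in_degrees(net)
  # binomial(2499, 0.2): mean 499.8, sd 19.996; sampling error ~ sd/sqrt(n)
  expect_equal(mean(deg), 2499 * 0.2, tolerance = 3 * 20 / sqrt(2500) / 499.8)
  expect_equal(sd(deg), sqrt(2499 * 0.2 * 0.8), tolerance = 0.05)
  # no self-edges: a presynaptic cell never targets itself
  pre <- rep(seq_len(2500), diff(net$pre_ptr))
  expect_true(all(pre != net$targets + 1L))
  # conductance draw intervals
  expect_true(all(net$g_syn >= 0.033 & net$g_syn <= 0.034))
  expect_true(all(net$b_decay >= 0.08 & net$b_decay <= 0.09))
  expect_true(all(net$g_ex >= 0.04381 & net$g_ex <= 0.04381 + 0.002 * 50))
  # reproducible from seed
  net2 <- build_network(cfg)
  expect_identical(net$targets, net2$targets)
  expect_identical(net$g_syn, net2$g_syn)
  expect_error(network_config(n_cells = 1), "invalid")
})

test_that("realizations at one g_I share all draws except excitation scale", {
  cfg1 <- network_config(n_cells = 100, g_E = 25, g_I = 33, seed = 3)
  cfg2 <- network_config(n_cells = 100, g_E = 90, g_I = 33, seed = 3)
  n1 <- build_network(cfg1); n2 <- build_network(cfg2)
  expect_identical(n1$targets, n2$targets)
  expect_identical(n1$g_syn, n2$g_syn)
  expect_identical(n1$u_ex, n2$u_ex)
  expect_false(identical(n1$g_ex, n2$g_ex))
  expect_equal(n2$g_ex - 0.04381, (n1$g_ex - 0.04381) * 90 / 25)
})

test_that("gating step obeys its closed forms and bounds", {
  # pure decay: s(t) = s0 exp(-B t)
  s <- 0.7
  for (i in 1:100) s <- gating_step(s, v_pre = -60, b = 0.085, dt = 1)
  expect_equal(s, 0.7 * exp(-0.085 * 100))
  # held-open fixed point a / (a + B) = 2 / 2.085
  s <- 0
  for (i in 1:200) s <- gating_step(s, v_pre = 30, b = 0.085, dt = 1)
  expect_equal(s, 2 / 2.085, tolerance = 1e-8)
  # absorbing at zero without input, and bounded in [0, 1]
  expect_equal(gating_step(0, -60, 0.085, 1), 0)
  expect_lte(gating_step(1, 30, 0.08, 10), 1)
  expect_error(gating_step(1.2, 0, 0.085, 1), "\\[0, 1\\]")
})

test_that("synaptic currents follow their reversal potentials", {
  # inhibitory: zero at the chloride reversal, zero when closed,
  # hand value at G = 0.034, s = 0.5, V = -50
  expect_equal(inhibitory_current(-80, 0.5, 0.034), 0)
  expect_equal(inhibitory_current(-50, 0, 0.034), 0)
  expect_equal(inhibitory_current(-50, 0.5, 0.034), 0.034 * 0.5 * 30)
  # sign: positive (hyperpolarizing, since it is subtracted) above -80
  expect_gt(inhibitory_current(-60, 0.5, 0.034), 0)
  # excitatory: zero at the cation reversal, linear below
  expect_equal(excitatory_current(0, 0.05), 0)
  expect_equal(excitatory_current(-80, 0), 0)
  expect_equal(excitatory_current(-80, 0.05), -4)
})

test_that("isolated cells are quiescent below threshold, tonic above", {
  cell <- msn_cell_model()
  rheo <- rheobase_analytic(cell)
  expect_equal(length(simulate_single_cell(rheo * 0.98, 10,
                                           cell = cell)$spike_times), 0)
  sp <- simulate_single_cell(rheo * 1.5, 10, cell = cell)$spike_times
  expect_gt(length(sp), 50)
  # tonic: ISI CV essentially zero after onset
  isis <- diff(sp[-(1:3)])
  expect_lt(sd(isis) / mean(isis), 0.02)
  # resting potential at the leak reversal
  v <- simulate_single_cell(0, 2, cell = cell, record = TRUE)$v
  expect_equal(tail(v[, 1], 1), cell$v_r, tolerance = 0.5)
})

test_that("rheobase bisection agrees with the steady-state value and dt", {
  cell <- msn_cell_model()
  rb <- rheobase_conductance(cell, dt = 0.05, tol = 1e-5, window = 20)
  expect_equal(rb, 0.0438, tolerance = 5e-3)
  expect_equal(rb, rheobase_analytic(cell), tolerance = 5e-3)
  rb2 <- rheobase_conductance(cell, dt = 0.025, tol = 1e-5, window = 20)
  expect_lt(abs(rb - rb2), 2e-4)     # stable under halved step
})

test_that("long first-spike latency appears near rheobase", {
  cell <- msn_cell_model()
  rheo <- rheobase_analytic(cell)
  lat_near <- simulate_single_cell(rheo + 2e-4, 12, cell = cell)$spike_times[1]
  lat_far <- simulate_single_cell(rheo * 2, 12, cell = cell)$spike_times[1]
  expect_gt(lat_near, 0.5)
  expect_lt(lat_far, 0.2)
  expect_gt(lat_near / lat_far, 10)
})

test_that("network simulation is deterministic and respects time bounds", {
  cfg <- network_config(n_cells = 60, p_connect = 0.2, g_E = 50, g_I = 21,
                        duration = 6, dt = 0.1, seed = 11, syn_every = 5,
                        syn_scale = 5, transient = 1)
  net <- build_network(cfg)
  r1 <- simulate_network(net, cfg)
  r2 <- simulate_network(net, cfg)
  expect_identical(r1$spike_times, r2$spike_times)
  all_sp <- unlist(r1$spike_times)
  expect_true(all(all_sp >= 0 & all_sp <= cfg$duration))
  # per-cell spike times strictly increasing
  for (st in r1$spike_times)
    if (length(st) > 1) expect_true(all(diff(st) > 0))
  # p = 0 edge case approximated by no edges: uncoupled supra-threshold
  # cells fire periodically (CV ~ 0)
  net0 <- net; net0$pre_ptr <- rep(0L, 61); net0$targets <- integer(0)
  net0$g_syn <- numeric(0)
  r0 <- simulate_network(net0, cfg)
  cvs <- vapply(r0$spike_times[lengths(r0$spike_times) >= 12],
                function(st) { i <- diff(st[-(1:2)]); sd(i) / mean(i) }, 0)
  expect_lt(max(cvs), 0.05)
})

test_that("IPSP probe reproduces the physiological anchors", {
  p0 <- ipsp_probe(0)
  expect_equal(p0$amplitude, 0)
  p <- ipsp_probe(33)
  expect_equal(p$amplitude, 1.8, tolerance = 0.02)
  expect_equal(p$half_decay, 20, tolerance = 0.05)
  # area within the physiological band quoted for near-threshold cells
  expect_gt(p$area, 30); expect_lt(p$area, 100)
  # amplitude grows with inhibition level
  amps <- vapply(c(5, 21, 41, 65), function(g) ipsp_probe(g)$amplitude, 0)
  expect_true(all(diff(amps) > 0))
  expect_gt(amps[1], 0)
})

test_that("halving the integration step barely changes network statistics", {
  stats_at <- function(dt, syn_every) {
    cfg <- network_config(n_cells = 250, p_connect = 0.2, g_E = 50, g_I = 33,
                          duration = 20, dt = dt, seed = 77,
                          syn_every = syn_every, syn_scale = 10,
                          transient = 2)
    res <- simulate_network(build_network(cfg), cfg)
    ns <- lengths(res$spike_times)
    cvs <- vapply(res$spike_times[ns >= 11],
                  function(st) { i <- diff(st); sd(i) / mean(i) }, 0)
    c(rate = mean(ns) / 20, cv = mean(cvs))
  }
  a <- stats_at(0.1, 5L)
  b <- stats_at(0.05, 10L)   # same 0.5 ms aggregation interval
  expect_lt(abs(a["rate"] - b["rate"]) / a["rate"], 0.02)
  expect_lt(abs(a["cv"] - b["cv"]) / a["cv"], 0.05)
})
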