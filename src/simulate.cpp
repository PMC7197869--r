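#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Network integrator.
//
// Cell dynamics (per-capacitance units, mV and ms): a single-compartment MSN
// membrane with linear leak, Boltzmann-gated inward-rectifier potassium
// conductance, exponential spike-initiation current and a slow gate u:
//   dV/dt = -k (V - v_r) - g_kir m(V) (V - v_r) - u
//           + g_sp dT exp((V - v_t)/dT)
//           - W (V - V_Cl) - G_ex (V - V_cat)
//   du/dt = a_u (b_u (V - v_r) - u),   m(V) = 1/(1 + exp((V - v_kir)/k_kir))
// On an upward crossing of 0 mV a spike is recorded and the membrane is held
// at v_peak for t_spike ms (the overshoot window during which the presynaptic
// gating Heaviside is 1), then reset to v_reset with u += d_u and clamped for
// the remainder of a t_lockout ms refractory period.
//
// Synaptic gating per presynaptic cell: ds/dt = a_g H(V)(1 - s) - B s,
// advanced by its exact exponential solution over each step (H frozen within
// a step). The per-cell total inhibitory conductance W_i = sum_j G_ij s_j is
// re-aggregated every syn_every membrane steps.

struct CellParams {
  double k, v_r, v_t, a_u, b_u, d_u, v_peak, v_reset, t_spike, t_lockout;
  double g_kir, v_kir, k_kir; // inward-rectifier: conductance, half-activation, slope
  double g_sp, delta_t;       // exponential spike-initiation strength and sharpness
};

// Membrane current balance (per unit capacitance):
//   leak -k (V - v_r); inward rectifier, a Boltzmann-gated K conductance that
//   deactivates with depolarization; exponential spike-initiation current;
//   slow gate u; recurrent and feedforward synaptic conductances.
static inline double dv_dt(const CellParams& p, double V, double u, double W,
                           double gex, double v_cl, double v_cat) {
  double kir = p.g_kir > 0.0
    ? p.g_kir / (1.0 + std::exp((V - p.v_kir) / p.k_kir)) * (V - p.v_r)
    : 0.0;
  // spike-initiation current capped at 500 mV/ms so the upstroke resolves
  // over a few steps at any dt and RK4 stages stay finite
  double x = (V - p.v_t) / p.delta_t;
  double spike = p.g_sp * p.delta_t * std::exp(x);
  if (spike > 500.0) spike = 500.0;
  return -p.k * (V - p.v_r) - kir - u + spike
    - W * (V - v_cl) - gex * (V - v_cat);
}

// [[Rcpp::export]]
List simulate_network_cpp(int n,
                          IntegerVector pre_ptr,    // length n+1, 0-based CSR
                          IntegerVector targets,    // 0-based postsynaptic ids
                          NumericVector w_edge,     // G_syn per edge
                          NumericVector B,          // gating decay per pre cell
                          NumericVector gex,        // per-cell G_ex
                          List cell,                // cell-model parameters
                          double duration_ms,
                          double dt,
                          int syn_every,
                          double transient_ms,
                          double v_cl, double v_cat, double a_gate,
                          IntegerVector record_cells, // 0-based, may be empty
                          int record_stride,
                          Nullable<List> cell_first = R_NilValue,
                          int n_first = 0) {
  CellParams p;
  p.k = cell["k"]; p.v_r = cell["v_r"]; p.v_t = cell["v_t"];
  p.a_u = cell["a_u"]; p.b_u = cell["b_u"]; p.d_u = cell["d_u"];
  p.v_peak = cell["v_peak"]; p.v_reset = cell["v_reset"];
  p.t_spike = cell["t_spike"]; p.t_lockout = cell["t_lockout"];
  p.g_kir = cell["g_kir"]; p.v_kir = cell["v_kir"]; p.k_kir = cell["k_kir"];
  p.g_sp = cell["g_sp"]; p.delta_t = cell["delta_t"];
  // optional distinct parameter set for the first n_first cells (used by the
  // IPSP probe to slow the presynaptic driver without touching the synapse
  // or the postsynaptic cell)
  CellParams pf = p;
  if (cell_first.isNotNull()) {
    List cf(cell_first);
    pf.k = cf["k"]; pf.v_r = cf["v_r"]; pf.v_t = cf["v_t"];
    pf.a_u = cf["a_u"]; pf.b_u = cf["b_u"]; pf.d_u = cf["d_u"];
    pf.v_peak = cf["v_peak"]; pf.v_reset = cf["v_reset"];
    pf.t_spike = cf["t_spike"]; pf.t_lockout = cf["t_lockout"];
    pf.g_kir = cf["g_kir"]; pf.v_kir = cf["v_kir"]; pf.k_kir = cf["k_kir"];
    pf.g_sp = cf["g_sp"]; pf.delta_t = cf["delta_t"];
  }

  std::vector<double> V(n, p.v_r), u(n, 0.0), s(n, 0.0), W(n, 0.0);
  std::vector<int> mode(n, 0);          // 0 normal, 1 overshoot, 2 refractory
  std::vector<double> t_mode(n, 0.0);
  std::vector<double> dec(n), dec_on(n), sinf(n);
  for (int j = 0; j < n; ++j) {
    dec[j] = std::exp(-B[j] * dt);
    dec_on[j] = std::exp(-(a_gate + B[j]) * dt);
    sinf[j] = a_gate / (a_gate + B[j]);
  }

  long total_steps = (long) std::llround((transient_ms + duration_ms) / dt);
  std::vector<int> sp_cell;
  std::vector<double> sp_time;

  int nrec = record_cells.size();
  long nrec_t = nrec > 0 ? total_steps / record_stride + 1 : 0;
  NumericMatrix vtrace(nrec > 0 ? nrec_t : 0, nrec);
  NumericMatrix utrace(nrec > 0 ? nrec_t : 0, nrec);
  long rec_row = 0;

  for (long step = 0; step < total_steps; ++step) {
    double t = step * dt;
    if (step % syn_every == 0) {
      std::fill(W.begin(), W.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        double sj = s[j];
        if (sj > 1e-12) {
          for (int e = pre_ptr[j]; e < pre_ptr[j + 1]; ++e)
            W[targets[e]] += w_edge[e] * sj;
        }
      }
    }
    if (nrec > 0 && step % record_stride == 0) {
      for (int r = 0; r < nrec; ++r) {
        vtrace(rec_row, r) = V[record_cells[r]];
        utrace(rec_row, r) = u[record_cells[r]];
      }
      ++rec_row;
    }
    for (int i = 0; i < n; ++i) {
      const CellParams& q = (i < n_first) ? pf : p;
      // gating follows the membrane state at the start of the step
      if (mode[i] == 1) s[i] = sinf[i] + (s[i] - sinf[i]) * dec_on[i];
      else             s[i] *= dec[i];

      if (mode[i] == 0) {
        double v0 = V[i], u0 = u[i], Wi = W[i], g = gex[i];
        double k1v = dv_dt(q, v0, u0, Wi, g, v_cl, v_cat);
        double k1u = q.a_u * (q.b_u * (v0 - q.v_r) - u0);
        double k2v = dv_dt(q, v0 + 0.5 * dt * k1v, u0 + 0.5 * dt * k1u, Wi, g, v_cl, v_cat);
        double k2u = q.a_u * (q.b_u * (v0 + 0.5 * dt * k1v - q.v_r) - (u0 + 0.5 * dt * k1u));
        double k3v = dv_dt(q, v0 + 0.5 * dt * k2v, u0 + 0.5 * dt * k2u, Wi, g, v_cl, v_cat);
        double k3u = q.a_u * (q.b_u * (v0 + 0.5 * dt * k2v - q.v_r) - (u0 + 0.5 * dt * k2u));
        double k4v = dv_dt(q, v0 + dt * k3v, u0 + dt * k3u, Wi, g, v_cl, v_cat);
        double k4u = q.a_u * (q.b_u * (v0 + dt * k3v - q.v_r) - (u0 + dt * k3u));
        double v1 = v0 + dt / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
        double u1 = u0 + dt / 6.0 * (k1u + 2 * k2u + 2 * k3u + k4u);
        if (!(v0 < 0.0 && v1 >= 0.0) &&
            (!std::isfinite(v1) || std::fabs(v1) > 200.0))
          stop("integration failure: |V| > 200 mV at cell %d, t = %.3f ms", i + 1, t);
        if (v0 < 0.0 && v1 >= 0.0) {
          double tsp = t + dt;
          if (tsp >= transient_ms && tsp - transient_ms <= duration_ms) {
            sp_cell.push_back(i);
            sp_time.push_back(std::min(tsp - transient_ms, duration_ms));
          }
          mode[i] = 1; t_mode[i] = q.t_spike; V[i] = q.v_peak; u[i] = u1;
        } else {
          V[i] = v1; u[i] = u1;
        }
      } else {
        // clamped: u relaxes toward b_u (V - v_r) with V held
        double vh = (mode[i] == 1) ? q.v_peak : q.v_reset;
        double uinf = q.b_u * (vh - q.v_r);
        u[i] = uinf + (u[i] - uinf) * std::exp(-q.a_u * dt);
        t_mode[i] -= dt;
        if (t_mode[i] <= 1e-9) {
          if (mode[i] == 1) {
            V[i] = q.v_reset; u[i] += q.d_u;
            mode[i] = 2; t_mode[i] = q.t_lockout - q.t_spike;
            if (t_mode[i] <= 0) mode[i] = 0;
          } else {
            mode[i] = 0;
          }
        }
      }
    }
  }

  // assemble per-cell spike-time lists (seconds past the transient)
  std::vector<int> counts(n, 0);
  for (size_t q = 0; q < sp_cell.size(); ++q) counts[sp_cell[q]]++;
  List spikes(n);
  std::vector<std::vector<double> > per(n);
  for (int i = 0; i < n; ++i) per[i].reserve(counts[i]);
  for (size_t q = 0; q < sp_cell.size(); ++q)
    per[sp_cell[q]].push_back(sp_time[q] / 1000.0);
  for (int i = 0; i < n; ++i) spikes[i] = NumericVector(per[i].begin(), per[i].end());

  List out = List::create(_["spike_times"] = spikes);
  if (nrec > 0) {
    out["v"] = vtrace(Range(0, rec_row - 1), Range(0, nrec - 1));
    out["u"] = utrace(Range(0, rec_row - 1), Range(0, nrec - 1));
    out["v_dt"] = dt * record_stride;
  }
  return out;
}
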