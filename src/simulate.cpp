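// Fixed-step current-clamp integrator for few-compartment conductance-based
// neuron models. Gates use exponential-Euler updates from tabulated
// steady-state/time-constant curves; the voltage update is implicit
// (backward Euler) over the coupled compartments, so the discrete charge
// balance C dV/dt = -(I_ion + I_axial) + I_inj holds exactly at every step.
//
// Units: mV, ms, cm^2, uF/cm^2, mS/cm^2, uS (axial), uM (calcium).
// Conductance g[mS] * V[mV] = I[uA]; recorded per-channel currents are nA.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double V_TAB_LO = -150.0;
const double V_TAB_HI = 100.0;
const double V_TAB_STEP = 0.05;
const int V_TAB_N = static_cast<int>((V_TAB_HI - V_TAB_LO) / V_TAB_STEP) + 1;

struct Gate {
  int role;       // 0 = voltage activation, 1 = voltage inactivation, 2 = calcium activation
  int exponent;
  double v_half, slope;
  double tau_base, tau_amp, tau_v_half, tau_sigma;
  double ca_half, hill;
  // tables over voltage (built at session construction, dt baked in)
  std::vector<double> xinf_tab;   // unused for calcium gates
  std::vector<double> efact_tab;  // 1 - exp(-dt / tau(V))
};

struct Placement {
  int comp;        // compartment index
  int param;       // index into the per-placement density vector
  double erev;
  bool feeds_ca;
  std::vector<Gate> gates;
};

struct Session {
  int ncomp;
  std::vector<double> area, cm_total;   // cm^2, uF (area * specific capacitance)
  std::vector<int> parent;              // -1 for soma/root
  std::vector<double> g_axial;          // uS to parent -> stored as mS
  std::vector<double> ca_influx;        // uM per (nA * ms)
  std::vector<double> ca_tau, ca_rest;  // ms, uM
  std::vector<double> ca_decay;         // exp(-dt/tau), precomputed
  std::vector<Placement> placements;
  double dt, tau_min;
};

inline double boltz(double v, double vh, double slope) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / slope));
}

inline double bell_tau(const Gate& g, double v, double tau_min) {
  double z = (v - g.tau_v_half) / g.tau_sigma;
  double tau = g.tau_base + g.tau_amp * std::exp(-0.5 * z * z);
  return tau > tau_min ? tau : tau_min;
}

inline double ipow(double x, int n) {
  double r = 1.0;
  while (n > 0) {
    if (n & 1) r *= x;
    x *= x;
    n >>= 1;
  }
  return r;
}

void build_gate_tables(Gate& g, double dt, double tau_min) {
  g.efact_tab.resize(V_TAB_N);
  if (g.role != 2) g.xinf_tab.resize(V_TAB_N);
  for (int i = 0; i < V_TAB_N; ++i) {
    double v = V_TAB_LO + i * V_TAB_STEP;
    double tau = bell_tau(g, v, tau_min);
    g.efact_tab[i] = 1.0 - std::exp(-dt / tau);
    if (g.role != 2) g.xinf_tab[i] = boltz(v, g.v_half, g.slope);
  }
}

inline void tab_index(double v, int& i0, double& w) {
  double p = (v - V_TAB_LO) / V_TAB_STEP;
  if (p <= 0.0) { i0 = 0; w = 0.0; return; }
  if (p >= V_TAB_N - 1) { i0 = V_TAB_N - 2; w = 1.0; return; }
  i0 = static_cast<int>(p);
  w = p - i0;
}

inline double hill_inf(const Gate& g, double ca) {
  if (ca <= 0.0) return 0.0;
  double num = std::pow(ca, g.hill);
  double den = num + std::pow(g.ca_half, g.hill);
  return den > 0.0 ? num / den : 0.0;
}

struct State {
  std::vector<double> v, ca;
  std::vector<double> gate_x;  // flattened gate states, placement-major
};

struct Workspace {
  std::vector<double> g_pl;
  Workspace(std::size_t npl) : g_pl(npl) {}
};

void init_state(const Session& s, State& st, double v0) {
  st.v.assign(s.ncomp, v0);
  st.ca = s.ca_rest;
  st.gate_x.clear();
  for (const auto& pl : s.placements) {
    for (const auto& g : pl.gates) {
      if (g.role == 2)
        st.gate_x.push_back(hill_inf(g, st.ca[pl.comp]));
      else
        st.gate_x.push_back(boltz(v0, g.v_half, g.slope));
    }
  }
}

// One integration step. inj_uA: injected current per compartment (uA).
// If rec_cur != nullptr, writes per-placement ionic currents (nA) at the new voltage.
void step(const Session& s, State& st, const std::vector<double>& dens,
          const std::vector<double>& inj_uA, double* rec_cur, long step_idx,
          Workspace& ws) {
  const int nc = s.ncomp;
  // accumulate per-compartment ionic conductance (mS) and g*E (uA) with updated gates
  double g_sum[4] = {0, 0, 0, 0}, ge_sum[4] = {0, 0, 0, 0};
  std::size_t gi = 0;
  const std::size_t npl = s.placements.size();
  std::vector<double>& g_pl = ws.g_pl;
  for (std::size_t k = 0; k < npl; ++k) {
    const Placement& pl = s.placements[k];
    double v = st.v[pl.comp];
    int i0; double w;
    tab_index(v, i0, w);
    double open = 1.0;
    for (const auto& gt : pl.gates) {
      double ef = gt.efact_tab[i0] * (1.0 - w) + gt.efact_tab[i0 + 1] * w;
      double xinf = (gt.role == 2)
        ? hill_inf(gt, st.ca[pl.comp])
        : gt.xinf_tab[i0] * (1.0 - w) + gt.xinf_tab[i0 + 1] * w;
      double x = st.gate_x[gi];
      x += (xinf - x) * ef;
      st.gate_x[gi] = x;
      open *= ipow(x, gt.exponent);
      ++gi;
    }
    double g = dens[pl.param] * s.area[pl.comp] * open;  // mS
    g_pl[k] = g;
    g_sum[pl.comp] += g;
    ge_sum[pl.comp] += g * pl.erev;
  }
  // implicit voltage solve: (C/dt + G_ion + G_ax) V_new - coupling = C/dt V_old + g*E + I_inj
  double A[4][4] = {{0}};
  double b[4];
  if (nc > 4) stop("at most 4 compartments supported");
  for (int i = 0; i < nc; ++i) {
    A[i][i] = s.cm_total[i] / s.dt + g_sum[i];
    b[i] = s.cm_total[i] / s.dt * st.v[i] + ge_sum[i] + inj_uA[i];
  }
  for (int i = 0; i < nc; ++i) {
    int p = s.parent[i];
    if (p < 0) continue;
    double ga = s.g_axial[i];  // mS
    A[i][i] += ga; A[p][p] += ga;
    A[i][p] -= ga; A[p][i] -= ga;
  }
  // Gaussian elimination with partial pivoting (n <= 4)
  int idx[4] = {0, 1, 2, 3};
  for (int c = 0; c < nc; ++c) {
    int piv = c;
    for (int r = c + 1; r < nc; ++r)
      if (std::fabs(A[idx[r]][c]) > std::fabs(A[idx[piv]][c])) piv = r;
    std::swap(idx[c], idx[piv]);
    double d = A[idx[c]][c];
    for (int r = c + 1; r < nc; ++r) {
      double f = A[idx[r]][c] / d;
      if (f == 0.0) continue;
      for (int cc = c; cc < nc; ++cc) A[idx[r]][cc] -= f * A[idx[c]][cc];
      b[idx[r]] -= f * b[idx[c]];
    }
  }
  double vnew[4];
  for (int c = nc - 1; c >= 0; --c) {
    double acc = b[idx[c]];
    for (int cc = c + 1; cc < nc; ++cc) acc -= A[idx[c]][cc] * vnew[cc];
    vnew[c] = acc / A[idx[c]][c];
  }
  for (int i = 0; i < nc; ++i) {
    if (!std::isfinite(vnew[i]))
      stop("solver blow-up: non-finite voltage at step %ld in compartment %d",
           step_idx, i + 1);
    st.v[i] = vnew[i];
  }
  // calcium update with per-placement currents at the new voltage
  double ca_in[4] = {0, 0, 0, 0};  // uM/ms
  for (std::size_t k = 0; k < npl; ++k) {
    const Placement& pl = s.placements[k];
    double i_uA = g_pl[k] * (st.v[pl.comp] - pl.erev);
    double i_nA = i_uA * 1e3;
    if (rec_cur) rec_cur[k] = i_nA;
    if (pl.feeds_ca) {
      double influx = -s.ca_influx[pl.comp] * i_nA;  // inward (negative) -> positive influx
      if (influx > 0.0) ca_in[pl.comp] += influx;
    }
  }
  for (int i = 0; i < nc; ++i) {
    double target = s.ca_rest[i] + ca_in[i] * s.ca_tau[i];
    double ca = target + (st.ca[i] - target) * s.ca_decay[i];
    st.ca[i] = ca > 0.0 ? ca : 0.0;
  }
}

Session* build_session_impl(List model, double dt, double tau_min) {
  Session* s = new Session();
  s->dt = dt;
  s->tau_min = tau_min;
  List comps = model["compartments"];
  NumericVector area = comps["area"], cm = comps["capacitance"];
  IntegerVector parent = comps["parent"];
  NumericVector gax = comps["g_axial"];
  s->ncomp = area.size();
  for (int i = 0; i < s->ncomp; ++i) {
    s->area.push_back(area[i]);
    s->cm_total.push_back(cm[i] * area[i]);
    s->parent.push_back(parent[i]);
    s->g_axial.push_back(gax[i] * 1e-3);  // uS -> mS
  }
  List ca = model["ca_pool"];
  NumericVector cin = ca["influx_factor"], ctau = ca["tau_removal"], crest = ca["ca_rest"];
  for (int i = 0; i < s->ncomp; ++i) {
    s->ca_influx.push_back(cin[i % cin.size()]);
    s->ca_tau.push_back(ctau[i % ctau.size()]);
    s->ca_rest.push_back(crest[i % crest.size()]);
    s->ca_decay.push_back(std::exp(-dt / s->ca_tau[i]));
  }
  List pls = model["placements"];
  for (int k = 0; k < pls.size(); ++k) {
    List pk = pls[k];
    Placement pl;
    pl.comp = as<int>(pk["comp"]);
    pl.param = as<int>(pk["param"]);
    pl.erev = as<double>(pk["erev"]);
    pl.feeds_ca = as<bool>(pk["feeds_ca"]);
    List gl = pk["gates"];
    for (int j = 0; j < gl.size(); ++j) {
      List gj = gl[j];
      Gate g;
      g.role = as<int>(gj["role"]);
      g.exponent = as<int>(gj["exponent"]);
      g.v_half = as<double>(gj["v_half"]);
      g.slope = as<double>(gj["slope"]);
      g.tau_base = as<double>(gj["tau_base"]);
      g.tau_amp = as<double>(gj["tau_amp"]);
      g.tau_v_half = as<double>(gj["tau_v_half"]);
      g.tau_sigma = as<double>(gj["tau_sigma"]);
      g.ca_half = as<double>(gj["ca_half"]);
      g.hill = as<double>(gj["hill"]);
      build_gate_tables(g, dt, tau_min);
      pl.gates.push_back(g);
    }
    s->placements.push_back(pl);
  }
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".cp_build_session")]]
SEXP cp_build_session(List model, double dt, double tau_min) {
  XPtr<Session> p(build_session_impl(model, dt, tau_min), true);
  return p;
}

// Simulate: settle for settle_ms without stimulus, then for each amplitude run
// pre/step/post from the settled state. Returns, per amplitude, Vm and Ca
// matrices (row per sample, column per compartment) and optionally per-placement
// currents (nA). Sample 0 is the settled initial state.
// [[Rcpp::export(name = ".cp_simulate")]]
List cp_simulate(SEXP session, NumericVector densities, NumericVector amps_pA,
                 double pre_ms, double step_ms, double post_ms,
                 double settle_ms, int inj_comp, bool record_currents,
                 bool record_full) {
  XPtr<Session> s(session);
  std::vector<double> dens(densities.begin(), densities.end());
  const int nc = s->ncomp;
  const double dt = s->dt;
  const std::size_t npl = s->placements.size();

  State st;
  init_state(*s, st, -80.0);
  Workspace ws(npl);
  std::vector<double> no_inj(nc, 0.0);
  long n_settle = static_cast<long>(std::floor(settle_ms / dt + 0.5));
  for (long i = 0; i < n_settle; ++i) step(*s, st, dens, no_inj, nullptr, i, ws);
  State settled = st;

  long n_pre = static_cast<long>(std::floor(pre_ms / dt + 0.5));
  long n_stim = static_cast<long>(std::floor(step_ms / dt + 0.5));
  long n_post = static_cast<long>(std::floor(post_ms / dt + 0.5));
  long n_tot = n_pre + n_stim + n_post;

  List out(amps_pA.size());
  for (int a = 0; a < amps_pA.size(); ++a) {
    st = settled;
    std::vector<double> inj(nc, 0.0);
    double amp_uA = amps_pA[a] * 1e-6;
    NumericMatrix vm(n_tot + 1, record_full ? nc : 1);
    NumericMatrix camat(record_full ? (n_tot + 1) : 0, record_full ? nc : 0);
    NumericMatrix cur(record_currents ? (n_tot + 1) : 0,
                      record_currents ? static_cast<int>(npl) : 0);
    std::vector<double> curbuf(npl, 0.0);
    // record initial (settled) state
    if (record_full) {
      for (int c = 0; c < nc; ++c) { vm(0, c) = st.v[c]; camat(0, c) = st.ca[c]; }
    } else {
      vm(0, 0) = st.v[0];
    }
    for (long i = 0; i < n_tot; ++i) {
      inj[inj_comp] = (i >= n_pre && i < n_pre + n_stim) ? amp_uA : 0.0;
      step(*s, st, dens, inj, record_currents ? curbuf.data() : nullptr, i + 1, ws);
      if (record_full) {
        for (int c = 0; c < nc; ++c) { vm(i + 1, c) = st.v[c]; camat(i + 1, c) = st.ca[c]; }
      } else {
        vm(i + 1, 0) = st.v[0];
      }
      if (record_currents)
        for (std::size_t k = 0; k < npl; ++k) cur(i + 1, k) = curbuf[k];
    }
    List tr = List::create(_["vm"] = vm,
                           _["ca"] = camat,
                           _["currents"] = cur,
                           _["onset_index"] = n_pre + 1,  // 1-based row of last pre sample
                           _["vrest"] = settled.v[0]);
    out[a] = tr;
  }
  return out;
}
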