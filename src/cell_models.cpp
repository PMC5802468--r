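// Conductance-based cell model right-hand sides.
//
// Two model families are implemented:
//   * "san"    -- single-compartment sinoatrial node pacemaker cell
//                 (mouse-type / rabbit-type differ only in parameter values)
//   * "neuron" -- reduced two-compartment layer-V pyramidal neuron
//
// The parameter layout is defined once here (X-macro lists) and exported to
// R via *_param_names(); model builders on the R side supply the values in
// this order.  All voltages in mV, time in ms, currents in nA, conductances
// in uS, capacitance in nF, concentrations in mM.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigm(double v, double vhalf, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
}

// ---------------------------------------------------------------------------
// SAN model
// ---------------------------------------------------------------------------

#define SAN_STATES(X)                                                   \
  X(V) X(dL12) X(fL12) X(dL13) X(fL13) X(dT) X(fT) X(pa) X(pi_) X(y)    \
  X(m) X(h) X(Cai) X(CaSR) X(w)

#define SAN_PARAMS(X)                                                   \
  X(Cm)                                                                 \
  X(gCaL12) X(vd12) X(kd12) X(taud12) X(vf12) X(kf12) X(tauf12)         \
  X(gCaL13) X(vd13) X(kd13) X(taud13) X(vf13) X(kf13) X(tauf13)         \
  X(KmfCa)                                                              \
  X(gCaT) X(vdT) X(kdT) X(taudT) X(vfT) X(kfT) X(taufT)                 \
  X(gKr) X(vpa) X(kpa) X(taupa) X(vpi) X(kpi) X(taupi)                  \
  X(gf) X(vy) X(ky) X(tauy) X(Ef)                                       \
  X(gNa) X(vm) X(km) X(taum) X(vh) X(kh) X(tauh)                        \
  X(gbNa) X(INaKmax)                                                    \
  X(kNCX) X(dNCX)                                                       \
  X(Prel) X(vrel) X(krel) X(Kw) X(tauw) X(kleak) X(KSRleak)                                \
  X(Pup) X(Kup)                                                         \
  X(alphaCa) X(betaCa) X(nuSR)                                          \
  X(ECa) X(EK) X(ENa)

enum SanState {
#define X(n) s_##n,
  SAN_STATES(X)
#undef X
  SAN_NSTATE
};

enum SanParam {
#define X(n) p_##n,
  SAN_PARAMS(X)
#undef X
  SAN_NPAR
};

struct SanCurrents {
  double ICaL12, ICaL13, ICaT, IKr, If, INa, INaK, INCX, IbNa, Itot;
};

// Voltage-dependent time constants: fixed shapes scaled by the tau parameter
// (which is the variant-accessible multiplier, equal to 1 at control).
static inline double san_tau_pa(double V, double scale) {
  return scale * (40.0 + 300.0 / (1.0 + std::exp((V + 30.0) / 12.0)));
}
static inline double san_tau_y(double V, double scale, double vy) {
  // bell-shaped around the activation midpoint, floor 60 ms
  double z = (V - vy) / 30.0;
  return scale * (60.0 + 350.0 * std::exp(-z * z));
}
static inline double san_tau_h(double V, double scale) {
  double z = (V + 70.0) / 20.0;
  return scale * (1.0 + 24.0 * std::exp(-z * z));
}

// Evaluate gate targets (inf, tau) for the 11 gating states, ionic currents,
// and full derivative vector.  Any of the output pointers may be NULL.
static void san_eval(const double* y, const double* p, double stim,
                     double* inf, double* tau, double* dy, SanCurrents* out) {
  const double V = y[s_V];
  const double Cai = y[s_Cai], CaSR = y[s_CaSR];

  double gi[SAN_NSTATE], gt[SAN_NSTATE];
  gi[s_dL12] = sigm(V, p[p_vd12], p[p_kd12]);     gt[s_dL12] = p[p_taud12];
  gi[s_fL12] = sigm(V, p[p_vf12], -p[p_kf12]);    gt[s_fL12] = p[p_tauf12];
  gi[s_dL13] = sigm(V, p[p_vd13], p[p_kd13]);     gt[s_dL13] = p[p_taud13];
  gi[s_fL13] = sigm(V, p[p_vf13], -p[p_kf13]);    gt[s_fL13] = p[p_tauf13];
  gi[s_dT]   = sigm(V, p[p_vdT], p[p_kdT]);       gt[s_dT]   = p[p_taudT];
  gi[s_fT]   = sigm(V, p[p_vfT], -p[p_kfT]);      gt[s_fT]   = p[p_taufT];
  gi[s_pa]   = sigm(V, p[p_vpa], p[p_kpa]);       gt[s_pa]   = san_tau_pa(V, p[p_taupa]);
  gi[s_pi_]  = sigm(V, p[p_vpi], -p[p_kpi]);      gt[s_pi_]  = p[p_taupi];
  gi[s_y]    = sigm(V, p[p_vy], -p[p_ky]);        gt[s_y]    = san_tau_y(V, p[p_tauy], p[p_vy]);
  gi[s_m]    = sigm(V, p[p_vm], p[p_km]);         gt[s_m]    = p[p_taum];
  gi[s_h]    = sigm(V, p[p_vh], -p[p_kh]);        gt[s_h]    = san_tau_h(V, p[p_tauh]);
  // RyR inactivation gate: recovers at low Cai, inactivates when Cai is high
  double Kw4 = std::pow(p[p_Kw], 4.0), Cai4 = std::pow(Cai, 4.0);
  gi[s_w] = Kw4 / (Kw4 + Cai4);
  gt[s_w] = p[p_tauw];

  if (inf) for (int i = 1; i < SAN_NSTATE; ++i) { inf[i] = gi[i]; tau[i] = gt[i]; }

  const double fCa = p[p_KmfCa] / (p[p_KmfCa] + Cai);
  SanCurrents c;
  c.ICaL12 = p[p_gCaL12] * y[s_dL12] * y[s_fL12] * fCa * (V - p[p_ECa]);
  c.ICaL13 = p[p_gCaL13] * y[s_dL13] * y[s_fL13] * fCa * (V - p[p_ECa]);
  c.ICaT   = p[p_gCaT] * y[s_dT] * y[s_fT] * (V - p[p_ECa]);
  c.IKr    = p[p_gKr] * y[s_pa] * y[s_pi_] * (V - p[p_EK]);
  c.If     = p[p_gf] * y[s_y] * (V - p[p_Ef]);
  c.INa    = p[p_gNa] * y[s_m] * y[s_m] * y[s_m] * y[s_h] * (V - p[p_ENa]);
  c.INaK   = p[p_INaKmax] / (1.0 + std::exp(-(V + 60.0) / 40.0));
  // simplified Na/Ca exchange, fixed [Na]i = 8, [Na]o = 140, [Ca]o = 1.8 mM
  {
    const double xf = std::exp(0.01871 * V), xr = std::exp(-0.01871 * V);
    const double t1 = 922.0 * xf;             // Nai^3 * Cao
    const double t2 = 2.744e6 * Cai * xr;     // Nao^3 * Cai
    c.INCX = p[p_kNCX] * (t1 - t2) / (1.0 + p[p_dNCX] * (t1 + t2));
  }
  c.IbNa = p[p_gbNa] * (V - p[p_ENa]);
  c.Itot = c.ICaL12 + c.ICaL13 + c.ICaT + c.IKr + c.If + c.INa + c.INaK +
           c.INCX + c.IbNa;
  if (out) *out = c;

  if (dy) {
    dy[s_V] = (-c.Itot + stim) / p[p_Cm];
    for (int i = 1; i < SAN_NSTATE; ++i) dy[i] = (gi[i] - y[i]) / gt[i];
    // Ca fluxes (cytosolic mM/ms)
    // SR release is opened by depolarisation (slaved to the AP) and closed
    // by the Ca-dependent refractoriness gate w; no regenerative CICR
    const double relOpen = sigm(V, p[p_vrel], p[p_krel]) * y[s_w];
    const double jrel  = p[p_Prel] * relOpen * (CaSR - Cai);
    // load-dependent diastolic leak: an overflow valve opened by SR filling;
    // depends only on the slow SR variable, so it cannot self-ignite
    const double SR4 = std::pow(CaSR, 4.0);
    const double KS4 = std::pow(p[p_KSRleak], 4.0);
    const double jleak = p[p_kleak] * (CaSR - Cai) * SR4 / (SR4 + KS4);
    const double Ku2 = p[p_Kup] * p[p_Kup];
    const double Ca2 = Cai * Cai;
    const double jup = p[p_Pup] * Ca2 / (Ca2 + Ku2);
    const double jmem = -p[p_alphaCa] *
      (c.ICaL12 + c.ICaL13 + c.ICaT - 2.0 * c.INCX);
    dy[s_Cai]  = p[p_betaCa] * (jmem + jrel + jleak - jup);
    dy[s_CaSR] = p[p_nuSR] * (jup - jrel - jleak);
  }
}

// ---------------------------------------------------------------------------
// Reduced two-compartment neuron
// ---------------------------------------------------------------------------

#define NRN_STATES(X)                                                   \
  X(Vs) X(Vd) X(m) X(h) X(pp) X(n) X(u) X(z) X(c) X(hc) X(s) X(hs)      \
  X(q) X(Cai)

#define NRN_PARAMS(X)                                                   \
  X(Cs) X(Cd) X(gc)                                                     \
  X(gNaT) X(vm) X(km) X(taum) X(vh) X(kh) X(tauh)                       \
  X(gNaP) X(vp) X(kp) X(taup)                                           \
  X(gKdr) X(vn) X(kn) X(taun)                                           \
  X(gKM) X(vu) X(ku) X(tauu)                                            \
  X(gSK) X(KSK) X(tauz)                                                 \
  X(gCaHVA) X(vc) X(kc) X(tauc) X(vhc) X(khc) X(tauhc)                  \
  X(gCaLVA) X(vs) X(ks) X(taus) X(vhs) X(khs) X(tauhs)                  \
  X(gH) X(vq) X(kq) X(tauq) X(Eh) X(gHd)                                \
  X(gLs) X(gLd) X(EL)                                                   \
  X(alphaCa) X(Pup) X(Ca0)                                              \
  X(ECa) X(EK) X(ENa)

enum NrnState {
#define X(n) n_##n,
  NRN_STATES(X)
#undef X
  NRN_NSTATE
};

enum NrnParam {
#define X(n) q_##n,
  NRN_PARAMS(X)
#undef X
  NRN_NPAR
};

struct NrnCurrents {
  double INaT, INaP, IKdr, IKM, ISK, ICaHVA, ICaLVA, IHs, IHd, ILs, ILd, Iax;
};

static inline double nrn_tau_m(double V, double scale) {
  double z = (V + 38.0) / 25.0;
  return scale * (0.08 + 0.25 * std::exp(-z * z));
}
static inline double nrn_tau_h(double V, double scale) {
  double z = (V + 55.0) / 20.0;
  return scale * (0.5 + 7.0 * std::exp(-z * z));
}
static inline double nrn_tau_n(double V, double scale) {
  double z = (V + 20.0) / 30.0;
  return scale * (0.6 + 2.8 * std::exp(-z * z));
}

static void nrn_eval(const double* y, const double* p,
                     double stim_s, double stim_d,
                     double* inf, double* tau, double* dy, NrnCurrents* out) {
  const double Vs = y[n_Vs], Vd = y[n_Vd], Cai = y[n_Cai];

  double gi[NRN_NSTATE], gt[NRN_NSTATE];
  gi[n_m]  = sigm(Vs, p[q_vm], p[q_km]);    gt[n_m]  = nrn_tau_m(Vs, p[q_taum]);
  gi[n_h]  = sigm(Vs, p[q_vh], -p[q_kh]);   gt[n_h]  = nrn_tau_h(Vs, p[q_tauh]);
  gi[n_pp] = sigm(Vs, p[q_vp], p[q_kp]);    gt[n_pp] = p[q_taup];
  gi[n_n]  = sigm(Vs, p[q_vn], p[q_kn]);    gt[n_n]  = nrn_tau_n(Vs, p[q_taun]);
  gi[n_u]  = sigm(Vs, p[q_vu], p[q_ku]);    gt[n_u]  = p[q_tauu];
  {
    double c4 = std::pow(Cai, 4.0), k4 = std::pow(p[q_KSK], 4.0);
    gi[n_z] = c4 / (c4 + k4);               gt[n_z]  = p[q_tauz];
  }
  gi[n_c]  = sigm(Vs, p[q_vc], p[q_kc]);    gt[n_c]  = p[q_tauc];
  gi[n_hc] = sigm(Vs, p[q_vhc], -p[q_khc]); gt[n_hc] = p[q_tauhc];
  gi[n_s]  = sigm(Vs, p[q_vs], p[q_ks]);    gt[n_s]  = p[q_taus];
  gi[n_hs] = sigm(Vs, p[q_vhs], -p[q_khs]); gt[n_hs] = p[q_tauhs];
  // single HCN gate driven by somatic V; conductance split soma/dendrite
  // (compartments track closely in the subthreshold range)
  gi[n_q]  = sigm(Vs, p[q_vq], -p[q_kq]);   gt[n_q]  = p[q_tauq];

  if (inf) for (int i = 2; i < NRN_NSTATE; ++i) { inf[i] = gi[i]; tau[i] = gt[i]; }

  NrnCurrents c;
  c.INaT   = p[q_gNaT] * y[n_m] * y[n_m] * y[n_m] * y[n_h] * (Vs - p[q_ENa]);
  c.INaP   = p[q_gNaP] * y[n_pp] * (Vs - p[q_ENa]);
  c.IKdr   = p[q_gKdr] * y[n_n] * y[n_n] * (Vs - p[q_EK]);
  c.IKM    = p[q_gKM] * y[n_u] * (Vs - p[q_EK]);
  c.ISK    = p[q_gSK] * y[n_z] * (Vs - p[q_EK]);
  c.ICaHVA = p[q_gCaHVA] * y[n_c] * y[n_c] * y[n_hc] * (Vs - p[q_ECa]);
  c.ICaLVA = p[q_gCaLVA] * y[n_s] * y[n_s] * y[n_hs] * (Vs - p[q_ECa]);
  c.IHs    = p[q_gH] * y[n_q] * (Vs - p[q_Eh]);
  c.IHd    = p[q_gHd] * y[n_q] * (Vd - p[q_Eh]);
  c.ILs    = p[q_gLs] * (Vs - p[q_EL]);
  c.ILd    = p[q_gLd] * (Vd - p[q_EL]);
  c.Iax    = p[q_gc] * (Vs - Vd);
  if (out) *out = c;

  if (dy) {
    dy[n_Vs] = (-(c.INaT + c.INaP + c.IKdr + c.IKM + c.ISK + c.ICaHVA +
                  c.ICaLVA + c.IHs + c.ILs) - c.Iax + stim_s) / p[q_Cs];
    dy[n_Vd] = (-(c.IHd + c.ILd) + c.Iax + stim_d) / p[q_Cd];
    for (int i = 2; i < NRN_NSTATE; ++i) dy[i] = (gi[i] - y[i]) / gt[i];
    dy[n_Cai] = -p[q_alphaCa] * (c.ICaHVA + c.ICaLVA) -
                p[q_Pup] * (Cai - p[q_Ca0]);
  }
}

// ---------------------------------------------------------------------------
// Name exports (keep R-side layouts in sync with the enums above)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector san_state_names_cpp() {
  CharacterVector out;
#define X(n) out.push_back(#n);
  SAN_STATES(X)
#undef X
  return out;
}

// [[Rcpp::export]]
CharacterVector san_param_names_cpp() {
  CharacterVector out;
#define X(n) out.push_back(#n);
  SAN_PARAMS(X)
#undef X
  return out;
}

// [[Rcpp::export]]
CharacterVector neuron_state_names_cpp() {
  CharacterVector out;
#define X(n) out.push_back(#n);
  NRN_STATES(X)
#undef X
  return out;
}

// [[Rcpp::export]]
CharacterVector neuron_param_names_cpp() {
  CharacterVector out;
#define X(n) out.push_back(#n);
  NRN_PARAMS(X)
#undef X
  return out;
}

// ---------------------------------------------------------------------------
// ODE right-hand sides (called from the R integration wrapper)
// ---------------------------------------------------------------------------

// family: 1 = san, 2 = neuron; stim: nA per compartment
// [[Rcpp::export]]
NumericVector cell_rhs_cpp(int family, double t, NumericVector y,
                           NumericVector p, NumericVector stim) {
  if (family == 1) {
    if (y.size() != SAN_NSTATE || p.size() != SAN_NPAR)
      stop("san state/parameter vector has wrong length");
    NumericVector dy(SAN_NSTATE);
    san_eval(y.begin(), p.begin(), stim.size() ? stim[0] : 0.0,
             NULL, NULL, dy.begin(), NULL);
    return dy;
  } else if (family == 2) {
    if (y.size() != NRN_NSTATE || p.size() != NRN_NPAR)
      stop("neuron state/parameter vector has wrong length");
    NumericVector dy(NRN_NSTATE);
    double ss = stim.size() > 0 ? stim[0] : 0.0;
    double sd = stim.size() > 1 ? stim[1] : 0.0;
    nrn_eval(y.begin(), p.begin(), ss, sd, NULL, NULL, dy.begin(), NULL);
    return dy;
  }
  stop("unknown model family code");
}

// Membrane currents along a stored trajectory (rows = time points).
// [[Rcpp::export]]
NumericMatrix cell_currents_cpp(int family, NumericMatrix traj,
                                NumericVector p) {
  int nt = traj.nrow();
  if (family == 1) {
    if (traj.ncol() != SAN_NSTATE) stop("trajectory has wrong state count");
    CharacterVector nm = CharacterVector::create(
      "ICaL12", "ICaL13", "ICaT", "IKr", "If", "INa", "INaK", "INCX",
      "IbNa", "Itot");
    NumericMatrix out(nt, nm.size());
    std::vector<double> y(SAN_NSTATE);
    for (int i = 0; i < nt; ++i) {
      for (int j = 0; j < SAN_NSTATE; ++j) y[j] = traj(i, j);
      SanCurrents c;
      san_eval(y.data(), p.begin(), 0.0, NULL, NULL, NULL, &c);
      out(i, 0) = c.ICaL12; out(i, 1) = c.ICaL13; out(i, 2) = c.ICaT;
      out(i, 3) = c.IKr; out(i, 4) = c.If; out(i, 5) = c.INa;
      out(i, 6) = c.INaK; out(i, 7) = c.INCX; out(i, 8) = c.IbNa;
      out(i, 9) = c.Itot;
    }
    colnames(out) = nm;
    return out;
  } else if (family == 2) {
    if (traj.ncol() != NRN_NSTATE) stop("trajectory has wrong state count");
    CharacterVector nm = CharacterVector::create(
      "INaT", "INaP", "IKdr", "IKM", "ISK", "ICaHVA", "ICaLVA", "IH",
      "ILs", "ILd", "Iax");
    NumericMatrix out(nt, nm.size());
    std::vector<double> y(NRN_NSTATE);
    for (int i = 0; i < nt; ++i) {
      for (int j = 0; j < NRN_NSTATE; ++j) y[j] = traj(i, j);
      NrnCurrents c;
      nrn_eval(y.data(), p.begin(), 0.0, 0.0, NULL, NULL, NULL, &c);
      out(i, 0) = c.INaT; out(i, 1) = c.INaP; out(i, 2) = c.IKdr;
      out(i, 3) = c.IKM; out(i, 4) = c.ISK; out(i, 5) = c.ICaHVA;
      out(i, 6) = c.ICaLVA; out(i, 7) = c.IHs + c.IHd; out(i, 8) = c.ILs;
      out(i, 9) = c.ILd; out(i, 10) = c.Iax;
    }
    colnames(out) = nm;
    return out;
  }
  stop("unknown model family code");
}

// ---------------------------------------------------------------------------
// Fixed-step SAN cell update: Rush-Larsen for gates, forward Euler for V/Ca.
// Shared by the 1D cable and 2D tissue steppers.
// ---------------------------------------------------------------------------

static inline void san_step_rl(double* y, const double* p, double dt,
                               bool freezeV) {
  double inf[SAN_NSTATE], tau[SAN_NSTATE], dy[SAN_NSTATE];
  san_eval(y, p, 0.0, inf, tau, dy, NULL);
  for (int i = 1; i < SAN_NSTATE; ++i) {
    if (i == s_Cai || i == s_CaSR) continue;
    y[i] = inf[i] + (y[i] - inf[i]) * std::exp(-dt / tau[i]);
  }
  y[s_Cai]  += dt * dy[s_Cai];
  y[s_CaSR] += dt * dy[s_CaSR];
  if (y[s_Cai] < 1e-6) y[s_Cai] = 1e-6;
  if (!freezeV) y[s_V] += dt * dy[s_V];
}

// 1D chain of diffusively coupled SAN cells with a two-stage voltage-clamp
// protocol: all cells clamped to clampV1 on [0, t1); the first
// ceil(clampFrac * n) cells clamped to clampV2 on [t1, t2); free afterwards.
// coupling = D / dx^2 in 1/ms.
// [[Rcpp::export]]
List cable_sim_cpp(NumericVector p, NumericVector y0, int ncell,
                   double coupling, double dt, double duration,
                   double clampV1, double t1, double clampV2, double t2,
                   double clampFrac, double record_dt, double vthresh) {
  if (y0.size() != SAN_NSTATE || p.size() != SAN_NPAR)
    stop("bad state/parameter length");
  int nclamp = (int)std::ceil(clampFrac * ncell);
  std::vector<double> st(ncell * SAN_NSTATE);
  for (int i = 0; i < ncell; ++i)
    for (int j = 0; j < SAN_NSTATE; ++j) st[i * SAN_NSTATE + j] = y0[j];

  int nstep = (int)std::round(duration / dt);
  int rec_every = std::max(1, (int)std::round(record_dt / dt));
  int nrec = nstep / rec_every + 1;
  NumericMatrix Vout(nrec, ncell);
  NumericVector tout(nrec);
  NumericVector act(ncell, NA_REAL);
  std::vector<double> vnew(ncell);

  int irec = 0;
  for (int i = 0; i < ncell; ++i) Vout(0, i) = st[i * SAN_NSTATE + s_V];
  tout[0] = 0.0; irec = 1;

  for (int k = 0; k < nstep; ++k) {
    double t = k * dt;
    // clamp phase bookkeeping
    bool phase1 = t < t1, phase2 = (t >= t1 && t < t2);
    // reaction step
    for (int i = 0; i < ncell; ++i) {
      double* y = &st[i * SAN_NSTATE];
      bool clamped = phase1 || (phase2 && i < nclamp);
      if (phase1) y[s_V] = clampV1;
      else if (phase2 && i < nclamp) y[s_V] = clampV2;
      san_step_rl(y, p.begin(), dt, clamped);
      if (std::isnan(y[s_V]) || std::fabs(y[s_V]) > 200.0)
        stop("cable integration unstable (|V|>200 or NaN) at t=%f ms; "
             "reduce dt or coupling", t);
    }
    // diffusion step in conservative flux form with no-flux ends
    for (int i = 0; i < ncell; ++i) {
      double vc = st[i * SAN_NSTATE + s_V];
      double f = 0.0;
      if (i > 0) f += st[(i - 1) * SAN_NSTATE + s_V] - vc;
      if (i < ncell - 1) f += st[(i + 1) * SAN_NSTATE + s_V] - vc;
      vnew[i] = vc + dt * coupling * f;
    }
    for (int i = 0; i < ncell; ++i) {
      bool clamped = phase1 || (phase2 && i < nclamp);
      if (!clamped) st[i * SAN_NSTATE + s_V] = vnew[i];
    }
    double tnext = (k + 1) * dt;
    // activation detection for free cells, from the pulse onset
    if (tnext >= t1) {
      for (int i = 0; i < ncell; ++i) {
        double v = st[i * SAN_NSTATE + s_V];
        if (ISNAN(act[i]) && v >= vthresh && i >= nclamp)
          act[i] = tnext;
      }
    }
    if ((k + 1) % rec_every == 0 && irec < nrec) {
      for (int i = 0; i < ncell; ++i) Vout(irec, i) = st[i * SAN_NSTATE + s_V];
      tout[irec] = tnext;
      ++irec;
    }
  }
  return List::create(_["time"] = tout, _["V"] = Vout,
                      _["activation"] = act, _["n_clamped"] = nclamp);
}

// ---------------------------------------------------------------------------
// Three-variable phenomenological atrial membrane model (Fenton-Karma type),
// expressed on the physical mV scale via V = V0 + Vamp * u.
// ---------------------------------------------------------------------------

#define ATR_PARAMS(X)                                                   \
  X(V0) X(Vamp) X(uc) X(uv) X(taud) X(tauv1m) X(tauv2m) X(tauvp)        \
  X(tauwm) X(tauwp) X(tau0) X(taur) X(tausi) X(kk) X(ucsi)

enum AtrParam {
#define X(n) a_##n,
  ATR_PARAMS(X)
#undef X
  ATR_NPAR
};

// [[Rcpp::export]]
CharacterVector atrial_param_names_cpp() {
  CharacterVector out;
#define X(n) out.push_back(#n);
  ATR_PARAMS(X)
#undef X
  return out;
}

static inline void atr_step(double& V, double& v, double& w,
                            const double* a, double dt) {
  double u = (V - a[a_V0]) / a[a_Vamp];
  double Hc = u >= a[a_uc] ? 1.0 : 0.0;
  double Hv = u >= a[a_uv] ? 1.0 : 0.0;
  double tauvm = Hv * a[a_tauv1m] + (1.0 - Hv) * a[a_tauv2m];
  double Jfi = -v / a[a_taud] * Hc * (1.0 - u) * (u - a[a_uc]);
  double Jso = u / a[a_tau0] * (1.0 - Hc) + Hc / a[a_taur];
  double Jsi = -w / (2.0 * a[a_tausi]) *
               (1.0 + std::tanh(a[a_kk] * (u - a[a_ucsi])));
  double du = -(Jfi + Jso + Jsi);
  double dv = (1.0 - Hc) * (1.0 - v) / tauvm - Hc * v / a[a_tauvp];
  double dw = (1.0 - Hc) * (1.0 - w) / a[a_tauwm] - Hc * w / a[a_tauwp];
  V += dt * a[a_Vamp] * du;
  v += dt * dv;
  w += dt * dw;
}

// ---------------------------------------------------------------------------
// 2D monodomain tissue: SAN disc (full pacemaker model per node) embedded in
// atrial tissue (three-variable model per node).  Operator splitting:
// reaction substeps then one anisotropic finite-difference diffusion step
// with no-flux boundaries.  Dx, Dy in cm^2/ms, dx in cm, dt in ms.
// [[Rcpp::export]]
List tissue2d_sim_cpp(NumericVector pSan, NumericVector y0San,
                      NumericVector pAtr, NumericMatrix sanWeight,
                      double dx, double Dx, double Dy,
                      double dt, int nsub, double duration,
                      IntegerMatrix probes, double record_dt,
                      bool diffusion_only) {
  if (y0San.size() != SAN_NSTATE || pSan.size() != SAN_NPAR ||
      pAtr.size() != ATR_NPAR)
    stop("bad parameter/state lengths");
  int nx = sanWeight.nrow(), ny = sanWeight.ncol();
  int nn = nx * ny;
  std::vector<double> V(nn), atr_v(nn, 1.0), atr_w(nn, 1.0);
  std::vector<int> isSan(nn, 0);
  std::vector<double> sanStates;
  std::vector<int> sanIdx(nn, -1);
  int nsan = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int id = i + nx * j;
      if (sanWeight(i, j) > 0.0) { isSan[id] = 1; sanIdx[id] = nsan++; }
    }
  sanStates.resize((size_t)nsan * SAN_NSTATE);
  // per-node parameter vectors: the pacemaker drive conductances are scaled
  // by the node's transition weight, emulating a gradual SAN-to-atrium
  // change of cell properties toward the disc border
  static const SanParam driveIdx[] = {p_gCaL12, p_gCaL13, p_gCaT, p_gf,
                                      p_gNa};
  std::vector<double> sanPars((size_t)nsan * SAN_NPAR);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int id = i + nx * j;
      if (!isSan[id]) continue;
      double* pp = &sanPars[(size_t)sanIdx[id] * SAN_NPAR];
      for (int k = 0; k < SAN_NPAR; ++k) pp[k] = pSan[k];
      double w = sanWeight(i, j);
      if (w < 1.0)
        for (SanParam k : driveIdx) pp[k] *= w;
    }
  for (int id = 0; id < nn; ++id) {
    if (isSan[id]) {
      double* y = &sanStates[(size_t)sanIdx[id] * SAN_NSTATE];
      for (int k = 0; k < SAN_NSTATE; ++k) y[k] = y0San[k];
      V[id] = y0San[s_V];
    } else {
      V[id] = pAtr[a_V0];
    }
  }

  double rx = Dx * dt / (dx * dx), ry = Dy * dt / (dx * dx);
  if (2.0 * (rx + ry) > 1.0)
    stop("explicit diffusion step unstable: 2(rx+ry)=%f > 1 (dt=%f ms)",
         2.0 * (rx + ry), dt);

  int nstep = (int)std::round(duration / dt);
  int rec_every = std::max(1, (int)std::round(record_dt / dt));
  int nrec = nstep / rec_every + 1;
  int np = probes.nrow();
  NumericMatrix Pout(nrec, np);
  NumericVector tout(nrec);
  std::vector<double> Vnew(nn);
  double sdt = dt / nsub;

  auto record = [&](int irec, double t) {
    tout[irec] = t;
    for (int k = 0; k < np; ++k) {
      int id = (probes(k, 0) - 1) + nx * (probes(k, 1) - 1);
      Pout(irec, k) = V[id];
    }
  };
  record(0, 0.0);
  int irec = 1;

  for (int kstep = 0; kstep < nstep; ++kstep) {
    if (!diffusion_only) {
      for (int id = 0; id < nn; ++id) {
        if (isSan[id]) {
          double* y = &sanStates[(size_t)sanIdx[id] * SAN_NSTATE];
          const double* pp = &sanPars[(size_t)sanIdx[id] * SAN_NPAR];
          y[s_V] = V[id];
          for (int ss = 0; ss < nsub; ++ss)
            san_step_rl(y, pp, sdt, false);
          V[id] = y[s_V];
        } else {
          for (int ss = 0; ss < nsub; ++ss)
            atr_step(V[id], atr_v[id], atr_w[id], pAtr.begin(), sdt);
        }
        if (std::isnan(V[id]) || std::fabs(V[id]) > 200.0)
          stop("2D integration unstable (|V|>200 or NaN) at t=%f ms, "
               "node %d (dt=%f)", kstep * dt, id + 1, dt);
      }
    }
    // anisotropic diffusion in conservative flux form; a no-flux boundary
    // simply has no flux across it, which conserves the spatial mean of V
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int id = i + nx * j;
        double fx = 0.0, fy = 0.0;
        if (i > 0)      fx += V[id - 1] - V[id];
        if (i < nx - 1) fx += V[id + 1] - V[id];
        if (j > 0)      fy += V[id - nx] - V[id];
        if (j < ny - 1) fy += V[id + nx] - V[id];
        Vnew[id] = V[id] + rx * fx + ry * fy;
      }
    }
    V.swap(Vnew);
    if ((kstep + 1) % rec_every == 0 && irec < nrec)
      record(irec++, (kstep + 1) * dt);
  }

  double vmean = 0.0;
  for (int id = 0; id < nn; ++id) vmean += V[id];
  vmean /= nn;
  return List::create(_["time"] = tout, _["probes"] = Pout,
                      _["n_san"] = nsan, _["V_mean_final"] = vmean);
}
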