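// Simulation cores: compartmental cable solver (Hines), dual-exponential
// synapses with NMDA magnesium block, spine/dendrite calcium reaction-
// diffusion with buffers and Michaelis-Menten pumps, and the dual
// amplitude/duration calcium-threshold weight-update rule.
//
// Unit conventions (consistent set):
//   time ms, voltage mV, capacitance nF, conductance uS, current nA,
//   length um, volume um^3, area um^2, concentration uM,
//   diffusion coefficient um^2/ms.
// Charge-to-concentration conversion: 1 nA of Ca2+ current into 1 um^3
// raises concentration by 5182.6 uM/ms (1e-12 C/ms / (2*96485 C/mol),
// expressed in 1e-21 mol, i.e. uM*um^3).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double CA_CONV = 1e6 / (2.0 * 96485.3329); // uM*um^3 per nA*ms
static const double EPS_AMP = 1e-9;  // uM guard on amplitude-threshold ties
static const double EPS_DUR = 1e-9;  // ms guard on duration-threshold ties

// ------------------------------------------------------------------
// calcium system
// ------------------------------------------------------------------

struct CaSys {
  int nelem = 0, nbuf = 0;
  std::vector<double> vol, area, leak;
  std::vector<int> is_spine;
  std::vector<int> pair_a, pair_b;
  std::vector<double> pair_k; // coupling area / distance (um)
  double d_ca = 0.2;
  std::vector<double> buf_tot, buf_kon, buf_koff, buf_d;
  double pmca_vmax = 0.0, pmca_km = 0.3, ncx_vmax = 0.0, ncx_km = 1.0;
  double ca_rest = 0.05;
  int react_sub = 4;
  bool pumps_on = true;
  std::vector<double> ca;
  std::vector<std::vector<double>> bound;
};

static CaSys ca_build(List geom, List pars, bool pumps_on) {
  CaSys S;
  S.vol = as<std::vector<double>>(geom["vol"]);
  S.area = as<std::vector<double>>(geom["area"]);
  S.is_spine = as<std::vector<int>>(geom["is_spine"]);
  S.pair_a = as<std::vector<int>>(geom["pair_a"]);
  S.pair_b = as<std::vector<int>>(geom["pair_b"]);
  S.pair_k = as<std::vector<double>>(geom["pair_k"]);
  S.nelem = (int)S.vol.size();
  S.d_ca = as<double>(pars["d_ca"]);
  S.buf_tot = as<std::vector<double>>(pars["buf_tot"]);
  S.buf_kon = as<std::vector<double>>(pars["buf_kon"]);
  S.buf_koff = as<std::vector<double>>(pars["buf_koff"]);
  S.buf_d = as<std::vector<double>>(pars["buf_d"]);
  S.nbuf = (int)S.buf_tot.size();
  S.pmca_vmax = as<double>(pars["pmca_vmax"]);
  S.pmca_km = as<double>(pars["pmca_km"]);
  S.ncx_vmax = as<double>(pars["ncx_vmax"]);
  S.ncx_km = as<double>(pars["ncx_km"]);
  S.ca_rest = as<double>(pars["ca_rest"]);
  S.react_sub = pars.containsElementNamed("react_substeps")
                    ? as<int>(pars["react_substeps"]) : 4;
  S.pumps_on = pumps_on;
  // resting state: free calcium at ca_rest, buffers at binding equilibrium
  S.ca.assign(S.nelem, S.ca_rest);
  S.bound.resize(S.nbuf);
  for (int b = 0; b < S.nbuf; b++) {
    double kd = S.buf_koff[b] / S.buf_kon[b];
    S.bound[b].assign(S.nelem, S.buf_tot[b] * S.ca_rest / (S.ca_rest + kd));
  }
  // constant leak influx balancing pump extrusion at rest
  S.leak.assign(S.nelem, 0.0);
  for (int i = 0; i < S.nelem; i++) {
    if (S.area[i] <= 0) continue;
    double out = S.pmca_vmax * S.ca_rest / (S.ca_rest + S.pmca_km);
    if (S.is_spine[i]) out += S.ncx_vmax * S.ca_rest / (S.ca_rest + S.ncx_km);
    S.leak[i] = out * S.area[i] / S.vol[i];
  }
  return S;
}

// one operator-split step: influx -> reaction -> diffusion -> extrusion
static void ca_step(CaSys &S, const double *influx, double dt) {
  const int n = S.nelem;
  // influx is interleaved with the semi-implicit (implicit in bound
  // fraction) mass-action update, sub-stepped: approximates continuous
  // injection against the stiff calmodulin N-lobe kinetics, stable at
  // large transients and exactly calcium-conserving
  const double dtr = dt / S.react_sub;
  for (int ss = 0; ss < S.react_sub; ss++) {
    if (influx) for (int i = 0; i < n; i++) S.ca[i] += dtr * influx[i];
    for (int b = 0; b < S.nbuf; b++) {
      const double kon = S.buf_kon[b], koff = S.buf_koff[b],
                   tot = S.buf_tot[b];
      double *bd = S.bound[b].data();
      for (int i = 0; i < n; i++) {
        double bnew = (bd[i] + dtr * kon * S.ca[i] * tot) /
                      (1.0 + dtr * (kon * S.ca[i] + koff));
        S.ca[i] -= bnew - bd[i];
        bd[i] = bnew;
      }
    }
  }
  // pairwise exponential relaxation of the concentration difference: exact
  // for an isolated pair, mass-conserving and unconditionally stable on the
  // stiff spine-neck couplings
  const int np = (int)S.pair_a.size();
  for (int p = 0; p < np; p++) {
    int a = S.pair_a[p], b = S.pair_b[p];
    double sv = 1.0 / S.vol[a] + 1.0 / S.vol[b];
    double r = S.d_ca * S.pair_k[p] * sv;
    double m = (S.ca[a] - S.ca[b]) * (1.0 - std::exp(-dt * r)) / sv;
    S.ca[a] -= m / S.vol[a];
    S.ca[b] += m / S.vol[b];
  }
  for (int bf = 0; bf < S.nbuf; bf++) {
    if (S.buf_d[bf] <= 0) continue;
    double *bd = S.bound[bf].data();
    for (int p = 0; p < np; p++) {
      int a = S.pair_a[p], b = S.pair_b[p];
      double sv = 1.0 / S.vol[a] + 1.0 / S.vol[b];
      double r = S.buf_d[bf] * S.pair_k[p] * sv;
      double m = (bd[a] - bd[b]) * (1.0 - std::exp(-dt * r)) / sv;
      bd[a] -= m / S.vol[a];
      bd[b] += m / S.vol[b];
    }
  }
  if (S.pumps_on) {
    for (int i = 0; i < n; i++) {
      if (S.area[i] <= 0) continue;
      double c = S.ca[i];
      double out = S.pmca_vmax * c / (c + S.pmca_km);
      if (S.is_spine[i]) out += S.ncx_vmax * c / (c + S.ncx_km);
      S.ca[i] += dt * (S.leak[i] - out * S.area[i] / S.vol[i]);
    }
  }
}

static void ca_check(const CaSys &S, double t, double dt) {
  for (int i = 0; i < S.nelem; i++) {
    if (!std::isfinite(S.ca[i]) || S.ca[i] < 0)
      stop("calcium concentration negative or non-finite in element %d at t = %g ms (dt = %g ms too large?)",
           i + 1, t, dt);
  }
}

// total calcium (free + bound), volume weighted, in uM*um^3
static double ca_mass(const CaSys &S) {
  double m = 0;
  for (int i = 0; i < S.nelem; i++) {
    double c = S.ca[i];
    for (int b = 0; b < S.nbuf; b++) c += S.bound[b][i];
    m += c * S.vol[i];
  }
  return m;
}

// ------------------------------------------------------------------
// plasticity rule
// ------------------------------------------------------------------

struct PlastState {
  double w, timer_ad, timer_ap;
  int engaged; // 0 none, +1 LTP branch, -1 LTD branch
};

struct PlastPars {
  double t_ad, t_ap, dur_d, dur_p, g_p, g_pmax, g_d, g_dmax, wmin, wmax;
};

static PlastPars plast_pars_from(NumericVector p) {
  PlastPars q;
  q.t_ad = p[0]; q.t_ap = p[1]; q.dur_d = p[2]; q.dur_p = p[3];
  q.g_p = p[4]; q.g_pmax = p[5]; q.g_d = p[6]; q.g_dmax = p[7];
  q.wmin = p[8]; q.wmax = p[9];
  return q;
}

// one rule step; returns engaged branch (+1/-1/0)
static int plast_step(PlastState &s, const PlastPars &p, double ca, double dt) {
  if (ca >= p.t_ad - EPS_AMP) s.timer_ad += dt; else s.timer_ad = 0;
  if (ca >= p.t_ap - EPS_AMP) s.timer_ap += dt; else s.timer_ap = 0;
  double range = p.wmax - p.wmin;
  double dw = 0;
  int engaged = 0;
  if (ca >= p.t_ap - EPS_AMP && s.timer_ap > p.dur_p + EPS_DUR) {
    dw = std::min(p.g_pmax, p.g_p * (ca - p.t_ap)) *
         (1.0 - (s.w - p.wmin) / range);
    engaged = 1;
  } else if (ca >= p.t_ad - EPS_AMP && s.timer_ad > p.dur_d + EPS_DUR) {
    dw = -std::min(p.g_dmax, p.g_d * (ca - p.t_ad)) *
         ((s.w - p.wmin) / range);
    engaged = -1;
  }
  s.w += dw * dt;
  if (s.w > p.wmax) s.w = p.wmax;
  if (s.w < p.wmin) s.w = p.wmin;
  return engaged;
}

// [[Rcpp::export]]
List weight_update_cpp(NumericVector ca, double dt, NumericVector pars,
                       double w0) {
  PlastPars p = plast_pars_from(pars);
  PlastState s; s.w = w0; s.timer_ad = 0; s.timer_ap = 0; s.engaged = 0;
  int n = ca.size();
  NumericVector w(n);
  std::vector<double> ev_t; std::vector<int> ev_sign;
  int prev = 0;
  for (int k = 0; k < n; k++) {
    if (ca[k] < 0) stop("negative calcium concentration in trace at sample %d", k + 1);
    int e = plast_step(s, p, ca[k], dt);
    if (e != 0 && e != prev) {
      ev_t.push_back((k + 1) * dt);
      ev_sign.push_back(e);
    }
    prev = e;
    w[k] = s.w;
  }
  return List::create(_["w"] = w, _["event_time"] = wrap(ev_t),
                      _["event_sign"] = wrap(ev_sign));
}

// ------------------------------------------------------------------
// standalone calcium run (module-level surface, used with prescribed influx)
// ------------------------------------------------------------------

// influx_rates: matrix (n influx elements) x (nsteps), uM/ms
// [[Rcpp::export]]
List calcium_run_cpp(List geom, List pars, IntegerVector influx_elem,
                     NumericMatrix influx_rates, double dt, int nsteps,
                     int rec_stride, bool pumps_on) {
  CaSys S = ca_build(geom, pars, pumps_on);
  int nin = influx_elem.size();
  bool has_influx = nin > 0 && influx_rates.ncol() > 0;
  std::vector<double> influx(S.nelem, 0.0);
  int nrec = nsteps / rec_stride;
  NumericMatrix ca_rec(S.nelem, nrec);
  NumericVector mass(nrec), t_rec(nrec);
  int ri = 0;
  for (int k = 0; k < nsteps; k++) {
    if (has_influx) {
      int col = std::min(k, (int)influx_rates.ncol() - 1);
      for (int j = 0; j < nin; j++) influx[influx_elem[j]] = influx_rates(j, col);
    }
    ca_step(S, has_influx ? influx.data() : nullptr, dt);
    if ((k + 1) % rec_stride == 0) {
      for (int i = 0; i < S.nelem; i++) ca_rec(i, ri) = S.ca[i];
      mass[ri] = ca_mass(S);
      t_rec[ri] = (k + 1) * dt;
      ri++;
    }
    if ((k & 255) == 0) ca_check(S, (k + 1) * dt, dt);
  }
  ca_check(S, nsteps * dt, dt);
  List bound_out(S.nbuf);
  for (int b = 0; b < S.nbuf; b++) bound_out[b] = wrap(S.bound[b]);
  return List::create(_["time"] = t_rec, _["ca"] = ca_rec, _["mass"] = mass,
                      _["ca_final"] = wrap(S.ca), _["bound_final"] = bound_out);
}

// ------------------------------------------------------------------
// fused cable + calcium + plasticity engine
// ------------------------------------------------------------------

// [[Rcpp::export]]
List sim_core_cpp(IntegerVector parent, NumericVector cap, NumericVector g_leak,
                  NumericVector e_leak, NumericVector g_axial, double v_init,
                  int soma_index, NumericVector soma_pars,
                  IntegerVector syn_node, IntegerVector syn_type,
                  NumericVector syn_gmax, NumericVector syn_tau_r,
                  NumericVector syn_tau_d, NumericVector syn_erev,
                  NumericVector syn_events, IntegerVector syn_ev_ptr,
                  NumericVector nmda_pars, NumericVector vgcc_g,
                  NumericVector vgcc_pars, int iclamp_node, double iclamp_amp,
                  double iclamp_on, double iclamp_off, double dt, double t_stop,
                  IntegerVector rec_nodes, int rec_stride, double spike_thresh,
                  List ca_geom, List ca_pars, IntegerVector syn_ca_elem,
                  IntegerVector node_ca_elem, IntegerVector spine_head_elem,
                  int ca_rec_stride, NumericVector plast_pars,
                  NumericVector w0, int w_rec_stride, bool record_influx) {
  const int nc = parent.size();
  const int nsyn = syn_node.size();
  const int nsteps = (int)std::llround(t_stop / dt);

  // --- cable pre-computation (Hines ordering assumed: parent[i] < i) ---
  std::vector<double> diag_static(nc), cphi(nc);
  for (int i = 0; i < nc; i++) {
    cphi[i] = cap[i] / dt;
    diag_static[i] = cphi[i] + g_leak[i];
    if (parent[i] >= 0) diag_static[i] += g_axial[i];
  }
  for (int i = 0; i < nc; i++)
    if (parent[i] >= 0) diag_static[parent[i]] += g_axial[i];

  std::vector<double> v(nc, v_init), diag(nc), rhs(nc);

  // --- soma spiking channels ---
  bool has_soma = soma_pars.size() >= 9;
  double gna = 0, ena = 0, vhm = 0, km = 1, gk = 0, ek = 0, vhn = 0, kn = 1,
         taun = 1;
  if (has_soma) {
    gna = soma_pars[0]; ena = soma_pars[1]; vhm = soma_pars[2];
    km = soma_pars[3]; gk = soma_pars[4]; ek = soma_pars[5];
    vhn = soma_pars[6]; kn = soma_pars[7]; taun = soma_pars[8];
  }
  double ngate = has_soma ? 1.0 / (1.0 + std::exp(-(v_init - vhn) / kn)) : 0.0;

  // --- synapses: dual exponential, normalized to peak gmax ---
  std::vector<double> sA(nsyn, 0.0), sB(nsyn, 0.0), decA(nsyn), decB(nsyn),
      norm(nsyn);
  std::vector<int> evp(nsyn);
  for (int s = 0; s < nsyn; s++) {
    double tr = syn_tau_r[s], td = syn_tau_d[s];
    decA[s] = std::exp(-dt / tr);
    decB[s] = std::exp(-dt / td);
    double tp = tr * td / (td - tr) * std::log(td / tr);
    norm[s] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    evp[s] = syn_ev_ptr[s];
  }
  const double mg = nmda_pars[0], mgK = nmda_pars[1], mgS = nmda_pars[2],
               ca_frac = nmda_pars[3];
  const double eca = vgcc_pars[0], vhca = vgcc_pars[1], kca = vgcc_pars[2];

  // --- calcium system (optional) ---
  bool has_ca = ca_geom.size() > 0 &&
                as<NumericVector>(ca_geom["vol"]).size() > 0;
  CaSys S;
  std::vector<double> influx;
  std::vector<int> touched;
  if (has_ca) {
    S = ca_build(ca_geom, ca_pars, true);
    influx.assign(S.nelem, 0.0);
  }

  // --- plasticity (optional) ---
  bool has_plast = plast_pars.size() >= 10 && w0.size() > 0;
  PlastPars pp;
  int nspine = spine_head_elem.size();
  std::vector<PlastState> ps;
  std::vector<int> prev_engaged;
  if (has_plast) {
    pp = plast_pars_from(plast_pars);
    ps.resize(nspine);
    prev_engaged.assign(nspine, 0);
    for (int s = 0; s < nspine; s++) {
      ps[s].w = w0[s]; ps[s].timer_ad = 0; ps[s].timer_ap = 0;
    }
  }

  // --- recording buffers ---
  const int nrecn = rec_nodes.size();
  const int nvrec = rec_stride > 0 ? nsteps / rec_stride : 0;
  NumericMatrix v_rec(nrecn, std::max(nvrec, 0));
  NumericVector tv_rec(std::max(nvrec, 0));
  const int ncarec = (has_ca && ca_rec_stride > 0) ? nsteps / ca_rec_stride : 0;
  NumericMatrix ca_rec(has_ca ? nspine : 0, ncarec);
  NumericMatrix influx_rec(record_influx && has_ca ? nspine : 0,
                           record_influx ? ncarec : 0);
  NumericVector tca_rec(ncarec);
  const int nwrec = (has_plast && w_rec_stride > 0) ? nsteps / w_rec_stride : 0;
  NumericMatrix w_rec(has_plast ? nspine : 0, nwrec);
  NumericVector tw_rec(nwrec);
  std::vector<double> spike_times, ev_t;
  std::vector<int> ev_spine, ev_sign;

  double v_soma_prev = v_init;
  int vi = 0, ci = 0, wi = 0;

  for (int k = 0; k < nsteps; k++) {
    const double t = (k + 1) * dt;
    // reset influx accumulators touched last step
    if (has_ca) {
      for (size_t j = 0; j < touched.size(); j++) influx[touched[j]] = 0.0;
      touched.clear();
    }
    // assemble
    for (int i = 0; i < nc; i++) {
      diag[i] = diag_static[i];
      rhs[i] = cphi[i] * v[i] + g_leak[i] * e_leak[i];
    }
    if (iclamp_node >= 0 && t > iclamp_on && t <= iclamp_off)
      rhs[iclamp_node] += iclamp_amp;
    if (has_soma) {
      double minf = 1.0 / (1.0 + std::exp(-(v[soma_index] - vhm) / km));
      double gna_t = gna * minf, gk_t = gk * ngate;
      diag[soma_index] += gna_t + gk_t;
      rhs[soma_index] += gna_t * ena + gk_t * ek;
    }
    // synapses
    for (int s = 0; s < nsyn; s++) {
      sA[s] *= decA[s];
      sB[s] *= decB[s];
      while (evp[s] < syn_ev_ptr[s + 1] && syn_events[evp[s]] <= t) {
        sA[s] += 1.0; sB[s] += 1.0; evp[s]++;
      }
      double g = syn_gmax[s] * norm[s] * (sB[s] - sA[s]);
      if (g <= 0) continue;
      int nd = syn_node[s];
      if (syn_type[s] == 1) { // NMDA: magnesium block at current voltage
        double block = 1.0 / (1.0 + mg / mgK * std::exp(-v[nd] / mgS));
        g *= block;
        if (has_ca && syn_ca_elem[s] >= 0) {
          double i_ca = ca_frac * g * (v[nd] - syn_erev[s]); // nA, inward < 0
          if (i_ca < 0) {
            int e = syn_ca_elem[s];
            if (influx[e] == 0.0) touched.push_back(e);
            influx[e] += -i_ca * CA_CONV / S.vol[e];
          }
        }
      }
      diag[nd] += g;
      rhs[nd] += g * syn_erev[s];
    }
    // Hines solve (parent[i] < i guaranteed)
    for (int i = nc - 1; i >= 1; i--) {
      int p = parent[i];
      double f = g_axial[i] / diag[i];
      diag[p] -= f * g_axial[i];
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < nc; i++)
      v[i] = (rhs[i] + g_axial[i] * v[parent[i]]) / diag[i];
    // gate update (semi-implicit) and spike detection
    if (has_soma) {
      double ninf = 1.0 / (1.0 + std::exp(-(v[soma_index] - vhn) / kn));
      ngate = (ngate + dt * ninf / taun) / (1.0 + dt / taun);
      if (v[soma_index] >= spike_thresh && v_soma_prev < spike_thresh)
        spike_times.push_back(t);
      v_soma_prev = v[soma_index];
    }
    if (!std::isfinite(v[0]) || std::fabs(v[0]) > 200)
      stop("membrane potential out of bounds at t = %g ms in compartment 1 (dt = %g ms)", t, dt);
    // VGCC calcium influx (current fed to calcium pool only)
    if (has_ca) {
      for (int i = 0; i < nc; i++) {
        if (vgcc_g[i] <= 0 || node_ca_elem[i] < 0) continue;
        double sinf = 1.0 / (1.0 + std::exp(-(v[i] - vhca) / kca));
        double i_ca = vgcc_g[i] * sinf * (v[i] - eca);
        if (i_ca < 0) {
          int e = node_ca_elem[i];
          if (influx[e] == 0.0) touched.push_back(e);
          influx[e] += -i_ca * CA_CONV / S.vol[e];
        }
      }
      ca_step(S, influx.data(), dt);
      if ((k & 511) == 0) ca_check(S, t, dt);
    }
    // plasticity on spine-head free calcium
    if (has_plast) {
      for (int s = 0; s < nspine; s++) {
        double cah = S.ca[spine_head_elem[s]];
        int e = plast_step(ps[s], pp, cah, dt);
        if (e != 0 && e != prev_engaged[s]) {
          ev_t.push_back(t); ev_spine.push_back(s + 1); ev_sign.push_back(e);
        }
        prev_engaged[s] = e;
      }
    }
    // recording
    if (rec_stride > 0 && (k + 1) % rec_stride == 0) {
      for (int j = 0; j < nrecn; j++) v_rec(j, vi) = v[rec_nodes[j]];
      tv_rec[vi] = t;
      vi++;
    }
    if (has_ca && ca_rec_stride > 0 && (k + 1) % ca_rec_stride == 0) {
      for (int s = 0; s < nspine; s++) ca_rec(s, ci) = S.ca[spine_head_elem[s]];
      if (record_influx)
        for (int s = 0; s < nspine; s++)
          influx_rec(s, ci) = influx[spine_head_elem[s]];
      tca_rec[ci] = t;
      ci++;
    }
    if (has_plast && w_rec_stride > 0 && (k + 1) % w_rec_stride == 0) {
      for (int s = 0; s < nspine; s++) w_rec(s, wi) = ps[s].w;
      tw_rec[wi] = t;
      wi++;
    }
  }
  if (has_ca) ca_check(S, t_stop, dt);

  NumericVector w_final(has_plast ? nspine : 0);
  if (has_plast) for (int s = 0; s < nspine; s++) w_final[s] = ps[s].w;
  return List::create(
      _["t_v"] = tv_rec, _["v"] = v_rec, _["spike_times"] = wrap(spike_times),
      _["t_ca"] = tca_rec, _["ca_spine"] = ca_rec,
      _["influx_spine"] = influx_rec, _["t_w"] = tw_rec, _["w"] = w_rec,
      _["w_final"] = w_final, _["event_time"] = wrap(ev_t),
      _["event_spine"] = wrap(ev_spine), _["event_sign"] = wrap(ev_sign));
}
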