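#include <Rcpp.h>
#include <cmath>
#include <sstream>
#include <vector>
using namespace Rcpp;

// Fixed-step explicit integrator for the closed-loop lumped-parameter
// network, with the four-step reflex controller running on its own tick.
// Deterministic: no RNG, no adaptive stepping.
//
// Valve codes: 0 none, 1 cardiac valve, 2 structural one-way
// (microvascular Starling / venous valve).
// valve_mode_post: 0 = all valves open (plain resistors) after arrest,
// 1 = diodes stay diodes, 2 = cardiac valves sealed shut, others diodes.

// [[Rcpp::export]]
List simulate_cpp(List topo, List pars, Nullable<List> ctrl_) {
  IntegerVector is_cardiac = topo["is_cardiac"];
  NumericVector C = topo["C"], Emin = topo["Emin"], Emax = topo["Emax"];
  NumericVector V0 = topo["V0"], act_delay = topo["act_delay"];
  IntegerVector thoracic = topo["thoracic"];
  NumericVector vu_w = topo["vu_w"], E_arrest = topo["E_arrest"];
  IntegerVector ef = topo["edge_from"], et = topo["edge_to"];
  NumericVector eR = topo["edge_R"];
  IntegerVector evalve = topo["edge_valve"], ereflex = topo["edge_reflex"];
  const int n = C.size(), m = eR.size();
  const int ctrl_a = as<int>(topo["ctrl_a_node"]);
  const int ctrl_v = as<int>(topo["ctrl_v_node"]);
  const int meas_abp = as<int>(topo["meas_abp_node"]);
  const int meas_cvp = as<int>(topo["meas_cvp_node"]);
  const int co_edge = as<int>(topo["co_edge"]);

  NumericVector Vinit = pars["V_init"];
  const double dt = as<double>(pars["dt"]);
  const double t0 = as<double>(pars["t0"]);
  const double t_end = as<double>(pars["t_end"]);
  const double record_from = as<double>(pars["record_from"]);
  const double fs = as<double>(pars["fs"]);
  const double HR0 = as<double>(pars["HR0"]);
  const double RR0 = as<double>(pars["RR0"]);
  const double pit_mean = as<double>(pars["pit_mean"]);
  const double pit_amp = as<double>(pars["pit_amp"]);
  const double sys_k = as<double>(pars["sys_k"]);
  const double arrest_time = as<double>(pars["arrest_time"]);
  const int valve_mode_post = as<int>(pars["valve_mode_post"]);

  const int samp_every = (int)std::lround(1.0 / (fs * dt));
  const long nsteps = (long)std::lround((t_end - t0) / dt);

  // controller setup
  bool con_on = false;
  int window_n = 250, tick_every = 1, n_arcs = 0;
  double set_a = 0, set_p = 0, set_v = 0, lim_abr = 18, lim_cpr = 5;
  std::vector<int> arc_source, arc_every;
  std::vector<std::vector<double>> kern, hist;
  std::vector<int> hist_head;
  std::vector<double> g_hr, g_ct, g_rs, g_vu, eff_arc;
  if (ctrl_.isNotNull()) {
    List ctrl(ctrl_);
    con_on = true;
    window_n = as<int>(ctrl["window_n"]);
    tick_every = as<int>(ctrl["tick_every"]);
    set_a = as<double>(ctrl["set_a"]);
    set_p = as<double>(ctrl["set_p"]);
    set_v = as<double>(ctrl["set_v"]);
    lim_abr = as<double>(ctrl["lim_abr"]);
    lim_cpr = as<double>(ctrl["lim_cpr"]);
    IntegerVector asrc = ctrl["arc_source"], aev = ctrl["arc_every"];
    NumericVector ghr = ctrl["g_hr"], gct = ctrl["g_contract"];
    NumericVector grs = ctrl["g_resist"], gvu = ctrl["g_vu"];
    List kl = ctrl["kernels"];
    n_arcs = asrc.size();
    for (int a = 0; a < n_arcs; ++a) {
      arc_source.push_back(asrc[a]);
      arc_every.push_back(aev[a]);
      NumericVector k = kl[a];
      kern.push_back(std::vector<double>(k.begin(), k.end()));
      hist.push_back(std::vector<double>(k.size(), 0.0));
      hist_head.push_back(-1);
      g_hr.push_back(ghr[a]); g_ct.push_back(gct[a]);
      g_rs.push_back(grs[a]); g_vu.push_back(gvu[a]);
      eff_arc.push_back(0.0);
    }
  }

  // state
  std::vector<double> V(Vinit.begin(), Vinit.end());
  std::vector<double> P(n), E(n), Vu(n);
  for (int i = 0; i < n; ++i) Vu[i] = V0[i];
  double cphase = 0.0, rphase = 0.0;
  double hr_eff = HR0, contract = 1.0, rscale = 1.0, dvu = 0.0;

  // afferent buffers (running-sum ring buffers)
  std::vector<double> buf_a(window_n), buf_p(window_n), buf_v(window_n);
  double sum_a = 0, sum_p = 0, sum_v = 0;
  int buf_i = 0;
  bool buf_init = false;
  long tick_count = 0;

  // pulse-pressure tracking
  double beat_max = -1e300, beat_min = 1e300, pp_commit = set_p;
  bool had_beat = false;

  const long n_out_max = nsteps / samp_every + 2;
  NumericVector out_t(n_out_max), out_abp(n_out_max), out_cvp(n_out_max),
      out_co(n_out_max), out_hr(n_out_max), out_ct(n_out_max),
      out_rs(n_out_max), out_dvu(n_out_max);
  long n_out = 0;
  std::string err = "";
  double sumV_start = 0, max_drift = 0;
  for (int i = 0; i < n; ++i) sumV_start += V[i];
  double minV = R_PosInf;

  const double twopi = 2.0 * M_PI;
  for (long s = 0; s < nsteps; ++s) {
    const double t = t0 + s * dt;
    const bool arrested = (t >= arrest_time);

    // elastances and pressures
    const double T_cycle = 60.0 / (hr_eff > 1e-9 ? hr_eff : 1e-9);
    const double Ts = sys_k * std::sqrt(T_cycle);
    const double pit = arrested ? 0.0 : (pit_mean + pit_amp * std::sin(twopi * rphase));
    for (int i = 0; i < n; ++i) {
      const double pe = thoracic[i] ? pit : 0.0;
      if (is_cardiac[i]) {
        double Ei;
        if (arrested) {
          Ei = E_arrest[i];
        } else {
          double u = cphase - act_delay[i];
          u -= std::floor(u);
          const double ts = u * T_cycle;
          const double act = (ts < Ts) ? 0.5 * (1.0 - std::cos(twopi * ts / Ts)) : 0.0;
          Ei = Emin[i] + (Emax[i] * contract - Emin[i]) * act;
        }
        E[i] = Ei;
        P[i] = Ei * (V[i] - Vu[i]) + pe;
      } else {
        P[i] = (V[i] - Vu[i]) / C[i] + pe;
      }
    }

    // controller tick
    if (con_on && (s % tick_every == 0)) {
      const double pa = P[ctrl_a];
      const double pv = P[ctrl_v];
      const double ppv = arrested ? 0.0 : pp_commit;
      if (!buf_init) {
        for (int j = 0; j < window_n; ++j) { buf_a[j] = pa; buf_p[j] = ppv; buf_v[j] = pv; }
        sum_a = pa * window_n; sum_p = ppv * window_n; sum_v = pv * window_n;
        buf_init = true;
      } else {
        sum_a += pa - buf_a[buf_i]; buf_a[buf_i] = pa;
        sum_p += ppv - buf_p[buf_i]; buf_p[buf_i] = ppv;
        sum_v += pv - buf_v[buf_i]; buf_v[buf_i] = pv;
        buf_i = (buf_i + 1) % window_n;
      }
      const double err_a = sum_a / window_n - set_a;
      const double err_p = sum_p / window_n - set_p;
      const double err_v = sum_v / window_n - set_v;
      const double sc_a = (2.0 * lim_abr / M_PI) * std::atan(M_PI * err_a / (2.0 * lim_abr));
      const double sc_p = (2.0 * lim_abr / M_PI) * std::atan(M_PI * err_p / (2.0 * lim_abr));
      const double sc_v = (2.0 * lim_cpr / M_PI) * std::atan(M_PI * err_v / (2.0 * lim_cpr));
      for (int a = 0; a < n_arcs; ++a) {
        if (tick_count % arc_every[a] != 0) continue;
        const double x = arc_source[a] == 0 ? sc_a : (arc_source[a] == 1 ? sc_p : sc_v);
        const int nk = (int)kern[a].size();
        if (hist_head[a] < 0) {
          for (int j = 0; j < nk; ++j) hist[a][j] = x;
          hist_head[a] = 0;
        } else {
          hist_head[a] = (hist_head[a] + 1) % nk;
          hist[a][hist_head[a]] = x;
        }
        double y = 0.0;
        int idx = hist_head[a];
        for (int j = 0; j < nk; ++j) {
          y += kern[a][j] * hist[a][idx];
          idx = (idx == 0) ? nk - 1 : idx - 1;
        }
        eff_arc[a] = y;
      }
      tick_count++;
      double dh = 0.0, dc = 0.0, dr = 0.0, dv = 0.0;
      for (int a = 0; a < n_arcs; ++a) {
        dh += g_hr[a] * eff_arc[a];
        dc += g_ct[a] * eff_arc[a];
        dr += g_rs[a] * eff_arc[a];
        dv += g_vu[a] * eff_arc[a];
      }
      hr_eff = HR0 + dh; if (hr_eff < 0.0) hr_eff = 0.0;
      contract = 1.0 + dc; if (contract < 0.1) contract = 0.1;
      rscale = 1.0 + dr; if (rscale < 0.1) rscale = 0.1;
      dvu = dv;
      for (int i = 0; i < n; ++i) {
        Vu[i] = V0[i] + dvu * vu_w[i];
        if (Vu[i] < 0.0) Vu[i] = 0.0;
      }
    }

    // pulse-pressure bookkeeping on the afferent arterial node
    if (!arrested) {
      const double pa_now = P[ctrl_a];
      if (pa_now > beat_max) beat_max = pa_now;
      if (pa_now < beat_min) beat_min = pa_now;
    }

    // flows
    double co_flow = 0.0;
    std::vector<double> dV(n, 0.0);
    for (int j = 0; j < m; ++j) {
      const double Rj = ereflex[j] ? eR[j] * rscale : eR[j];
      const double dP = P[ef[j]] - P[et[j]];
      double q;
      if (evalve[j] == 0) {
        q = dP / Rj;
      } else if (!arrested) {
        q = dP > 0.0 ? dP / Rj : 0.0;
      } else if (valve_mode_post == 0) {
        q = dP / Rj;
      } else if (valve_mode_post == 2 && evalve[j] == 1) {
        q = 0.0;
      } else {
        q = dP > 0.0 ? dP / Rj : 0.0;
      }
      if (j == co_edge) co_flow = q;
      dV[ef[j]] -= q * dt;
      dV[et[j]] += q * dt;
    }

    // record sample (state at time t)
    if (s % samp_every == 0 && t >= record_from - 1e-9) {
      out_t[n_out] = t;
      out_abp[n_out] = P[meas_abp];
      out_cvp[n_out] = P[meas_cvp];
      out_co[n_out] = co_flow * 60.0 / 1000.0;  // mL/s -> L/min
      out_hr[n_out] = arrested ? 0.0 : hr_eff;
      out_ct[n_out] = contract;
      out_rs[n_out] = rscale;
      out_dvu[n_out] = dvu;
      n_out++;
      // integrity checks at sampling cadence
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        sv += V[i];
        if (V[i] < minV) minV = V[i];
        if (!std::isfinite(V[i]) || V[i] < 0.0) {
          std::ostringstream os;
          os << "non-finite or negative volume in compartment " << i
             << " at t = " << t;
          err = os.str();
        }
      }
      const double drift = std::fabs(sv - sumV_start);
      if (drift > max_drift) max_drift = drift;
      if (!err.empty()) break;
    }

    // advance
    for (int i = 0; i < n; ++i) V[i] += dV[i];
    if (!arrested) {
      const double new_cphase = cphase + dt * hr_eff / 60.0;
      if (new_cphase >= 1.0) {
        cphase = new_cphase - std::floor(new_cphase);
        if (had_beat || beat_max > beat_min) pp_commit = beat_max - beat_min;
        had_beat = true;
        beat_max = -1e300; beat_min = 1e300;
      } else {
        cphase = new_cphase;
      }
      rphase = rphase + dt * RR0 / 60.0;
      rphase -= std::floor(rphase);
    }
  }

  NumericVector Vfin(n), Pfin(n);
  for (int i = 0; i < n; ++i) { Vfin[i] = V[i]; Pfin[i] = P[i]; }
  return List::create(
    _["time"] = head(out_t, n_out), _["abp"] = head(out_abp, n_out),
    _["cvp"] = head(out_cvp, n_out), _["co"] = head(out_co, n_out),
    _["hr"] = head(out_hr, n_out), _["contract"] = head(out_ct, n_out),
    _["resist_scale"] = head(out_rs, n_out), _["dvu"] = head(out_dvu, n_out),
    _["sumV_start"] = sumV_start, _["max_drift"] = max_drift,
    _["minV"] = minV, _["V_final"] = Vfin, _["P_final"] = Pfin,
    _["error"] = err);
}
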