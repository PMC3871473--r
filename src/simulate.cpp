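#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state lumped model: LV volume (mL) and arterial Windkessel pressure
// (mmHg). Pressures in mmHg, volumes in mL, flows in mL/s, time in s.

struct EwkParams {
  double period;      // cardiac cycle length (s)
  double t_sys_frac;  // fraction of cycle in systolic activation
  double tau_peak;    // peak of activation as fraction of t_sys_frac
  double e_max, e_min, v0;
  double r_valve, r_char, r_periph, c_art, p_ven, r_mitral;
  double regurg_frac;
};

// Double-cosine activation: 0 -> 1 over [0, t_pk], 1 -> 0 over
// [t_pk, t_sys_frac], 0 in diastole. Continuous and periodic.
static inline double activation(double phase, const EwkParams& p) {
  double t_end = p.t_sys_frac;
  double t_pk = p.t_sys_frac * p.tau_peak;
  if (phase < t_pk) return 0.5 * (1.0 - std::cos(M_PI * phase / t_pk));
  if (phase < t_end)
    return 0.5 * (1.0 + std::cos(M_PI * (phase - t_pk) / (t_end - t_pk)));
  return 0.0;
}

struct Flows {
  double p_lv, p_ao, q_ao, q_mit, q_reg;
};

static inline Flows algebraic(double t, double v, double pa,
                              const EwkParams& p) {
  // fractional cycle phase without fmod (keeps the symbol footprint old)
  double cycles = t / p.period;
  double phase = cycles - std::floor(cycles);
  double E = p.e_min + (p.e_max - p.e_min) * activation(phase, p);
  Flows f;
  f.p_lv = E * (v - p.v0);
  // aortic valve + characteristic resistance in series into the Windkessel
  f.q_ao = f.p_lv > pa ? (f.p_lv - pa) / (p.r_valve + p.r_char) : 0.0;
  f.q_mit = p.p_ven > f.p_lv ? (p.p_ven - f.p_lv) / p.r_mitral : 0.0;
  f.q_reg = (p.regurg_frac > 0.0 && f.p_lv > p.p_ven)
                ? p.regurg_frac * (f.p_lv - p.p_ven) / p.r_mitral
                : 0.0;
  f.p_ao = pa + f.q_ao * p.r_char;  // micromanometer site, distal to valve
  return f;
}

static inline void deriv(double t, double v, double pa, const EwkParams& p,
                         double& dv, double& dpa) {
  Flows f = algebraic(t, v, pa, p);
  dv = f.q_mit - f.q_ao - f.q_reg;
  dpa = (f.q_ao - (pa - p.p_ven) / p.r_periph) / p.c_art;
}

// Fixed-step RK4 from t0 over n_steps of size dt. When record = true the
// state and algebraic outputs are sampled at t0 + i*dt for i in [0, n_steps).
// [[Rcpp::export(name = ".simulate_ewk")]]
List simulate_ewk(double t0, double v_init, double pa_init, int n_steps,
                  double dt, List pars, bool record) {
  EwkParams p;
  p.period = as<double>(pars["period"]);
  p.t_sys_frac = as<double>(pars["t_sys_frac"]);
  p.tau_peak = as<double>(pars["tau_peak"]);
  p.e_max = as<double>(pars["e_max"]);
  p.e_min = as<double>(pars["e_min"]);
  p.v0 = as<double>(pars["v0"]);
  p.r_valve = as<double>(pars["r_valve_ao"]);
  p.r_char = as<double>(pars["r_char"]);
  p.r_periph = as<double>(pars["r_periph"]);
  p.c_art = as<double>(pars["c_art"]);
  p.p_ven = as<double>(pars["p_ven"]);
  p.r_mitral = as<double>(pars["r_mitral"]);
  p.regurg_frac = as<double>(pars["regurg_frac"]);

  NumericMatrix out(record ? n_steps : 0, 6);
  double v = v_init, pa = pa_init, t = t0;
  double k1v, k1p, k2v, k2p, k3v, k3p, k4v, k4p;

  for (int i = 0; i < n_steps; ++i) {
    if (record) {
      Flows f = algebraic(t, v, pa, p);
      out(i, 0) = f.p_lv;
      out(i, 1) = f.p_ao;
      out(i, 2) = f.q_ao;
      out(i, 3) = f.q_mit;
      out(i, 4) = f.q_reg;
      out(i, 5) = v;
    }
    deriv(t, v, pa, p, k1v, k1p);
    deriv(t + dt / 2, v + dt / 2 * k1v, pa + dt / 2 * k1p, p, k2v, k2p);
    deriv(t + dt / 2, v + dt / 2 * k2v, pa + dt / 2 * k2p, p, k3v, k3p);
    deriv(t + dt, v + dt * k3v, pa + dt * k3p, p, k4v, k4p);
    v += dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v);
    pa += dt / 6 * (k1p + 2 * k2p + 2 * k3p + k4p);
    t = t0 + (i + 1) * dt;
    if (!std::isfinite(v) || !std::isfinite(pa))
      stop("simulation error: non-finite state (check resistances/compliance)");
    if (v < -1e-9)
      stop("simulation error: negative ventricular volume (check v0/p_ven)");
  }

  if (record) {
    colnames(out) = CharacterVector::create("p_lv", "p_ao", "q_ao_mls",
                                            "q_mit_mls", "q_reg_mls", "v_lv");
  }
  return List::create(_["out"] = out, _["v_end"] = v, _["pa_end"] = pa,
                      _["t_end"] = t);
}
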