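#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step forward-Euler integrators for every model in the package.
// The R level owns model construction, protocols and analysis; these loops
// only advance state. All times in ms, voltages in mV.

namespace {

// piecewise-linear function: continuous through knots, outer slopes beyond.
struct PLFun {
  std::vector<double> kx, ky, seg_a; // seg_a[i]: slope on (kx[i], kx[i+1]]
  double sl, sr;
  void init(const List& spec) {
    NumericVector x = spec["knots_x"], y = spec["knots_y"];
    kx.assign(x.begin(), x.end());
    ky.assign(y.begin(), y.end());
    sl = as<double>(spec["left_slope"]);
    sr = as<double>(spec["right_slope"]);
    seg_a.resize(kx.size() > 1 ? kx.size() - 1 : 0);
    for (size_t i = 0; i + 1 < kx.size(); ++i)
      seg_a[i] = (ky[i + 1] - ky[i]) / (kx[i + 1] - kx[i]);
  }
  double eval(double x) const {
    const size_t n = kx.size();
    if (!std::isfinite(x)) return std::numeric_limits<double>::quiet_NaN();
    if (x <= kx[0]) return ky[0] + sl * (x - kx[0]);
    if (x > kx[n - 1]) return ky[n - 1] + sr * (x - kx[n - 1]);
    size_t i = 0;
    while (i + 1 < n && x > kx[i + 1]) ++i;
    return ky[i] + seg_a[i] * (x - kx[i]);
  }
};

// step function with midpoint rule at thresholds
struct StepFun {
  std::vector<double> thr, lev;
  void init(const List& spec) {
    NumericVector t = spec["thresholds"], l = spec["levels"];
    thr.assign(t.begin(), t.end());
    lev.assign(l.begin(), l.end());
  }
  double eval(double x) const {
    for (size_t i = 0; i < thr.size(); ++i) {
      if (x < thr[i]) return lev[i];
      if (x == thr[i]) return 0.5 * (lev[i] + lev[i + 1]);
    }
    return lev[thr.size()];
  }
};

inline double xexpm1(double z) { // z / (exp(z) - 1), stable through z = 0
  if (std::fabs(z) < 1e-7) return 1.0 - z / 2.0;
  return z / std::expm1(z);
}

// Wang-Buzsaki rate functions (standard published forms); v in mV, rates 1/ms
inline double wb_am(double v) { return xexpm1(-0.1 * (v + 35.0)); }
inline double wb_bm(double v) { return 4.0 * std::exp(-(v + 60.0) / 18.0); }
inline double wb_ah(double v) { return 0.07 * std::exp(-(v + 58.0) / 20.0); }
inline double wb_bh(double v) { return 1.0 / (std::exp(-0.1 * (v + 28.0)) + 1.0); }
inline double wb_an(double v) { return 0.1 * xexpm1(-0.1 * (v + 34.0)); }
inline double wb_bn(double v) { return 0.125 * std::exp(-(v + 44.0) / 80.0); }

inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

inline double polyval(const NumericVector& c, double v) {
  // coefficients in increasing powers
  double acc = 0.0;
  for (int i = c.size() - 1; i >= 0; --i) acc = acc * v + c[i];
  return acc;
}

void check_finite(double v, double t) {
  if (!std::isfinite(v))
    stop("simulation diverged: non-finite voltage at t = %f ms", t);
}

} // namespace

// Simulate the Wang-Buzsaki model (full or with approximated gating curves).
// route: 0 exact rates, 1 lookup table, 2 polynomial fits, 3 piecewise-linear
// fits. Gating ODEs advance as dx/dt = (x_inf - x)/tau_eff with tau_eff
// already including the rate scale phi. Approximated steady states are
// clamped to [0,1] and approximated taus floored at 0.01 ms (numerical
// guards; the exact route needs neither). Returns a strided trace matrix
// (t, v, h, n) with the count of tiny gating clips as an attribute.
// [[Rcpp::export]]
NumericMatrix sim_wbm_cpp(NumericVector Iv, double dt, NumericVector init,
                          int route, List approx, List params, int stride) {
  const int n_steps = Iv.size();
  const double c = params["c"], gl = params["g_l"], gna = params["g_Na"],
               gk = params["g_K"], El = params["E_l"], Ena = params["E_Na"],
               Ek = params["E_K"], phi = params["phi"];
  double v = init[0], h = init[1], n = init[2];

  // lookup-table route
  double tb_vmin = 0, tb_off = 0;
  int tb_rows = 0;
  NumericMatrix tb;
  // polynomial route
  NumericVector c_minf, c_hinf, c_ninf, c_tauh, c_taun;
  // piecewise-linear route
  PLFun pl_minf, pl_hinf, pl_ninf, pl_tauh, pl_taun;
  if (route == 1) {
    tb = as<NumericMatrix>(approx["values"]);
    tb_vmin = as<double>(approx["v_min"]);
    tb_off = as<double>(approx["row_offset"]);
    tb_rows = as<int>(approx["n_rows"]);
  } else if (route == 2) {
    c_minf = as<NumericVector>(approx["m_inf"]);
    c_hinf = as<NumericVector>(approx["h_inf"]);
    c_ninf = as<NumericVector>(approx["n_inf"]);
    c_tauh = as<NumericVector>(approx["tau_h"]);
    c_taun = as<NumericVector>(approx["tau_n"]);
  } else if (route == 3) {
    pl_minf.init(approx["m_inf"]);
    pl_hinf.init(approx["h_inf"]);
    pl_ninf.init(approx["n_inf"]);
    pl_tauh.init(approx["tau_h"]);
    pl_taun.init(approx["tau_n"]);
  }

  const int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, 4);
  int rec = 0;
  long clips = 0;

  for (int i = 0; i < n_steps; ++i) {
    if (i % stride == 0 && rec < n_rec) {
      out(rec, 0) = i * dt; out(rec, 1) = v; out(rec, 2) = h; out(rec, 3) = n;
      ++rec;
    }
    double minf, hinf, ninf, tauh, taun;
    if (route == 0) {
      const double am = wb_am(v), bm = wb_bm(v), ah = wb_ah(v), bh = wb_bh(v),
                   an = wb_an(v), bn = wb_bn(v);
      minf = am / (am + bm);
      hinf = ah / (ah + bh);
      ninf = an / (an + bn);
      tauh = 1.0 / (phi * (ah + bh));
      taun = 1.0 / (phi * (an + bn));
    } else if (route == 1) {
      double u = (v - tb_vmin) / tb_off;
      int idx = (int)std::floor(u);
      if (idx < 0) idx = 0;
      if (idx > tb_rows - 1) idx = tb_rows - 1;
      double w = u - idx;
      if (w < 0) w = 0; if (w > 1) w = 1; // constant extrapolation
      minf = tb(idx, 0) + w * (tb(idx + 1, 0) - tb(idx, 0));
      hinf = tb(idx, 1) + w * (tb(idx + 1, 1) - tb(idx, 1));
      ninf = tb(idx, 2) + w * (tb(idx + 1, 2) - tb(idx, 2));
      tauh = tb(idx, 3) + w * (tb(idx + 1, 3) - tb(idx, 3));
      taun = tb(idx, 4) + w * (tb(idx + 1, 4) - tb(idx, 4));
    } else if (route == 2) {
      minf = clamp01(polyval(c_minf, v));
      hinf = clamp01(polyval(c_hinf, v));
      ninf = clamp01(polyval(c_ninf, v));
      tauh = std::max(0.01, polyval(c_tauh, v));
      taun = std::max(0.01, polyval(c_taun, v));
    } else {
      minf = clamp01(pl_minf.eval(v));
      hinf = clamp01(pl_hinf.eval(v));
      ninf = clamp01(pl_ninf.eval(v));
      tauh = std::max(0.01, pl_tauh.eval(v));
      taun = std::max(0.01, pl_taun.eval(v));
    }
    const double n4 = n * n * n * n;
    const double dv = (Iv[i] + gl * (El - v) + gk * n4 * (Ek - v) +
                       gna * minf * minf * minf * h * (Ena - v)) / c;
    const double dh = (hinf - h) / tauh;
    const double dn = (ninf - n) / taun;
    v += dt * dv; h += dt * dh; n += dt * dn;
    // clip only sub-1e-9 numerical overshoot of gating bounds
    if (h < 0 && h > -1e-9) { h = 0; ++clips; }
    if (h > 1 && h < 1 + 1e-9) { h = 1; ++clips; }
    if (n < 0 && n > -1e-9) { n = 0; ++clips; }
    if (n > 1 && n < 1 + 1e-9) { n = 1; ++clips; }
    if ((i & 255) == 0) check_finite(v, i * dt);
  }
  check_finite(v, n_steps * dt);
  out.attr("clips") = (double)clips;
  out.attr("n_recorded") = rec;
  return out;
}

// 2D Rinzel-reduced Wang-Buzsaki system: h replaced by eps + kappa * n.
// [[Rcpp::export]]
NumericMatrix sim_reduced_cpp(NumericVector Iv, double dt, NumericVector init,
                              double eps, double kappa, List params, int stride) {
  const int n_steps = Iv.size();
  const double c = params["c"], gl = params["g_l"], gna = params["g_Na"],
               gk = params["g_K"], El = params["E_l"], Ena = params["E_Na"],
               Ek = params["E_K"], phi = params["phi"];
  double v = init[0], n = init[1];
  const int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, 3);
  int rec = 0;
  for (int i = 0; i < n_steps; ++i) {
    if (i % stride == 0 && rec < n_rec) {
      out(rec, 0) = i * dt; out(rec, 1) = v; out(rec, 2) = n; ++rec;
    }
    const double am = wb_am(v), bm = wb_bm(v), an = wb_an(v), bn = wb_bn(v);
    const double minf = am / (am + bm);
    const double ninf = an / (an + bn);
    const double taun = 1.0 / (phi * (an + bn));
    const double hh = eps + kappa * n;
    const double n4 = n * n * n * n;
    const double dv = (Iv[i] + gl * (El - v) + gk * n4 * (Ek - v) +
                       gna * minf * minf * minf * hh * (Ena - v)) / c;
    v += dt * dv;
    n += dt * (ninf - n) / taun;
    if ((i & 255) == 0) check_finite(v, i * dt);
  }
  check_finite(v, n_steps * dt);
  out.attr("n_recorded") = rec;
  return out;
}

// 2D polynomial/piecewise-linear reduction:
//   tau_v(v) * dv/dt = I - I0 + a0 (v - v0)^2 (v1 - v) * Lfac(v) + gK n^4 (EK - v)
//   tau_n(v) * dn/dt = n_inf(v) - n
// Lfac is 1 for v > v0 and 1 + s (v - v0) below (the left-branch steepener;
// its knot at the cubic's double root leaves the right-hand side smooth).
// [[Rcpp::export]]
NumericMatrix sim_pl2d_cpp(NumericVector Iv, double dt, NumericVector init,
                           List q, int stride) {
  const int n_steps = Iv.size();
  const double I0 = q["I0"], a0 = q["a0"], v0 = q["v0"], v1 = q["v1"],
               s = q["lfac_slope"], gk = q["g_K"], Ek = q["E_K"];
  PLFun tau_v, n_inf, tau_n;
  tau_v.init(q["tau_v"]);
  n_inf.init(q["n_inf"]);
  tau_n.init(q["tau_n"]);
  double v = init[0], n = init[1];
  const int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, 3);
  int rec = 0;
  for (int i = 0; i < n_steps; ++i) {
    if (i % stride == 0 && rec < n_rec) {
      out(rec, 0) = i * dt; out(rec, 1) = v; out(rec, 2) = n; ++rec;
    }
    const double lfac = v <= v0 ? 1.0 + s * (v - v0) : 1.0;
    const double cubic = a0 * (v - v0) * (v - v0) * (v1 - v) * lfac;
    const double n4 = n * n * n * n;
    const double dv = (Iv[i] - I0 + cubic + gk * n4 * (Ek - v)) / tau_v.eval(v);
    const double dn = (n_inf.eval(v) - n) / tau_n.eval(v);
    v += dt * dv; n += dt * dn;
    if ((i & 255) == 0) check_finite(v, i * dt);
  }
  check_finite(v, n_steps * dt);
  out.attr("n_recorded") = rec;
  return out;
}

namespace {

struct SynState {
  bool on = false;
  double gampa = 0, gnmda = 0, esyn = 0, tampa = 2, tn1 = 1, tn2 = 200, mg = 1;
  double sa = 0, an = 0, bn = 0;
  const int* counts = nullptr;
  void init(SEXP syn) {
    if (Rf_isNull(syn)) return;
    List s(syn);
    on = true;
    gampa = as<double>(s["g_ampa"]);
    gnmda = as<double>(s["g_nmda"]);
    esyn = as<double>(s["E_syn"]);
    tampa = as<double>(s["tau_ampa"]);
    tn1 = as<double>(s["tau_nmda1"]);
    tn2 = as<double>(s["tau_nmda2"]);
    mg = as<double>(s["Mg"]);
    counts_vec = as<IntegerVector>(s["counts"]);
    counts = INTEGER(counts_vec);
  }
  IntegerVector counts_vec;
  double current(double v, int step, double dt) {
    if (!on) return 0.0;
    if (counts[step] > 0) {
      sa += counts[step]; an += counts[step]; bn += counts[step];
    }
    const double block = 1.0 + mg * std::exp(-0.062 * v) / 3.57;
    const double I = gampa * sa * (esyn - v) +
                     gnmda * (bn - an) * (esyn - v) / block;
    sa -= dt * sa / tampa;
    an -= dt * an / tn1;
    bn -= dt * bn / tn2;
    return I;
  }
};

} // namespace

// Phenomenological 2D models. type 1: cubic with three roots (integrator);
// type 2: cubic with a double root at v0 (resonator).
//   tau_v(v) dv/dt = P(v) * Lfac(v) + I + Isyn - w^k
//   tau_w(v) dw/dt = w_inf(v) - w
// [[Rcpp::export]]
NumericMatrix sim_pheno_cpp(NumericVector Iv, double dt, NumericVector init,
                            List m, int stride, SEXP syn) {
  const int n_steps = Iv.size();
  const int type = as<int>(m["type"]);
  const double v0 = m["v0"], v2 = m["v2"], a0 = m["a0"], a1 = m["a1"],
               v3 = m["v3"], r0 = m["r0"], r1 = m["r1"],
               v4 = m["v4"], v5 = m["v5"], v6 = m["v6"], v7 = m["v7"],
               s0 = m["s0"], s1 = m["s1"], s2 = m["s2"];
  const int k = as<int>(m["k"]);
  const double v1 = (type == 1) ? as<double>(m["v1"]) : 0.0;
  const double wslope = 1.0 / (v5 - v4);
  SynState synst;
  synst.init(syn);

  double v = init[0], w = init[1];
  const int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, 3);
  int rec = 0;
  for (int i = 0; i < n_steps; ++i) {
    if (i % stride == 0 && rec < n_rec) {
      out(rec, 0) = i * dt; out(rec, 1) = v; out(rec, 2) = w; ++rec;
    }
    const double isyn = synst.current(v, i, dt);
    const double lfac = v <= v0 ? a0 + a1 * (v - v0) : a0;
    double P;
    if (type == 1) P = (v0 - v) * (v1 - v) * (v2 - v);
    else           P = (v0 - v) * (v0 - v) * (v2 - v);
    double wk = w;
    for (int j = 1; j < k; ++j) wk *= w;
    const double tauv = v <= v3 ? r0 + r1 * (v - v3) : r0;
    double winf = (v - v4) * wslope;
    winf = clamp01(winf);
    const double tauw = v < v6 ? s0 : (v == v6 ? 0.5 * (s0 + s1)
                        : (v < v7 ? s1 : (v == v7 ? 0.5 * (s1 + s2) : s2)));
    const double dv = (P * lfac + Iv[i] + isyn - wk) / tauv;
    const double dw = (winf - w) / tauw;
    v += dt * dv; w += dt * dw;
    if ((i & 255) == 0) check_finite(v, i * dt);
  }
  check_finite(v, n_steps * dt);
  out.attr("n_recorded") = rec;
  return out;
}

// Izhikevich hybrid model (quadratic voltage, linear slow variable, hard
// reset at +30 mV): baseline for the plateau-potential contrast experiment.
// [[Rcpp::export]]
NumericMatrix sim_izhi_cpp(NumericVector Iv, double dt, NumericVector init,
                           List m, int stride, SEXP syn) {
  const int n_steps = Iv.size();
  const double a = m["a"], b = m["b"], cr = m["c"], d = m["d"];
  SynState synst;
  synst.init(syn);
  double v = init[0], u = init[1];
  const int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, 3);
  int rec = 0;
  for (int i = 0; i < n_steps; ++i) {
    if (i % stride == 0 && rec < n_rec) {
      out(rec, 0) = i * dt; out(rec, 1) = v; out(rec, 2) = u; ++rec;
    }
    const double isyn = synst.current(v, i, dt);
    const double dv = 0.04 * v * v + 5.0 * v + 140.0 - u + Iv[i] + isyn;
    const double du = a * (b * v - u);
    v += dt * dv; u += dt * du;
    if (v >= 30.0) { v = cr; u += d; }
    if ((i & 255) == 0) check_finite(v, i * dt);
  }
  check_finite(v, n_steps * dt);
  out.attr("n_recorded") = rec;
  return out;
}
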