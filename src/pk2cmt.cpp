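#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Macro-constant reparameterization of the two-compartment model.
// k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp; (alpha, beta) are the roots of
// s^2 - (k10+k12+k21) s + k10 k21 = 0 with alpha >= beta.
struct Macro {
  double la, lb;  // alpha, beta
  double Aa, Ab;  // unit-bolus central coefficients
};

static Macro macro_coefs(double cl, double q, double v1, double v2) {
  double k10 = cl / v1, k12 = q / v1, k21 = q / v2;
  double s = k10 + k12 + k21, p = k10 * k21;
  double disc2 = s * s - 4.0 * p;
  double disc = disc2 > 0.0 ? std::sqrt(disc2) : 0.0;
  Macro m;
  m.la = 0.5 * (s + disc);
  m.lb = 0.5 * (s - disc);
  // Near-repeated roots: clamp the relative gap at 1e-9 so the partial
  // fraction coefficients stay finite (equivalent to the series limit to
  // within ~1e-9 relative).
  if (m.la - m.lb < 1e-9 * m.la) m.lb = m.la * (1.0 - 1e-9);
  double gap = m.la - m.lb;
  m.Aa = (m.la - k21) / (v1 * gap);
  m.Ab = (k21 - m.lb) / (v1 * gap);
  return m;
}

// Central concentration contribution of one zero-order infusion
// (amount amt over duration T starting at elapsed time 0), evaluated at
// elapsed time te > 0. T <= 0 is treated as a bolus.
static inline double one_dose(double te, double amt, double T, const Macro& m) {
  if (te <= 0.0) return 0.0;
  if (T <= 0.0) {
    return amt * (m.Aa * std::exp(-m.la * te) + m.Ab * std::exp(-m.lb * te));
  }
  double R = amt / T;
  double t1 = te < T ? te : T;          // time infused so far
  double t2 = te > T ? te - T : 0.0;    // decay time since infusion end
  double ga = (m.la > 0.0) ? -std::expm1(-m.la * t1) / m.la : t1;
  double gb = (m.lb > 0.0) ? -std::expm1(-m.lb * t1) / m.lb : t1;
  return R * (m.Aa * ga * std::exp(-m.la * t2) +
              m.Ab * gb * std::exp(-m.lb * t2));
}

static double conc_at(double t, const double* dt, const double* da,
                      const double* dd, int nd, const Macro& m) {
  double c = 0.0;
  for (int d = 0; d < nd; ++d) c += one_dose(t - dt[d], da[d], dd[d], m);
  return c > 0.0 ? c : 0.0;
}

// [[Rcpp::export]]
NumericVector conc2cmt_cpp(NumericVector t, NumericVector dose_t,
                           NumericVector dose_amt, NumericVector dose_dur,
                           double cl, double q, double v1, double v2) {
  Macro m = macro_coefs(cl, q, v1, v2);
  int nt = t.size(), nd = dose_t.size();
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i)
    out[i] = conc_at(t[i], dose_t.begin(), dose_amt.begin(),
                     dose_dur.begin(), nd, m);
  return out;
}

struct Subj {
  const double *y, *t, *dt, *da, *dd;
  int n, nd;
  double cl_pop, q, v1, v2, sa2, sp2, w;  // w = 1/omega^2 penalty weight
};

// Penalized conditional -2 log-likelihood in eta (the FOCE-I inner
// objective): sum_j [log v_j + (y_j - f_j)^2 / v_j] + eta^2 / omega^2,
// with v_j evaluated at the conditional prediction (interaction).
static double h_eta(double eta, const Subj& s, std::vector<double>* fout) {
  Macro m = macro_coefs(s.cl_pop * std::exp(eta), s.q, s.v1, s.v2);
  double h = s.w * eta * eta;
  for (int j = 0; j < s.n; ++j) {
    double f = conc_at(s.t[j], s.dt, s.da, s.dd, s.nd, m);
    double v = s.sa2 + s.sp2 * f * f;
    if (v < 1e-12) v = 1e-12;
    double r = s.y[j] - f;
    h += std::log(v) + r * r / v;
    if (fout) (*fout)[j] = f;
  }
  return h;
}

// Brent's localmin on [a, b] (derivative-free scalar minimizer).
static double brent_min(const Subj& s, double a, double b, double tol) {
  const double gold = 0.3819660112501051;
  double x, w, v, fx, fw, fv, d = 0.0, e = 0.0;
  x = w = v = a + gold * (b - a);
  fx = fw = fv = h_eta(x, s, nullptr);
  for (int iter = 0; iter < 200; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-12;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double qq = (x - v) * (fx - fw);
      double pp = (x - v) * qq - (x - w) * r;
      qq = 2.0 * (qq - r);
      if (qq > 0.0) pp = -pp;
      qq = std::fabs(qq);
      double etemp = e;
      e = d;
      if (std::fabs(pp) < std::fabs(0.5 * qq * etemp) &&
          pp > qq * (a - x) && pp < qq * (b - x)) {
        d = pp / qq;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = h_eta(u, s, nullptr);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

// Core FOCE-I computation for one subject; shared by the one-subject and
// whole-population entry points.
static double foce_core(Subj& s, double omega2, bool flat, double* eta_out,
                        double* f_out, double* g_out, double* v_out) {
  double eta = 0.0;
  if (omega2 > 0.0) {
    s.w = flat ? 0.0 : 1.0 / omega2;
    eta = brent_min(s, -7.0, 7.0, 1e-10);
  } else {
    s.w = 0.0;
  }
  std::vector<double> f(s.n), fp(s.n), fm(s.n);
  h_eta(eta, s, &f);
  const double heps = 1e-4;
  h_eta(eta + heps, s, &fp);
  h_eta(eta - heps, s, &fm);

  double sum_logv = 0.0, q_rr = 0.0, q_gr = 0.0, q_gg = 0.0, dev0 = 0.0;
  for (int j = 0; j < s.n; ++j) {
    double g = (fp[j] - fm[j]) / (2.0 * heps);
    double v = s.sa2 + s.sp2 * f[j] * f[j];
    if (v < 1e-12) v = 1e-12;
    double r = s.y[j] - f[j] + g * eta;  // linearized population residual
    sum_logv += std::log(v);
    q_rr += r * r / v;
    q_gr += g * r / v;
    q_gg += g * g / v;
    dev0 += (s.y[j] - f[j]) * (s.y[j] - f[j]) / v;
    if (f_out) f_out[j] = f[j];
    if (g_out) g_out[j] = g;
    if (v_out) v_out[j] = v;
  }
  const double l2pi = std::log(2.0 * M_PI);
  double ofv;
  if (omega2 > 0.0 && !flat) {
    double den = 1.0 + omega2 * q_gg;
    ofv = sum_logv + std::log(den) + q_rr - omega2 * q_gr * q_gr / den +
          s.n * l2pi;
  } else {
    // omega2 == 0 (pure fixed-effects deviance) or flat prior
    // (conditional deviance at the mode; not a marginal likelihood).
    ofv = sum_logv + dev0 + s.n * l2pi;
  }
  if (eta_out) *eta_out = eta;
  return ofv;
}

// FOCE-I contribution of one subject. omega2 may be 0 (eta fixed at 0,
// fixed-effects deviance), a positive variance, or +Inf (flat prior;
// penalized term dropped -- used by the MAP module's flat-prior limit).
// Returns the -2 log marginal likelihood contribution (including the
// n log 2 pi constant so it is comparable with numerical integration),
// the conditional mode eta, conditional predictions f, the sensitivity
// G = df/deta at the mode, and the residual variances v.
// [[Rcpp::export]]
List foce_subject_cpp(NumericVector y, NumericVector t, NumericVector dose_t,
                      NumericVector dose_amt, NumericVector dose_dur,
                      double cl_pop, double q, double v1, double v2,
                      double omega2, double sigma_add, double sigma_prop) {
  Subj s;
  s.y = y.begin(); s.t = t.begin();
  s.dt = dose_t.begin(); s.da = dose_amt.begin(); s.dd = dose_dur.begin();
  s.n = y.size(); s.nd = dose_t.size();
  s.cl_pop = cl_pop; s.q = q; s.v1 = v1; s.v2 = v2;
  s.sa2 = sigma_add * sigma_add; s.sp2 = sigma_prop * sigma_prop;

  bool flat = !R_finite(omega2);
  NumericVector fv(s.n), gv(s.n), vv(s.n);
  double eta;
  double ofv = foce_core(s, omega2, flat, &eta, fv.begin(), gv.begin(),
                         vv.begin());
  return List::create(_["ofv"] = ofv, _["eta"] = eta, _["f"] = fv,
                      _["g"] = gv, _["v"] = vv);
}

// Whole-population FOCE-I objective over flattened per-subject arrays.
// obs_start / dose_start are 0-based offsets of length n_subjects + 1.
// Returns the summed objective (Inf when any subject's contribution is
// non-finite) and the per-subject conditional modes.
// [[Rcpp::export]]
List foce_pop_cpp(NumericVector y, NumericVector t, IntegerVector obs_start,
                  NumericVector dose_t, NumericVector dose_amt,
                  NumericVector dose_dur, IntegerVector dose_start,
                  NumericVector cl_pop, NumericVector vc_pop,
                  double q, double vp, double omega2,
                  double sigma_add, double sigma_prop) {
  int ns = obs_start.size() - 1;
  if (cl_pop.size() != ns || vc_pop.size() != ns)
    stop("cl_pop/vc_pop must have one entry per subject");
  bool flat = !R_finite(omega2);
  NumericVector etas(ns);
  double total = 0.0;
  bool ok = true;
  for (int i = 0; i < ns && ok; ++i) {
    Subj s;
    s.y = y.begin() + obs_start[i];
    s.t = t.begin() + obs_start[i];
    s.n = obs_start[i + 1] - obs_start[i];
    s.dt = dose_t.begin() + dose_start[i];
    s.da = dose_amt.begin() + dose_start[i];
    s.dd = dose_dur.begin() + dose_start[i];
    s.nd = dose_start[i + 1] - dose_start[i];
    s.cl_pop = cl_pop[i]; s.q = q; s.v1 = vc_pop[i]; s.v2 = vp;
    s.sa2 = sigma_add * sigma_add; s.sp2 = sigma_prop * sigma_prop;
    double eta;
    double ofv = foce_core(s, omega2, flat, &eta, nullptr, nullptr,
                           nullptr);
    if (!R_finite(ofv)) ok = false;
    etas[i] = eta;
    total += ofv;
  }
  return List::create(_["ofv"] = ok ? total : R_PosInf, _["eta"] = etas);
}
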