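// Laplace-approximated marginal likelihoods for per-taxon count GLMMs
// (negative binomial, zero-truncated NB, Bernoulli, zero-inflated NB) with a
// single random intercept per grouping factor.  The inner optimisation over
// each group's random intercept is a safeguarded 1-D Newton; the outer
// parameters are optimised from R via optim() calling these objectives.

#include <Rcpp.h>
using namespace Rcpp;

// family codes
static const int FAM_NB = 0;
static const int FAM_BERN = 1;
static const int FAM_TRUNCNB = 2;
static const int FAM_ZINB = 3;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Per-evaluation caches: the log-gamma part of the NB pmf depends only on
// (z, theta), which are fixed while the group modes are optimised, so it is
// precomputed once per objective evaluation (single-threaded use).
static std::vector<double> g_lgc;
static double g_lth = 0.0;

// NB log-pmf via log-gamma; stable for large z and theta.
static inline double nb_lp(double z, double mu, double th) {
  double lmth = std::log(mu + th);
  return R::lgammafn(z + th) - R::lgammafn(th) - R::lgammafn(z + 1.0) +
         th * (std::log(th) - lmth) + (z > 0.0 ? z * (std::log(mu) - lmth) : 0.0);
}

// Unit log-likelihood and its first two derivatives w.r.t. eta (the linear
// predictor on the link scale: log mu for counts, logit p for Bernoulli).
// phi is the zero-inflation probability (ZINB only; constant in eta).
static inline void unit_ll_i(int family, int i, double z, double eta,
                             double th, double phi, double &l, double &d1,
                             double &d2) {
  if (family == FAM_BERN) {
    // z in {0,1}, p = plogis(eta)
    double p = 1.0 / (1.0 + std::exp(-clampd(eta, -35.0, 35.0)));
    p = clampd(p, 1e-12, 1.0 - 1e-12);
    l = z > 0.5 ? std::log(p) : std::log1p(-p);
    d1 = z - p;
    d2 = -p * (1.0 - p);
    return;
  }
  double mu = std::exp(clampd(eta, -35.0, 35.0));
  mu = clampd(mu, 1e-12, 1e12);
  double lmth = std::log(mu + th);
  double u = mu / (mu + th);          // in (0,1)
  double nb_l = g_lgc[i] + th * (g_lth - lmth) +
                (z > 0.0 ? z * (std::log(mu) - lmth) : 0.0);
  double nb_d1 = (z - mu) * th / (mu + th);
  double nb_d2 = -(z + th) * mu * th / ((mu + th) * (mu + th));
  if (family == FAM_NB) {
    l = nb_l;
    d1 = nb_d1; d2 = nb_d2;
  } else if (family == FAM_TRUNCNB) {
    // zero-truncated NB for z >= 1: l = nb(z) - log(1 - p0)
    double lp0 = th * (g_lth - lmth);
    double p0 = std::exp(lp0);
    p0 = clampd(p0, 0.0, 1.0 - 1e-12);
    double B = p0 / (1.0 - p0);
    l = nb_l - std::log1p(-p0);
    d1 = nb_d1 - th * u * B;
    d2 = nb_d2 - th * u * B * ((1.0 - u) - th * u * (1.0 + B));
  } else { // FAM_ZINB
    if (z > 0.5) {
      l = std::log1p(-phi) + nb_l;
      d1 = nb_d1; d2 = nb_d2;
    } else {
      double lp0 = th * (g_lth - lmth);
      double q = std::exp(lp0);
      double denom = phi + (1.0 - phi) * q;
      denom = clampd(denom, 1e-300, 1.0);
      double s = (1.0 - phi) * q / denom;   // share of the NB zero mass
      l = std::log(denom);
      d1 = -th * u * s;
      d2 = -th * u * s * ((1.0 - u) - th * u * (1.0 - s));
    }
  }
}

// Fill the per-observation lgamma cache for the current theta.
static void fill_lgc(int family, const NumericVector &z, double th) {
  int n = z.size();
  g_lgc.assign(n, 0.0);
  g_lth = std::log(th);
  if (family == FAM_BERN) return;
  double lgth = R::lgammafn(th);
  for (int i = 0; i < n; ++i)
    g_lgc[i] = R::lgammafn(z[i] + th) - lgth - R::lgammafn(z[i] + 1.0);
}

struct ParLayout {
  int p;        // fixed-effect coefficients
  bool has_theta;
  int q;        // zero-model coefficients (ZINB)
  bool has_re;
};

static ParLayout layout(int family, int p, int q, bool has_re) {
  ParLayout L;
  L.p = p;
  L.has_theta = (family == FAM_NB || family == FAM_TRUNCNB || family == FAM_ZINB);
  L.q = (family == FAM_ZINB) ? q : 0;
  L.has_re = has_re;
  return L;
}

// Evaluate per-observation eta0 (fixed part incl. offset) and phi.
static void fill_fixed(const NumericVector &par, const NumericMatrix &X,
                       const NumericVector &offset, const NumericMatrix &Gz,
                       int family, const ParLayout &L,
                       std::vector<double> &eta0, std::vector<double> &phi,
                       double &theta) {
  int n = X.nrow(), p = L.p;
  for (int i = 0; i < n; ++i) {
    double e = offset[i];
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta0[i] = e;
  }
  theta = 1.0;
  int pos = p;
  if (L.has_theta) theta = std::exp(clampd(par[pos++], -12.0, 16.0));
  if (family == FAM_ZINB) {
    for (int i = 0; i < n; ++i) {
      double g = 0.0;
      for (int j = 0; j < L.q; ++j) g += Gz(i, j) * par[pos + j];
      phi[i] = 1.0 / (1.0 + std::exp(-clampd(g, -35.0, 35.0)));
    }
  }
}

// Penalised per-group objective f(b) = sum_i l_i(eta0_i + b) - b^2/(2s2),
// with derivatives; obs index range given by idx vector.
static double group_f(double b, const std::vector<int> &idx,
                      const std::vector<double> &eta0,
                      const std::vector<double> &phi,
                      const NumericVector &z, int family, double theta,
                      double s2, double &g1, double &g2) {
  double f = -b * b / (2.0 * s2);
  g1 = -b / s2;
  g2 = -1.0 / s2;
  double l, d1, d2;
  for (size_t k = 0; k < idx.size(); ++k) {
    int i = idx[k];
    unit_ll_i(family, i, z[i], eta0[i] + b, theta, phi[i], l, d1, d2);
    f += l; g1 += d1; g2 += d2;
  }
  return f;
}

// Warm-start cache for the group modes: successive objective evaluations
// during one outer optimisation differ only slightly, so the previous modes
// are excellent Newton starts.  Reset between model fits.
static std::vector<double> g_warm;

// [[Rcpp::export(name = ".glmmWarmReset")]]
void glmmWarmReset() { g_warm.clear(); }

// Safeguarded Newton for the group mode; returns b-hat, sets curvature H>0.
static double solve_group(const std::vector<int> &idx,
                          const std::vector<double> &eta0,
                          const std::vector<double> &phi,
                          const NumericVector &z, int family, double theta,
                          double s2, double &H, double &fval,
                          double b_init = 0.0) {
  double b = b_init, g1, g2;
  double f = group_f(b, idx, eta0, phi, z, family, theta, s2, g1, g2);
  for (int it = 0; it < 60; ++it) {
    if (std::fabs(g1) < 1e-10 * (1.0 + std::fabs(f))) break;
    double curv = g2;
    if (curv > -1e-8) curv = -(std::fabs(curv) + 1e-4);
    double step = -g1 / curv;
    if (std::fabs(step) > 50.0) step = step > 0 ? 50.0 : -50.0;
    if (std::fabs(step) < 1e-12) break;
    double fnew, ng1, ng2, bnew;
    int halves = 0;
    for (;;) {
      bnew = clampd(b + step, -30.0, 30.0);
      fnew = group_f(bnew, idx, eta0, phi, z, family, theta, s2, ng1, ng2);
      if (fnew >= f - 1e-12 || halves >= 15) break;
      step *= 0.5; ++halves;
    }
    if (fnew < f) break;      // no improvement possible
    b = bnew; f = fnew; g1 = ng1; g2 = ng2;
  }
  H = -g2;
  if (H < 1e-10) H = 1e-10;
  fval = f;
  return b;
}

static void build_index(const IntegerVector &group, int ngroups,
                        std::vector<std::vector<int> > &idx) {
  idx.assign(ngroups, std::vector<int>());
  for (int i = 0; i < group.size(); ++i) idx[group[i]].push_back(i);
}

// Negative marginal log-likelihood (Laplace over random intercepts).
// par = [beta (ncol X) | log_theta (count families) | gamma (ZINB, ncol Gz)
//        | log_sigma2 (if has_re)]
// group: 0-based labels, or length 0 for a pure fixed-effects model.
// [[Rcpp::export(name = ".glmmNll")]]
double glmmNll(NumericVector par, NumericVector z, NumericMatrix X,
               NumericVector offset, IntegerVector group, int ngroups,
               int family, NumericMatrix Gz) {
  bool has_re = group.size() > 0 && ngroups > 0;
  ParLayout L = layout(family, X.ncol(), Gz.ncol(), has_re);
  int n = X.nrow();
  std::vector<double> eta0(n), phi(n, 0.0);
  double theta;
  fill_fixed(par, X, offset, Gz, family, L, eta0, phi, theta);
  fill_lgc(family, z, theta);
  double ll = 0.0;
  if (!has_re) {
    double l, d1, d2;
    for (int i = 0; i < n; ++i) {
      unit_ll_i(family, i, z[i], eta0[i], theta, phi[i], l, d1, d2);
      ll += l;
    }
  } else {
    int pos = L.p + (L.has_theta ? 1 : 0) + L.q;
    double s2 = std::exp(clampd(par[pos], -14.0, 5.0));
    std::vector<std::vector<int> > idx;
    build_index(group, ngroups, idx);
    if ((int) g_warm.size() != ngroups) g_warm.assign(ngroups, 0.0);
    for (int g = 0; g < ngroups; ++g) {
      double H, fval;
      double bhat = solve_group(idx[g], eta0, phi, z, family, theta, s2,
                                H, fval, g_warm[g]);
      g_warm[g] = bhat;
      // marginal contribution: f(b-hat) - 0.5*log(s2*H)
      ll += fval - 0.5 * std::log(s2 * H);
    }
  }
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}

// Third derivative of the unit log-likelihood w.r.t. eta, plus the
// zero-model (gamma) partials for ZINB; used by the analytic gradient.
static void unit_d3(int family, double z, double eta, double th, double phi,
                    double &d3, double &dg, double &d1g, double &d2g) {
  d3 = 0.0; dg = 0.0; d1g = 0.0; d2g = 0.0;
  if (family == FAM_BERN) {
    double p = 1.0 / (1.0 + std::exp(-clampd(eta, -35.0, 35.0)));
    p = clampd(p, 1e-12, 1.0 - 1e-12);
    d3 = -p * (1.0 - p) * (1.0 - 2.0 * p);
    return;
  }
  double mu = std::exp(clampd(eta, -35.0, 35.0));
  mu = clampd(mu, 1e-12, 1e12);
  double mt = mu + th;
  double u = mu / mt, v = th / mt;
  double nb3 = -(z + th) * th * mu * (th - mu) / (mt * mt * mt);
  if (family == FAM_NB) { d3 = nb3; return; }
  if (family == FAM_TRUNCNB) {
    double lp0 = th * (std::log(th) - std::log(mt));
    double p0 = clampd(std::exp(lp0), 0.0, 1.0 - 1e-12);
    double B = p0 / (1.0 - p0);
    double D = v - th * u * (1.0 + B);
    double Dp = -u * v - th * u * (1.0 + B) * (v - th * u * B);
    double App = th * (u * v * B * D - th * u * u * B * (1.0 + B) * D +
                       u * B * Dp);
    d3 = nb3 - App;
    return;
  }
  // FAM_ZINB
  if (z > 0.5) { d3 = nb3; dg = -phi; return; }
  double lp0 = th * (std::log(th) - std::log(mt));
  double q = std::exp(lp0);
  double denom = clampd(phi + (1.0 - phi) * q, 1e-300, 1.0);
  double s = (1.0 - phi) * q / denom;
  double F = v - th * u * (1.0 - s);
  double Fp = -u * v - th * u * (1.0 - s) * (v + th * u * s);
  double Epp = th * (u * v * s * F - th * u * u * s * (1.0 - s) * F +
                     u * s * Fp);
  d3 = -Epp;
  double pp = phi * (1.0 - phi);
  dg = pp * (1.0 - q) / denom;
  double dsdg = -(pp / denom) * (q + s * (1.0 - q));
  d1g = -th * u * dsdg;
  d2g = -th * u * dsdg * (F + th * u * s);
}

// Analytic gradient of the negative Laplace marginal log-likelihood for
// beta, the ZINB gamma, and log sigma2 (envelope theorem plus the implicit
// derivative of the log-determinant correction through the group modes);
// log theta is differenced centrally.
// [[Rcpp::export(name = ".glmmGrad")]]
NumericVector glmmGrad(NumericVector par, NumericVector z, NumericMatrix X,
                       NumericVector offset, IntegerVector group,
                       int ngroups, int family, NumericMatrix Gz) {
  bool has_re = group.size() > 0 && ngroups > 0;
  ParLayout L = layout(family, X.ncol(), Gz.ncol(), has_re);
  int n = X.nrow(), p = L.p, q = L.q;
  int npar = p + (L.has_theta ? 1 : 0) + q + (L.has_re ? 1 : 0);
  NumericVector grad(npar);
  std::vector<double> eta0(n), phi(n, 0.0);
  double theta;
  fill_fixed(par, X, offset, Gz, family, L, eta0, phi, theta);
  fill_lgc(family, z, theta);
  int spos = p + (L.has_theta ? 1 : 0) + q;
  double s2 = has_re ? std::exp(clampd(par[spos], -14.0, 10.0)) : 0.0;

  double l, d1, d2, d3, dg, d1g, d2g;
  if (!has_re) {
    for (int i = 0; i < n; ++i) {
      unit_ll_i(family, i, z[i], eta0[i], theta, phi[i], l, d1, d2);
      unit_d3(family, z[i], eta0[i], theta, phi[i], d3, dg, d1g, d2g);
      for (int j = 0; j < p; ++j) grad[j] -= d1 * X(i, j);
      for (int j = 0; j < q; ++j) grad[p + 1 + j] -= dg * Gz(i, j);
    }
  } else {
    std::vector<std::vector<int> > idx;
    build_index(group, ngroups, idx);
    if ((int) g_warm.size() != ngroups) g_warm.assign(ngroups, 0.0);
    std::vector<double> T2(p), T3(p), T2g(q), T3g(q);
    for (int g = 0; g < ngroups; ++g) {
      double H, fval;
      double bhat = solve_group(idx[g], eta0, phi, z, family, theta, s2,
                                H, fval, g_warm[g]);
      g_warm[g] = bhat;
      std::fill(T2.begin(), T2.end(), 0.0);
      std::fill(T3.begin(), T3.end(), 0.0);
      std::fill(T2g.begin(), T2g.end(), 0.0);
      std::fill(T3g.begin(), T3g.end(), 0.0);
      double P3 = 0.0;
      for (size_t k = 0; k < idx[g].size(); ++k) {
        int i = idx[g][k];
        double eta = eta0[i] + bhat;
        unit_ll_i(family, i, z[i], eta, theta, phi[i], l, d1, d2);
        unit_d3(family, z[i], eta, theta, phi[i], d3, dg, d1g, d2g);
        P3 += d3;
        for (int j = 0; j < p; ++j) {
          grad[j] -= d1 * X(i, j);          // envelope term
          T2[j] += d2 * X(i, j);
          T3[j] += d3 * X(i, j);
        }
        for (int j = 0; j < q; ++j) {
          grad[p + 1 + j] -= dg * Gz(i, j);
          T2g[j] += d1g * Gz(i, j);
          T3g[j] += d2g * Gz(i, j);
        }
      }
      // log-det corrections: dH/dpsi = -T3[psi] - P3 * (T2[psi]/H)
      for (int j = 0; j < p; ++j)
        grad[j] += -(1.0 / (2.0 * H)) * (-T3[j] - P3 * T2[j] / H) * (-1.0);
      for (int j = 0; j < q; ++j)
        grad[p + 1 + j] +=
          -(1.0 / (2.0 * H)) * (-T3g[j] - P3 * T2g[j] / H) * (-1.0);
      // log sigma2 component
      double dHds = -1.0 / s2 - P3 * bhat / (s2 * H);
      double dLds = bhat * bhat / (2.0 * s2) - 0.5 - dHds / (2.0 * H);
      grad[spos] -= dLds;
    }
  }
  if (L.has_theta) {
    double h = 1e-6;
    NumericVector ph(clone(par)), pl(clone(par));
    ph[p] += h; pl[p] -= h;
    double fh = glmmNll(ph, z, X, offset, group, ngroups, family, Gz);
    double fl = glmmNll(pl, z, X, offset, group, ngroups, family, Gz);
    grad[p] = (fh - fl) / (2.0 * h);
  }
  return grad;
}

// Conditional modes of the random intercepts at the given parameters.
// [[Rcpp::export(name = ".glmmModes")]]
NumericVector glmmModes(NumericVector par, NumericVector z, NumericMatrix X,
                        NumericVector offset, IntegerVector group, int ngroups,
                        int family, NumericMatrix Gz) {
  bool has_re = group.size() > 0 && ngroups > 0;
  if (!has_re) return NumericVector(0);
  ParLayout L = layout(family, X.ncol(), Gz.ncol(), has_re);
  int n = X.nrow();
  std::vector<double> eta0(n), phi(n, 0.0);
  double theta;
  fill_fixed(par, X, offset, Gz, family, L, eta0, phi, theta);
  fill_lgc(family, z, theta);
  int pos = L.p + (L.has_theta ? 1 : 0) + L.q;
  double s2 = std::exp(clampd(par[pos], -14.0, 5.0));
  std::vector<std::vector<int> > idx;
  build_index(group, ngroups, idx);
  NumericVector b(ngroups);
  for (int g = 0; g < ngroups; ++g) {
    double H, fval;
    b[g] = solve_group(idx[g], eta0, phi, z, family, theta, s2, H, fval);
  }
  return b;
}
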