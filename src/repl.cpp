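// Restricted pseudo-likelihood (REPL) fitter for a random-intercept
// logistic model with an arm-only covariate.
//
// The linearisation (Wolfinger-O'Connell style, subject-specific expansion)
// iterates an individual-level pseudo-response
//   z_ijk = eta_j + (y_ijk - mu_j) / (mu_j (1 - mu_j)),
// and a REML fit of the linear mixed pseudo-model
//   z = X beta + u + e,  Var(u_j) = sigma_b^2,  Var(e_ijk) = phi / v_j,
// with v_j = mu_j (1 - mu_j). Because the arm covariate is
// cluster-constant, the REML fit depends on the data only through
// per-cluster sufficient statistics: the cluster mean pseudo-response
//   zbar_j = eta_j + (ybar_j - mu_j) / v_j           (weight w_j = m_j v_j)
// and the within-cluster pseudo sum of squares
//   SSW_j = m_j ybar_j (1 - ybar_j) / v_j^2          (m_j - 1 residual df),
// so each cluster costs O(1) regardless of its size. Writing
// sigma_b^2 = phi * gamma and profiling phi leaves a 1-D REML criterion in
// the variance ratio gamma, minimised by grid bracketing + golden-section.
// The within-cluster degrees of freedom anchor the residual scale phi near
// the binomial value 1, which keeps the doubly-iterative algorithm stable.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct RemlFit {
  double beta0, beta1, phi, gamma, a11, a12, det;
};

// profiled REML criterion for variance ratio gamma; X = [1, arm].
// qw = sum_j v_j * SSW_j (within-cluster quadratic form in phi units),
// ntot = total number of individuals.
double reml_crit(double gamma, const std::vector<double>& zbar,
                 const std::vector<double>& invw, const IntegerVector& arm,
                 double qw, double ntot, RemlFit* out) {
  const int n = zbar.size();
  double a11 = 0, a12 = 0, b1 = 0, b2 = 0;
  double sumlogd = 0;
  std::vector<double> d(n);
  for (int j = 0; j < n; ++j) {
    d[j] = gamma + invw[j];
    sumlogd += std::log(d[j]);
    const double id = 1.0 / d[j];
    a11 += id;
    b1 += zbar[j] * id;
    if (arm[j]) { a12 += id; b2 += zbar[j] * id; }
  }
  const double det = a12 * (a11 - a12);
  if (det <= 0 || !R_finite(det)) return R_PosInf;
  const double beta1 = (a11 * b2 - a12 * b1) / det;
  const double beta0 = (b1 - a12 * beta1) / a11;
  double q = qw;
  for (int j = 0; j < n; ++j) {
    const double r = zbar[j] - beta0 - (arm[j] ? beta1 : 0.0);
    q += r * r / d[j];
  }
  double phi = q / (ntot - 2);
  if (phi < 1e-300) phi = 1e-300;
  if (out) {
    out->beta0 = beta0; out->beta1 = beta1; out->phi = phi;
    out->gamma = gamma; out->a11 = a11; out->a12 = a12; out->det = det;
  }
  return (ntot - 2) * std::log(phi) + sumlogd + std::log(det);
}

// minimise the REML criterion: coarse grid (incl. the gamma = 0 boundary)
// then golden-section refinement between the grid neighbours of the best
RemlFit reml_solve(const std::vector<double>& zbar,
                   const std::vector<double>& invw,
                   const IntegerVector& arm, double qw, double ntot) {
  static const int NG = 33;
  double grid[NG + 1];
  grid[0] = 0.0;
  for (int k = 0; k <= NG - 1; ++k)
    grid[k + 1] = std::pow(10.0, -7.0 + 11.0 * k / (NG - 1));
  int best = 0;
  double bestval = R_PosInf;
  for (int k = 0; k <= NG; ++k) {
    const double val = reml_crit(grid[k], zbar, invw, arm, qw, ntot,
                                 nullptr);
    if (val < bestval) { bestval = val; best = k; }
  }
  double lo = grid[best > 0 ? best - 1 : 0];
  double hi = grid[best < NG ? best + 1 : NG];
  const double gr = 0.3819660112501051;
  double x1 = lo + gr * (hi - lo), x2 = hi - gr * (hi - lo);
  double f1 = reml_crit(x1, zbar, invw, arm, qw, ntot, nullptr);
  double f2 = reml_crit(x2, zbar, invw, arm, qw, ntot, nullptr);
  for (int it = 0; it < 60 && (hi - lo) > 1e-11 * (1.0 + hi); ++it) {
    if (f1 < f2) {
      hi = x2; x2 = x1; f2 = f1;
      x1 = lo + gr * (hi - lo);
      f1 = reml_crit(x1, zbar, invw, arm, qw, ntot, nullptr);
    } else {
      lo = x1; x1 = x2; f1 = f2;
      x2 = hi - gr * (hi - lo);
      f2 = reml_crit(x2, zbar, invw, arm, qw, ntot, nullptr);
    }
  }
  RemlFit fit;
  const double fopt = reml_crit(0.5 * (lo + hi), zbar, invw, arm, qw, ntot,
                                &fit);
  // the boundary gamma = 0 wins ties (no between-cluster variance)
  RemlFit fit0;
  if (reml_crit(0.0, zbar, invw, arm, qw, ntot, &fit0) <= fopt) fit = fit0;
  return fit;
}

inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct ReplResult {
  RemlFit reml;
  std::vector<double> zbar, w, eta;
  bool converged;
  int iter;
  bool boundary;
};

ReplResult repl_run(const NumericVector& y, const NumericVector& m,
                    const IntegerVector& arm, int max_iter, double tol) {
  const int n = y.size();
  const double ETA_MAX = 30.0;
  double ntot = 0;
  for (int j = 0; j < n; ++j) ntot += m[j];
  std::vector<double> eta(n), zbar(n), w(n), invw(n);
  for (int j = 0; j < n; ++j) {
    const double mu = (y[j] + 0.5) / (m[j] + 1.0);
    eta[j] = std::log(mu / (1.0 - mu));
  }
  RemlFit fit{};
  double prev[3] = {NA_REAL, NA_REAL, NA_REAL};
  double prev2[3] = {NA_REAL, NA_REAL, NA_REAL};
  bool converged = false, oscillating = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double qw = 0;
    for (int j = 0; j < n; ++j) {
      const double mu = expit(eta[j]);
      const double v = std::max(mu * (1.0 - mu), 1e-12);
      const double ybar = y[j] / m[j];
      zbar[j] = eta[j] + (ybar - mu) / v;
      w[j] = m[j] * v;
      invw[j] = 1.0 / w[j];
      qw += m[j] * ybar * (1.0 - ybar) / v;  // v_j * SSW_j
    }
    fit = reml_solve(zbar, invw, arm, qw, ntot);
    const double sigma2 = fit.phi * fit.gamma;
    for (int j = 0; j < n; ++j) {
      const double xb = fit.beta0 + (arm[j] ? fit.beta1 : 0.0);
      const double shrink = fit.gamma / (fit.gamma + invw[j]);
      double e = xb + shrink * (zbar[j] - xb);
      if (e > ETA_MAX) e = ETA_MAX;
      if (e < -ETA_MAX) e = -ETA_MAX;
      eta[j] = e;
    }
    const double cur[3] = {fit.beta0, fit.beta1, sigma2};
    if (R_finite(prev[0])) {
      double rel = 0;
      for (int k = 0; k < 3; ++k) {
        const double den = std::max(std::fabs(prev[k]), 1.0);
        rel = std::max(rel, std::fabs(cur[k] - prev[k]) / den);
      }
      if (rel < tol) { converged = true; break; }
      if (R_finite(prev2[0])) {
        double rel2 = 0;
        for (int k = 0; k < 3; ++k) {
          const double den = std::max(std::fabs(prev2[k]), 1.0);
          rel2 = std::max(rel2, std::fabs(cur[k] - prev2[k]) / den);
        }
        // genuine period-2 cycle: repeats the state from two iterations
        // back while still moving by a non-vanishing step (a damped
        // zig-zag approaching the fixed point must not trip this)
        if (rel2 < tol && rel > 1e-3) { oscillating = true; break; }
      }
    }
    for (int k = 0; k < 3; ++k) { prev2[k] = prev[k]; prev[k] = cur[k]; }
  }
  bool boundary = false;
  for (int j = 0; j < n; ++j)
    if (std::fabs(eta[j]) >= ETA_MAX - 1e-9) boundary = true;
  ReplResult res;
  res.reml = fit;
  res.zbar = zbar; res.w = w; res.eta = eta;
  res.converged = converged && !oscillating && !boundary;
  res.iter = std::min(iter, max_iter);
  res.boundary = boundary;
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".repl_fit_core")]]
List repl_fit_core(NumericVector y, NumericVector m, IntegerVector arm,
                   int max_iter = 100, double tol = 1e-8) {
  ReplResult r = repl_run(y, m, arm, max_iter, tol);
  const RemlFit& f = r.reml;
  // cov(beta) = phi * A^{-1}, A = X' D^{-1} X (D in phi units, A22 = A12)
  NumericMatrix cov(2, 2);
  cov(0, 0) = f.phi * f.a12 / f.det;
  cov(0, 1) = cov(1, 0) = -f.phi * f.a12 / f.det;
  cov(1, 1) = f.phi * f.a11 / f.det;
  return List::create(
    _["beta0"] = f.beta0, _["beta1"] = f.beta1,
    _["sigma_b2"] = f.phi * f.gamma, _["phi"] = f.phi,
    _["gamma"] = f.gamma, _["cov_beta"] = cov,
    _["z"] = NumericVector(r.zbar.begin(), r.zbar.end()),
    _["w"] = NumericVector(r.w.begin(), r.w.end()),
    _["eta"] = NumericVector(r.eta.begin(), r.eta.end()),
    _["converged"] = r.converged, _["boundary"] = r.boundary,
    _["iterations"] = r.iter);
}

// Batched fits over repetitions (columns of y/m matrices); returns one row
// per repetition: beta0, beta1, se(beta1), sigma_b2, phi, converged.
// [[Rcpp::export(name = ".repl_fit_many")]]
NumericMatrix repl_fit_many(NumericMatrix y, NumericMatrix m,
                            IntegerVector arm, int max_iter = 100,
                            double tol = 1e-8) {
  const int n = y.nrow(), reps = y.ncol();
  NumericMatrix out(reps, 6);
  colnames(out) = CharacterVector::create("beta0", "beta1", "se1",
                                          "sigma_b2", "phi", "converged");
  NumericVector yj(n), mj(n);
  for (int r = 0; r < reps; ++r) {
    for (int j = 0; j < n; ++j) { yj[j] = y(j, r); mj[j] = m(j, r); }
    ReplResult res = repl_run(yj, mj, arm, max_iter, tol);
    const RemlFit& f = res.reml;
    out(r, 0) = f.beta0;
    out(r, 1) = f.beta1;
    out(r, 2) = std::sqrt(f.phi * f.a11 / f.det);
    out(r, 3) = f.phi * f.gamma;
    out(r, 4) = f.phi;
    out(r, 5) = res.converged ? 1.0 : 0.0;
  }
  return out;
}
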