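// Coordinate-descent kernel for penalized weighted least squares.
//
// The R level drives the IRLS outer loop (recomputing working responses
// and weights); these routines perform the inner cyclic sweeps over the
// standardized design.  Each coordinate update solves
//   min_b  v_j/2 * (b - w_j/v_j)^2 + P(b)
// by applying the univariate thresholding operator to w_j/v_j with the
// penalty parameters rescaled by 1/v_j, which reduces to the verbatim
// operator when v_j = 1 (orthonormal columns, normalized weights).

#include <Rcpp.h>
using namespace Rcpp;

static const int PEN_L1 = 0, PEN_EN = 1, PEN_SCAD = 2, PEN_MCP = 3,
                 PEN_HALF = 4, PEN_HLR = 5, PEN_LOGSUM = 6, PEN_LOGSUM_L2 = 7;

static inline double soft(double w, double lam) {
  double a = std::fabs(w) - lam;
  return a > 0 ? (w > 0 ? a : -a) : 0.0;
}

static inline double op_en(double w, double lam, double a) {
  if (a == 0.0) return w / (1.0 + lam);
  return soft(w, lam * a) / (1.0 + lam * (1.0 - a));
}

static inline double op_scad(double w, double lam, double a) {
  double aw = std::fabs(w);
  if (aw <= 2.0 * lam) return soft(w, lam);
  if (aw <= a * lam) return soft(w, a * lam / (a - 1.0)) / (1.0 - 1.0 / (a - 1.0));
  return w;
}

static inline double op_mcp(double w, double lam, double g) {
  double aw = std::fabs(w);
  if (aw <= g * lam) return soft(w, lam) / (1.0 - 1.0 / g);
  return w;
}

static inline double pen_scad(double b, double lam, double a) {
  b = std::fabs(b);
  if (b <= lam) return lam * b;
  if (b <= a * lam) return (2.0 * a * lam * b - b * b - lam * lam) /
                           (2.0 * (a - 1.0));
  return lam * lam * (a + 1.0) / 2.0;
}

static inline double pen_mcp(double b, double lam, double g) {
  b = std::fabs(b);
  if (b <= g * lam) return lam * b - b * b / (2.0 * g);
  return g * lam * lam / 2.0;
}

// SCAD/MCP updates under general curvature v: min_b v/2 (b - w/v)^2 + P(b).
// The folded-concave branch boundaries do not survive a plain lam/v
// rescale, so the stationary candidates of every branch (plus the branch
// boundaries and zero) are enumerated and the objective decides.
static inline double argmin_cand(const double *cand, int m, double u,
                                 double v, double lam, double shape,
                                 bool scad) {
  double best = cand[0], fbest = R_PosInf;
  for (int i = 0; i < m; ++i) {
    double b = cand[i];
    double f = 0.5 * v * (b - u) * (b - u) +
               (scad ? pen_scad(b, lam, shape) : pen_mcp(b, lam, shape));
    if (f < fbest) { fbest = f; best = b; }
  }
  return best;
}

static inline double op_scad_v(double w, double v, double lam, double a) {
  double u = w / v;
  if (v == 1.0) return op_scad(u, lam, a);
  double su = u >= 0 ? 1.0 : -1.0;
  double cand[6];
  int m = 0;
  cand[m++] = soft(u, lam / v);
  double d = 1.0 - 1.0 / (v * (a - 1.0));
  if (d > 0) cand[m++] = soft(u, a * lam / (v * (a - 1.0))) / d;
  cand[m++] = u;
  cand[m++] = 0.0;
  cand[m++] = su * lam;
  cand[m++] = su * a * lam;
  return argmin_cand(cand, m, u, v, lam, a, true);
}

static inline double op_mcp_v(double w, double v, double lam, double g) {
  double u = w / v;
  if (v == 1.0) return op_mcp(u, lam, g);
  double su = u >= 0 ? 1.0 : -1.0;
  double cand[4];
  int m = 0;
  if (g * v > 1.0) cand[m++] = soft(u, lam / v) / (1.0 - 1.0 / (g * v));
  cand[m++] = u;
  cand[m++] = 0.0;
  cand[m++] = su * g * lam;
  return argmin_cand(cand, m, u, v, lam, g, false);
}

static inline double op_half(double w, double lam) {
  double aw = std::fabs(w);
  if (aw <= 1.5 * std::pow(lam, 2.0 / 3.0)) return 0.0;
  double arg = (lam / 4.0) * std::pow(aw / 3.0, -1.5);
  if (arg > 1.0) arg = 1.0;
  double phi = std::acos(arg);
  double b = (2.0 / 3.0) * aw * (1.0 + std::cos(2.0 * (M_PI - phi) / 3.0));
  return w > 0 ? b : -b;
}

static inline double op_hlr(double w, double lam, double a) {
  if (a == 0.0) return w / (1.0 + lam);
  return op_half(w, lam * a) / (1.0 + lam * (1.0 - a));
}

// zero rule written in threshold form (|w| <= 2*sqrt(lam) - eps, the
// algebraic equivalent of c2 <= 0) so it agrees bitwise with the
// LogSum+L2 rule at lam2 = 0
static inline double op_logsum(double w, double lam, double eps) {
  double aw = std::fabs(w);
  double thr = 2.0 * std::sqrt(lam) - eps;
  if (aw <= (thr > 0 ? thr : 0)) return 0.0;
  double disc = (aw + eps) * (aw + eps) - 4.0 * lam;
  if (disc < 0) disc = 0;  // |w| > thr implies disc >= 0; clamp edge noise
  double root = ((aw - eps) + std::sqrt(disc)) / 2.0;
  if (root <= 0) return 0.0;
  return w > 0 ? root : -root;
}

static inline double op_logsum_l2(double w, double l1, double l2, double eps) {
  double A = 1.0 + 2.0 * l2;
  double thr = 2.0 * std::sqrt(l1 * A) - A * eps;
  double aw = std::fabs(w);
  if (aw <= (thr > 0 ? thr : 0)) return 0.0;
  double disc = (aw + A * eps) * (aw + A * eps) - 4.0 * l1 * A;
  if (disc < 0) disc = 0;  // |w| > thr implies disc >= 0; clamp edge noise
  double root = ((aw - A * eps) + std::sqrt(disc)) / (2.0 * A);
  if (root <= 0) return 0.0;
  return w > 0 ? root : -root;
}

// Update for scaled problem: operator applied at u = w/v with penalty
// parameters divided by v (shape parameters scad_a/gamma/a/eps unscaled).
static inline double thresh_update(double w, double v, int kind, double lam,
                                   double a, double scad_a, double gamma,
                                   double l1, double l2, double eps) {
  double u = w / v;
  switch (kind) {
  case PEN_L1:        return soft(u, lam / v);
  case PEN_EN:        return op_en(u, lam / v, a);
  case PEN_SCAD:      return op_scad_v(w, v, lam, scad_a);
  case PEN_MCP:       return op_mcp_v(w, v, lam, gamma);
  case PEN_HALF:      return op_half(u, lam / v);
  case PEN_HLR:       return op_hlr(u, lam / v, a);
  case PEN_LOGSUM:    return op_logsum(u, lam / v, eps);
  case PEN_LOGSUM_L2: return op_logsum_l2(u, l1 / v, l2 / v, eps);
  }
  return 0.0;
}

// [[Rcpp::export(name = ".cpp_threshold")]]
NumericVector cpp_threshold(NumericVector w, double v, int kind, double lam,
                            double a, double scad_a, double gamma,
                            double l1, double l2, double eps) {
  int m = w.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = thresh_update(w[i], v, kind, lam, a, scad_a, gamma, l1, l2, eps);
  return out;
}

// Repeated cyclic sweeps at fixed working response/weights.
// X: n x p standardized design; r: residual Z - beta0 - X beta (updated in
// place on copies); Wn: weights, expected to sum to 1.  Returns the updated
// coefficients, intercept, residual, number of sweeps and last max change.
// [[Rcpp::export(name = ".cpp_cd_solve")]]
List cpp_cd_solve(NumericMatrix X, NumericVector r_in, NumericVector Wn,
                  NumericVector beta_in, double beta0, bool intercept,
                  int kind, double lam, double a, double scad_a, double gamma,
                  double l1, double l2, double eps,
                  double tol, int max_inner) {
  int n = X.nrow(), p = X.ncol();
  NumericVector r = clone(r_in);
  NumericVector beta = clone(beta_in);

  // per-coordinate curvature v_j = sum_i Wn_i x_ij^2 (fixed while W fixed)
  NumericVector v(p);
  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += Wn[i];
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = X(i, j);
      s += Wn[i] * x * x;
    }
    v[j] = s;
  }

  double maxdiff = 0.0;
  int sweep = 0;
  for (sweep = 0; sweep < max_inner; ++sweep) {
    maxdiff = 0.0;
    if (intercept) {
      double num = 0.0;
      for (int i = 0; i < n; ++i) num += Wn[i] * r[i];
      double d0 = num / sw;
      beta0 += d0;
      for (int i = 0; i < n; ++i) r[i] -= d0;
      if (std::fabs(d0) > maxdiff) maxdiff = std::fabs(d0);
    }
    for (int j = 0; j < p; ++j) {
      if (v[j] <= 0.0) {  // constant column: coefficient pinned at zero
        if (beta[j] != 0.0) {
          for (int i = 0; i < n; ++i) r[i] += X(i, j) * beta[j];
          beta[j] = 0.0;
        }
        continue;
      }
      double wj = 0.0;
      for (int i = 0; i < n; ++i) wj += Wn[i] * X(i, j) * r[i];
      wj += v[j] * beta[j];
      double bnew = thresh_update(wj, v[j], kind, lam, a, scad_a, gamma,
                                  l1, l2, eps);
      double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        beta[j] = bnew;
        double ad = std::fabs(d);
        if (ad > maxdiff) maxdiff = ad;
      }
    }
    if (maxdiff < tol) { ++sweep; break; }
  }
  return List::create(_["beta"] = beta, _["beta0"] = beta0, _["r"] = r,
                      _["n_sweeps"] = sweep, _["max_change"] = maxdiff);
}

// Single cyclic sweep (exposed for the cd_sweep contract and its tests).
// [[Rcpp::export(name = ".cpp_cd_sweep")]]
List cpp_cd_sweep(NumericMatrix X, NumericVector r_in, NumericVector Wn,
                  NumericVector beta_in, double beta0, bool intercept,
                  int kind, double lam, double a, double scad_a, double gamma,
                  double l1, double l2, double eps) {
  return cpp_cd_solve(X, r_in, Wn, beta_in, beta0, intercept, kind, lam, a,
                      scad_a, gamma, l1, l2, eps,
                      R_PosInf, 1);
}
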