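#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Penalized quadratic subproblem for the sparse-group-lasso multinomial fit.
//
// Coefficients live in a (pd x K) matrix (K = M - 1 free classes); a channel
// group is a contiguous run of rows spanning all K columns.  The curvature of
// the quadratic model is block-diagonal per feature row: H[, , j] is the
// (K x K) multinomial covariance block of row j; cross-row blocks are zero.

static inline double soft(double v, double t) {
  if (v > t) return v - t;
  if (v < -t) return v + t;
  return 0.0;
}

// Minimize w(b) = c*b + 0.5*h*b^2 + gamma*sqrt(b^2 + r) + xi*|b| over b.
// Closed forms where available; otherwise a safeguarded Newton/bisection root
// of the stationarity condition  c + xi*s + h*b + gamma*b/sqrt(b^2+r) = 0,
// s = -sign(c), which is strictly increasing in b for h > 0.
double inner_update_scalar(double c, double h, double gamma, double r,
                           double xi, double tol) {
  if (!(h > 0.0)) return 0.0;  // bounded quadratic model => coefficient stays 0
  if (r <= 0.0 || gamma <= 0.0) {
    double th = xi + gamma;
    if (c > th) return (th - c) / h;
    if (c < -th) return (-th - c) / h;
    return 0.0;
  }
  if (std::fabs(c) <= xi) return 0.0;
  double s = (c > 0.0) ? -1.0 : 1.0;
  double a = c + xi * s;  // same sign as c, |a| = |c| - xi > 0
  double lo, hi;
  if (c > 0.0) { lo = -(a + gamma) / h; hi = 0.0; }
  else         { lo = 0.0; hi = (-a + gamma) / h; }
  // phi(lo) < 0 < phi(hi) by construction; widen defensively if rounding bites
  auto phi = [&](double b) {
    return a + h * b + gamma * b / std::sqrt(b * b + r);
  };
  double flo = phi(lo), fhi = phi(hi);
  int guard = 0;
  while (flo > 0.0 && guard++ < 60) { lo -= (hi - lo) + 1.0; flo = phi(lo); }
  guard = 0;
  while (fhi < 0.0 && guard++ < 60) { hi += (hi - lo) + 1.0; fhi = phi(hi); }
  double b = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    double f = phi(b);
    if (std::fabs(f) < tol) return b;
    if (f > 0.0) hi = b; else lo = b;
    double sq = std::sqrt(b * b + r);
    double dphi = h + gamma * r / (sq * sq * sq);
    double bn = b - f / dphi;           // Newton, safeguarded by the bracket
    if (!(bn > lo && bn < hi)) bn = 0.5 * (lo + hi);
    if (std::fabs(bn - b) < 1e-16 * (1.0 + std::fabs(b))) return bn;
    b = bn;
  }
  return b;
}

// [[Rcpp::export]]
double cpp_inner_update(double c, double h, double gamma, double r, double xi,
                        double tol) {
  return inner_update_scalar(c, h, gamma, r, xi, tol);
}

// Group objective of the quadratic subproblem restricted to group J, measured
// from beta_J = 0:  sum(u*b) + 0.5*sum_j b_j' H_j b_j + gamma*||b|| + xi*sum|b|
static double group_value(const NumericMatrix& u, const NumericVector& H,
                          const NumericMatrix& b, int s0, int len, int K,
                          int pd, double gamma, double xi) {
  double lin = 0.0, quad = 0.0, l1 = 0.0, l2sq = 0.0;
  for (int j = s0; j < s0 + len; ++j) {
    for (int m = 0; m < K; ++m) {
      double bj = b(j, m);
      lin += u(j, m) * bj;
      l1 += std::fabs(bj);
      l2sq += bj * bj;
      for (int m2 = 0; m2 < K; ++m2)
        quad += 0.5 * bj * H[m + K * m2 + K * K * j] * b(j, m2);
    }
  }
  return lin + quad + gamma * std::sqrt(l2sq) + xi * l1;
}

// [[Rcpp::export]]
NumericMatrix cpp_solve_subproblem(NumericMatrix q, NumericVector H,
                                   NumericMatrix beta_tilde,
                                   NumericMatrix beta_init,
                                   IntegerVector grp_start,
                                   IntegerVector grp_len,
                                   double lambda, double alpha,
                                   NumericVector w,
                                   double middle_tol, double inner_tol,
                                   int max_middle, int max_inner,
                                   double eps_zero) {
  const int pd = q.nrow(), K = q.ncol(), p = grp_start.size();
  const double xi = lambda * alpha;
  NumericMatrix beta = clone(beta_init);

  // u = gradient of Q at beta = 0 (rowwise):  q - H %*% beta_tilde
  NumericMatrix u(pd, K);
  for (int j = 0; j < pd; ++j)
    for (int m = 0; m < K; ++m) {
      double acc = q(j, m);
      for (int m2 = 0; m2 < K; ++m2)
        acc -= H[m + K * m2 + K * K * j] * beta_tilde(j, m2);
      u(j, m) = acc;
    }

  for (int sweep = 0; sweep < max_middle; ++sweep) {
    double max_change = 0.0;
    for (int J = 0; J < p; ++J) {
      const int s0 = grp_start[J], len = grp_len[J];
      const double gamma = lambda * (1.0 - alpha) * w[J];

      // group zero test: ||soft(g_J, xi)||_2 <= gamma with g_J = u_J
      double nrm2 = 0.0;
      for (int j = s0; j < s0 + len; ++j)
        for (int m = 0; m < K; ++m) {
          double v = soft(u(j, m), xi);
          nrm2 += v * v;
        }
      if (std::sqrt(nrm2) <= gamma) {
        for (int j = s0; j < s0 + len; ++j)
          for (int m = 0; m < K; ++m) {
            if (std::fabs(beta(j, m)) > max_change)
              max_change = std::fabs(beta(j, m));
            beta(j, m) = 0.0;
          }
        continue;
      }

      double gnorm2 = 0.0;
      for (int j = s0; j < s0 + len; ++j)
        for (int m = 0; m < K; ++m) gnorm2 += beta(j, m) * beta(j, m);

      // re-entry branch: group parked at zero but fails the zero test ->
      // move along the soft-thresholded negative gradient with a line search
      if (std::sqrt(gnorm2) < eps_zero) {
        NumericMatrix dir(pd, K);
        double any = 0.0;
        for (int j = s0; j < s0 + len; ++j)
          for (int m = 0; m < K; ++m) {
            dir(j, m) = -soft(u(j, m), xi);
            any += std::fabs(dir(j, m));
          }
        if (any > 0.0) {
          double t = 1.0;
          for (int bt = 0; bt < 60; ++bt) {
            NumericMatrix trial(pd, K);
            for (int j = s0; j < s0 + len; ++j)
              for (int m = 0; m < K; ++m) trial(j, m) = t * dir(j, m);
            if (group_value(u, H, trial, s0, len, K, pd, gamma, xi) < 0.0) {
              for (int j = s0; j < s0 + len; ++j)
                for (int m = 0; m < K; ++m) beta(j, m) = trial(j, m);
              gnorm2 = 0.0;
              for (int j = s0; j < s0 + len; ++j)
                for (int m = 0; m < K; ++m)
                  gnorm2 += beta(j, m) * beta(j, m);
              break;
            }
            t *= 0.5;
          }
        }
      }

      // inner modified coordinate descent over the group's coordinates
      for (int it = 0; it < max_inner; ++it) {
        double cmax = 0.0;
        for (int j = s0; j < s0 + len; ++j)
          for (int m = 0; m < K; ++m) {
            double cc = u(j, m);
            for (int m2 = 0; m2 < K; ++m2)
              if (m2 != m) cc += H[m + K * m2 + K * K * j] * beta(j, m2);
            double h = H[m + K * m + K * K * j];
            double old = beta(j, m);
            double r = gnorm2 - old * old;
            if (r < 0.0) r = 0.0;
            double bn = inner_update_scalar(cc, h, gamma, r, xi, inner_tol);
            if (bn != old) {
              gnorm2 += bn * bn - old * old;
              if (gnorm2 < 0.0) gnorm2 = 0.0;
              beta(j, m) = bn;
              double ch = std::fabs(bn - old);
              if (ch > cmax) cmax = ch;
              if (ch > max_change) max_change = ch;
            }
          }
        if (cmax < inner_tol) break;
      }
    }
    if (max_change < middle_tol) break;
  }
  return beta;
}
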