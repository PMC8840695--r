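#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Numerically stable log(1 + exp(x)).
static inline double log1pexp_(double x) {
  if (x > 37.0) return x;
  if (x < -37.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double expit_(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// Row ranges per cluster; rows must arrive sorted by cluster index (0-based).
static void cluster_offsets(const IntegerVector& cl, int C,
                            std::vector<int>& start, std::vector<int>& end) {
  std::vector<int> cnt(C, 0);
  const int n = cl.size();
  for (int i = 0; i < n; i++) {
    int c = cl[i];
    if (c < 0 || c >= C) stop("cluster index out of range");
    if (i > 0 && cl[i] < cl[i - 1]) stop("rows must be sorted by cluster");
    cnt[c]++;
  }
  start.assign(C, 0);
  end.assign(C, 0);
  int pos = 0;
  for (int c = 0; c < C; c++) {
    start[c] = pos;
    pos += cnt[c];
    end[c] = pos;
  }
}

static inline double clamp_(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Negative marginal log-likelihood of the bivariate logit GLMM with
// cluster-level random intercepts u = (u1, u2) ~ MVN(0, Sigma), integrated by
// per-cluster mode-centred, curvature-scaled (adaptive) Gauss-Hermite
// quadrature on a tensor-product grid.
//
// par = [theta1 (p1), theta2 (p2), l1, l21, l2] with Sigma = L L',
// L = [[exp(l1), 0], [l21, exp(l2)]] (log-Cholesky, PD by construction).
// ghx / ghlogw: physicists' Gauss-Hermite nodes and log-weights
// (sum w = sqrt(pi)).
// [[Rcpp::export]]
double agq_joint_nll_cpp(NumericVector par,
                         NumericMatrix X1, NumericVector y1,
                         IntegerVector cl1, NumericVector w1,
                         NumericMatrix X2, NumericVector y2,
                         IntegerVector cl2, NumericVector w2,
                         int ncluster,
                         NumericVector ghx, NumericVector ghlogw) {
  const int p1 = X1.ncol(), p2 = X2.ncol();
  const int n1 = X1.nrow(), n2 = X2.nrow();
  if (par.size() != p1 + p2 + 3) stop("parameter vector has wrong length");

  std::vector<double> eta1(n1), eta2(n2);
  for (int i = 0; i < n1; i++) {
    double s = 0.0;
    for (int j = 0; j < p1; j++) s += X1(i, j) * par[j];
    eta1[i] = s;
  }
  for (int i = 0; i < n2; i++) {
    double s = 0.0;
    for (int j = 0; j < p2; j++) s += X2(i, j) * par[p1 + j];
    eta2[i] = s;
  }

  const double l1 = clamp_(par[p1 + p2], -8.0, 5.0);
  const double b  = clamp_(par[p1 + p2 + 1], -150.0, 150.0);
  const double l2 = clamp_(par[p1 + p2 + 2], -8.0, 5.0);
  const double a = std::exp(l1), c = std::exp(l2);
  // Q = Sigma^{-1} from L^{-1} = [[1/a, 0], [-b/(a c), 1/c]]
  const double Q11 = 1.0 / (a * a) + (b * b) / (a * a * c * c);
  const double Q12 = -b / (a * c * c);
  const double Q22 = 1.0 / (c * c);
  const double logdetS = 2.0 * (l1 + l2);

  std::vector<int> s1, e1, s2, e2;
  cluster_offsets(cl1, ncluster, s1, e1);
  cluster_offsets(cl2, ncluster, s2, e2);

  const int K = ghx.size();
  std::vector<double> sum1(K), vals(K * K);

  double total = 0.0;
  for (int cidx = 0; cidx < ncluster; cidx++) {
    // Newton ascent for the mode of the penalized per-cluster log-likelihood
    // g(u) = sum_k sum_i w [y*(eta+u_k) - log1pexp(eta+u_k)] - u'Qu/2.
    double u1v = 0.0, u2v = 0.0;
    double M11 = Q11, M22 = Q22;
    const double M12 = Q12;
    for (int it = 0; it < 100; it++) {
      double g1 = -(Q11 * u1v + Q12 * u2v);
      double g2 = -(Q12 * u1v + Q22 * u2v);
      double h1 = 0.0, h2 = 0.0;
      for (int r = s1[cidx]; r < e1[cidx]; r++) {
        double p = expit_(eta1[r] + u1v);
        g1 += w1[r] * (y1[r] - p);
        h1 += w1[r] * p * (1.0 - p);
      }
      for (int r = s2[cidx]; r < e2[cidx]; r++) {
        double p = expit_(eta2[r] + u2v);
        g2 += w2[r] * (y2[r] - p);
        h2 += w2[r] * p * (1.0 - p);
      }
      M11 = h1 + Q11;
      M22 = h2 + Q22;
      double det = M11 * M22 - M12 * M12;
      double d1 = (M22 * g1 - M12 * g2) / det;
      double d2 = (-M12 * g1 + M11 * g2) / det;
      double nrm = std::sqrt(d1 * d1 + d2 * d2);
      if (nrm > 10.0) { d1 *= 10.0 / nrm; d2 *= 10.0 / nrm; }
      u1v += d1;
      u2v += d2;
      if (std::fabs(d1) < 1e-10 && std::fabs(d2) < 1e-10) break;
    }
    // curvature at the mode: M = -Hessian of g
    {
      double h1 = 0.0, h2 = 0.0;
      for (int r = s1[cidx]; r < e1[cidx]; r++) {
        double p = expit_(eta1[r] + u1v);
        h1 += w1[r] * p * (1.0 - p);
      }
      for (int r = s2[cidx]; r < e2[cidx]; r++) {
        double p = expit_(eta2[r] + u2v);
        h2 += w2[r] * p * (1.0 - p);
      }
      M11 = h1 + Q11;
      M22 = h2 + Q22;
    }
    const double detM = M11 * M22 - M12 * M12;
    if (!(detM > 0.0)) stop("non-positive curvature at mode (cluster %d)", cidx + 1);
    // A = lower Cholesky of M^{-1}
    const double Minv11 = M22 / detM, Minv12 = -M12 / detM, Minv22 = M11 / detM;
    const double A11 = std::sqrt(Minv11);
    const double A21 = Minv12 / A11;
    const double A22 = std::sqrt(Minv22 - A21 * A21);
    const double sqrt2 = std::sqrt(2.0);

    // outcome-1 contribution depends on z1 only
    for (int i = 0; i < K; i++) {
      double uu1 = u1v + sqrt2 * A11 * ghx[i];
      double s = 0.0;
      for (int r = s1[cidx]; r < e1[cidx]; r++) {
        double e = eta1[r] + uu1;
        s += w1[r] * (y1[r] * e - log1pexp_(e));
      }
      sum1[i] = s;
    }
    double mx = -INFINITY;
    for (int i = 0; i < K; i++) {
      const double z1 = ghx[i];
      const double uu1 = u1v + sqrt2 * A11 * z1;
      for (int j = 0; j < K; j++) {
        const double z2 = ghx[j];
        const double uu2 = u2v + sqrt2 * (A21 * z1 + A22 * z2);
        double g = sum1[i]
          - 0.5 * (Q11 * uu1 * uu1 + 2.0 * Q12 * uu1 * uu2 + Q22 * uu2 * uu2);
        for (int r = s2[cidx]; r < e2[cidx]; r++) {
          double e = eta2[r] + uu2;
          g += w2[r] * (y2[r] * e - log1pexp_(e));
        }
        double v = ghlogw[i] + ghlogw[j] + z1 * z1 + z2 * z2 + g;
        vals[i * K + j] = v;
        if (v > mx) mx = v;
      }
    }
    double s = 0.0;
    for (int q = 0; q < K * K; q++) s += std::exp(vals[q] - mx);
    const double ll_c = std::log(2.0) - 0.5 * std::log(detM) + mx + std::log(s)
      - 0.5 * logdetS - std::log(2.0 * M_PI);
    if (!std::isfinite(ll_c)) stop("non-finite likelihood contribution (cluster %d)", cidx + 1);
    total += ll_c;
  }
  return -total;
}

// Univariate counterpart: scalar cluster random intercept, u ~ N(0, sigma^2),
// par = [theta (p), log(sigma)].
// [[Rcpp::export]]
double agq_uni_nll_cpp(NumericVector par,
                       NumericMatrix X, NumericVector y,
                       IntegerVector cl, NumericVector w,
                       int ncluster,
                       NumericVector ghx, NumericVector ghlogw) {
  const int p = X.ncol();
  const int n = X.nrow();
  if (par.size() != p + 1) stop("parameter vector has wrong length");

  std::vector<double> eta(n);
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int j = 0; j < p; j++) s += X(i, j) * par[j];
    eta[i] = s;
  }
  const double ls = clamp_(par[p], -8.0, 5.0);
  const double sig2 = std::exp(2.0 * ls);
  const double Q = 1.0 / sig2;

  std::vector<int> st, en;
  cluster_offsets(cl, ncluster, st, en);

  const int K = ghx.size();
  std::vector<double> vals(K);
  const double sqrt2 = std::sqrt(2.0);

  double total = 0.0;
  for (int cidx = 0; cidx < ncluster; cidx++) {
    double uv = 0.0, M = Q;
    for (int it = 0; it < 100; it++) {
      double g = -Q * uv, h = 0.0;
      for (int r = st[cidx]; r < en[cidx]; r++) {
        double pr = expit_(eta[r] + uv);
        g += w[r] * (y[r] - pr);
        h += w[r] * pr * (1.0 - pr);
      }
      M = h + Q;
      double d = g / M;
      if (d > 10.0) d = 10.0;
      if (d < -10.0) d = -10.0;
      uv += d;
      if (std::fabs(d) < 1e-10) break;
    }
    {
      double h = 0.0;
      for (int r = st[cidx]; r < en[cidx]; r++) {
        double pr = expit_(eta[r] + uv);
        h += w[r] * pr * (1.0 - pr);
      }
      M = h + Q;
    }
    if (!(M > 0.0)) stop("non-positive curvature at mode (cluster %d)", cidx + 1);
    const double Asc = 1.0 / std::sqrt(M);
    double mx = -INFINITY;
    for (int i = 0; i < K; i++) {
      const double z = ghx[i];
      const double uu = uv + sqrt2 * Asc * z;
      double g = -0.5 * Q * uu * uu;
      for (int r = st[cidx]; r < en[cidx]; r++) {
        double e = eta[r] + uu;
        g += w[r] * (y[r] * e - log1pexp_(e));
      }
      double v = ghlogw[i] + z * z + g;
      vals[i] = v;
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int i = 0; i < K; i++) s += std::exp(vals[i] - mx);
    const double ll_c = 0.5 * std::log(2.0) - 0.5 * std::log(M) + mx + std::log(s)
      - ls - 0.5 * std::log(2.0 * M_PI);
    if (!std::isfinite(ll_c)) stop("non-finite likelihood contribution (cluster %d)", cidx + 1);
    total += ll_c;
  }
  return -total;
}
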