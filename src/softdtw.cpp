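#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// soft-min_gamma(a,b,c) = -gamma*log(exp(-a/g)+exp(-b/g)+exp(-c/g)),
// computed stably; +Inf entries contribute nothing.
static inline double softmin3(double a, double b, double c, double gamma) {
  double m = std::min(a, std::min(b, c));
  if (m == INF) return INF;
  double s = 0.0;
  if (a < INF) s += std::exp(-(a - m) / gamma);
  if (b < INF) s += std::exp(-(b - m) / gamma);
  if (c < INF) s += std::exp(-(c - m) / gamma);
  return m - gamma * std::log(s);
}

static inline double sq(double v) { return v * v; }

// Forward DP over the (n+1) x (m+1) grid; R(0,0)=0, first row/col +Inf.
static double sdtw_forward(const double* x, int n, const double* y, int m,
                           double gamma, std::vector<double>& R) {
  int w = m + 1;
  std::fill(R.begin(), R.end(), INF);
  R[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = sq(x[i - 1] - y[j - 1]);
      R[i * w + j] = d + softmin3(R[(i - 1) * w + (j - 1)],
                                  R[(i - 1) * w + j],
                                  R[i * w + (j - 1)], gamma);
    }
  }
  return R[n * w + m];
}

// [[Rcpp::export]]
double sdtw_value_cpp(NumericVector x, NumericVector y, double gamma) {
  int n = x.size(), m = y.size();
  std::vector<double> R((n + 1) * (m + 1));
  return sdtw_forward(x.begin(), n, y.begin(), m, gamma, R);
}

// Value and gradient wrt x (Cuturi & Blondel backward recursion).
static double sdtw_value_grad(const double* x, int n, const double* y, int m,
                              double gamma, double* grad) {
  int w = m + 2;
  std::vector<double> R((n + 2) * (m + 2), -INF);
  // forward pass on padded grid
  for (int i = 1; i <= n; ++i) R[i * w + 0] = INF;
  for (int j = 1; j <= m; ++j) R[0 * w + j] = INF;
  R[0] = 0.0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      R[i * w + j] = sq(x[i - 1] - y[j - 1]) +
        softmin3(R[(i - 1) * w + (j - 1)], R[(i - 1) * w + j],
                 R[i * w + (j - 1)], gamma);
  double value = R[n * w + m];
  R[(n + 1) * w + (m + 1)] = value;

  std::vector<double> E((n + 2) * (m + 2), 0.0);
  E[(n + 1) * w + (m + 1)] = 1.0;
  auto dcell = [&](int i, int j) -> double {
    if (i > n || j > m) return 0.0;
    return sq(x[i - 1] - y[j - 1]);
  };
  for (int j = m; j >= 1; --j) {
    for (int i = n; i >= 1; --i) {
      double rij = R[i * w + j];
      double a = std::exp((R[(i + 1) * w + j] - rij - dcell(i + 1, j)) / gamma);
      double b = std::exp((R[i * w + (j + 1)] - rij - dcell(i, j + 1)) / gamma);
      double c = std::exp((R[(i + 1) * w + (j + 1)] - rij - dcell(i + 1, j + 1)) / gamma);
      E[i * w + j] = a * E[(i + 1) * w + j] + b * E[i * w + (j + 1)] +
                     c * E[(i + 1) * w + (j + 1)];
    }
  }
  for (int i = 0; i < n; ++i) {
    double g = 0.0;
    for (int j = 0; j < m; ++j)
      g += E[(i + 1) * w + (j + 1)] * 2.0 * (x[i] - y[j]);
    grad[i] = g;
  }
  return value;
}

// Total soft-DTW objective of candidate barycenter b against the rows of Y,
// with its gradient; used by the barycenter descent.
// [[Rcpp::export]]
List sdtw_bary_obj_cpp(NumericVector b, NumericMatrix Y, double gamma) {
  int T = b.size(), n = Y.nrow();
  NumericVector grad(T);
  std::vector<double> gi(T);
  std::vector<double> yi(T);
  double total = 0.0;
  for (int r = 0; r < n; ++r) {
    for (int t = 0; t < T; ++t) yi[t] = Y(r, t);
    total += sdtw_value_grad(b.begin(), T, yi.data(), Y.ncol(), gamma, gi.data());
    for (int t = 0; t < T; ++t) grad[t] += gi[t];
  }
  return List::create(_["value"] = total, _["gradient"] = grad);
}

// Pairwise soft-DTW between rows of X (n x T) and rows of C (k x T).
// [[Rcpp::export]]
NumericMatrix sdtw_cross_cpp(NumericMatrix X, NumericMatrix C, double gamma) {
  int n = X.nrow(), k = C.nrow(), Tx = X.ncol(), Tc = C.ncol();
  NumericMatrix D(n, k);
  std::vector<double> R((Tx + 1) * (Tc + 1));
  std::vector<double> xi(Tx), cj(Tc);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < Tx; ++t) xi[t] = X(i, t);
    for (int j = 0; j < k; ++j) {
      for (int t = 0; t < Tc; ++t) cj[t] = C(j, t);
      D(i, j) = sdtw_forward(xi.data(), Tx, cj.data(), Tc, gamma, R);
    }
  }
  return D;
}
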