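#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
using namespace Rcpp;

// Collapsed Gibbs sampler for a Dirichlet-process mixture of Gaussian
// processes with a shared squared-exponential kernel. The per-cluster
// marginal likelihood integrates the latent GP mean analytically: for a
// cluster of m series with per-series sums s = sum_a y_a and total sum of
// squares ssq,
//   log p = -mT/2 log(2*pi*sn2) - 1/2 log|K| - 1/2 log|A_m|
//           - ssq/(2 sn2) + (1/2) (s/sn2)' A_m^{-1} (s/sn2),
// where A_m = K^{-1} + (m/sn2) I.  A_m^{-1} and log|A_m| are precomputed in
// R for every possible cluster size and passed in, so each Gibbs move is
// O(T^2).

struct ClusterStats {
  int size;
  std::vector<double> sum;   // length T
  double ssq;
  double lm;                 // cached log marginal
};

class Marginal {
public:
  Marginal(const List& Ainv, const NumericVector& logdetA, double logdetK,
           double sn2, int T)
    : Ainv_(Ainv), logdetA_(logdetA), logdetK_(logdetK), sn2_(sn2), T_(T) {}

  double operator()(int m, const double* s, double ssq) const {
    const NumericMatrix Am = Ainv_[m - 1];
    double qf = 0.0;
    for (int i = 0; i < T_; ++i) {
      double acc = 0.0;
      for (int j = 0; j < T_; ++j) acc += Am(i, j) * s[j];
      qf += s[i] * acc;
    }
    return -0.5 * m * T_ * (std::log(2.0 * M_PI) + std::log(sn2_))
           - 0.5 * logdetK_ - 0.5 * logdetA_[m - 1]
           - ssq / (2.0 * sn2_) + 0.5 * qf / (sn2_ * sn2_);
  }

private:
  const List& Ainv_;
  const NumericVector& logdetA_;
  double logdetK_;
  double sn2_;
  int T_;
};

// [[Rcpp::export]]
List dpgp_gibbs_cpp(NumericMatrix Y, List Ainv, NumericVector logdetA,
                    double logdetK, double sn2, double alpha,
                    int n_sweeps, int n_burn, IntegerVector init) {
  const int n = Y.nrow(), T = Y.ncol();
  Marginal lm(Ainv, logdetA, logdetK, sn2, T);

  std::vector<double> yy(n);  // per-item sum of squares
  for (int i = 0; i < n; ++i) {
    double s2 = 0.0;
    for (int t = 0; t < T; ++t) s2 += Y(i, t) * Y(i, t);
    yy[i] = s2;
  }

  // initialise clusters from init labels (1-based, contiguous not required)
  std::vector<int> lab(n);
  std::vector<ClusterStats> cl;
  {
    std::map<int, int> remap;
    for (int i = 0; i < n; ++i) {
      int key = init[i];
      auto it = remap.find(key);
      int c;
      if (it == remap.end()) {
        c = cl.size();
        remap[key] = c;
        cl.push_back({0, std::vector<double>(T, 0.0), 0.0, 0.0});
      } else c = it->second;
      lab[i] = c;
      cl[c].size += 1;
      for (int t = 0; t < T; ++t) cl[c].sum[t] += Y(i, t);
      cl[c].ssq += yy[i];
    }
    for (auto& c : cl) c.lm = lm(c.size, c.sum.data(), c.ssq);
  }

  const int n_kept = n_sweeps - n_burn;
  IntegerMatrix kept(n_kept > 0 ? n_kept : 0, n);
  NumericMatrix S(n, n);
  std::vector<double> logw, lmplus, snew(T);
  int rec = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      int ci = lab[i];
      // remove item i from its cluster
      cl[ci].size -= 1;
      for (int t = 0; t < T; ++t) cl[ci].sum[t] -= Y(i, t);
      cl[ci].ssq -= yy[i];
      if (cl[ci].size == 0) {
        // swap-remove the emptied cluster
        int last = cl.size() - 1;
        if (ci != last) {
          cl[ci] = cl[last];
          for (int j = 0; j < n; ++j) if (lab[j] == last) lab[j] = ci;
        }
        cl.pop_back();
      } else {
        cl[ci].lm = lm(cl[ci].size, cl[ci].sum.data(), cl[ci].ssq);
      }

      const int K = cl.size();
      logw.assign(K + 1, 0.0);
      lmplus.assign(K + 1, 0.0);
      for (int c = 0; c < K; ++c) {
        for (int t = 0; t < T; ++t) snew[t] = cl[c].sum[t] + Y(i, t);
        lmplus[c] = lm(cl[c].size + 1, snew.data(), cl[c].ssq + yy[i]);
        logw[c] = std::log((double)cl[c].size) + lmplus[c] - cl[c].lm;
      }
      // new cluster under the CRP prior
      std::vector<double> si(T);
      for (int t = 0; t < T; ++t) si[t] = Y(i, t);
      lmplus[K] = lm(1, si.data(), yy[i]);
      logw[K] = std::log(alpha) + lmplus[K];

      double mx = logw[0];
      for (int c = 1; c <= K; ++c) if (logw[c] > mx) mx = logw[c];
      double tot = 0.0;
      for (int c = 0; c <= K; ++c) { logw[c] = std::exp(logw[c] - mx); tot += logw[c]; }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = K;
      for (int c = 0; c <= K; ++c) { acc += logw[c]; if (u <= acc) { pick = c; break; } }

      if (pick == K) {
        ClusterStats fresh{1, si, yy[i], lmplus[K]};
        cl.push_back(fresh);
        lab[i] = K;
      } else {
        cl[pick].size += 1;
        for (int t = 0; t < T; ++t) cl[pick].sum[t] += Y(i, t);
        cl[pick].ssq += yy[i];
        cl[pick].lm = lmplus[pick];
        lab[i] = pick;
      }
    }

    if (sweep >= n_burn && n_kept > 0) {
      for (int i = 0; i < n; ++i) kept(rec, i) = lab[i];
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          if (lab[i] == lab[j]) { S(i, j) += 1.0; }
      ++rec;
    }
  }

  for (int i = 0; i < n; ++i) {
    S(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double v = (rec > 0) ? S(i, j) / rec : (lab[i] == lab[j] ? 1.0 : 0.0);
      S(i, j) = v; S(j, i) = v;
    }
  }

  // least-squares partition: kept sample minimising sum_{i<j} (1{same} - S_ij)^2
  int best = 0;
  double bestloss = R_PosInf;
  for (int r = 0; r < rec; ++r) {
    double loss = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double same = (kept(r, i) == kept(r, j)) ? 1.0 : 0.0;
        double d = same - S(i, j);
        loss += d * d;
      }
    if (loss < bestloss) { bestloss = loss; best = r; }
  }

  IntegerVector final_lab(n);
  if (rec > 0) {
    for (int i = 0; i < n; ++i) final_lab[i] = kept(best, i);
  } else {
    for (int i = 0; i < n; ++i) final_lab[i] = lab[i];
  }
  return List::create(_["labels"] = final_lab, _["similarity"] = S,
                      _["n_kept"] = rec, _["ls_loss"] = bestloss);
}
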