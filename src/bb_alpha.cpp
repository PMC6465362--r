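#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean-constrained beta-binomial window log-likelihood.
//
// For a window of CpGs with counts (M_j, T_j) and pooled mean mhat, the
// emission model is BetaBinomial(M_j | T_j, alpha, beta) with
// beta = alpha * (1 - mhat) / mhat, so that the distribution mean is fixed
// at mhat and alpha alone controls polarization.
//
// With integer counts the likelihood reduces to ascending-factorial sums:
//   log BB(M|T,a,b) - log C(T,M) =
//     sum_{i<M} log(a+i) + sum_{i<T-M} log(b+i) - sum_{i<T} log(a+b+i)
// Tabulating, per window, the exceedance counts
//   cntM[i] = #{j : M_j > i},  cntU[i] = #{j : T_j-M_j > i},
//   cntT[i] = #{j : T_j > i}
// gives a likelihood evaluation costing O(max T) instead of O(n_cpg).
// The binomial coefficients do not depend on alpha and are dropped.

static double bb_table_loglik(double alpha, double mhat,
                              const std::vector<double> &cntM,
                              const std::vector<double> &cntU,
                              const std::vector<double> &cntT) {
  double beta = alpha * (1.0 - mhat) / mhat;
  double ll = 0.0;
  size_t n = cntT.size();
  for (size_t i = 0; i < n; ++i) {
    if (cntM[i] > 0) ll += cntM[i] * std::log(alpha + (double)i);
    if (cntU[i] > 0) ll += cntU[i] * std::log(beta + (double)i);
    ll -= cntT[i] * std::log(alpha + beta + (double)i);
  }
  return ll;
}

// Golden-section maximization of the window log-likelihood over
// log(alpha) in [lo, hi]; unimodal in practice, tolerance on log(alpha).
static double maximize_alpha(double mhat,
                             const std::vector<double> &cntM,
                             const std::vector<double> &cntU,
                             const std::vector<double> &cntT,
                             double lo, double hi, double tol) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c = b - gr * (b - a);
  double d = a + gr * (b - a);
  double fc = bb_table_loglik(std::exp(c), mhat, cntM, cntU, cntT);
  double fd = bb_table_loglik(std::exp(d), mhat, cntM, cntU, cntT);
  while (b - a > tol) {
    if (fc > fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = bb_table_loglik(std::exp(c), mhat, cntM, cntU, cntT);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = bb_table_loglik(std::exp(d), mhat, cntM, cntU, cntT);
    }
  }
  return std::exp((a + b) / 2.0);
}

// [[Rcpp::export]]
List bb_alpha_windows(IntegerVector M, IntegerVector T,
                      IntegerVector win_start, IntegerVector win_end,
                      double log_alpha_min = -8.0,
                      double log_alpha_max = 8.0,
                      double tol = 1e-9) {
  int nw = win_start.size();
  NumericVector mhat(nw), alpha(nw);
  LogicalVector ok(nw);
  for (int w = 0; w < nw; ++w) {
    int s = win_start[w] - 1, e = win_end[w] - 1;  // 1-based inclusive in
    if (s < 0 || e >= M.size() || e < s)
      stop("window indices out of range");
    long sumM = 0, sumT = 0;
    int maxT = 0;
    for (int j = s; j <= e; ++j) {
      sumM += M[j]; sumT += T[j];
      if (T[j] > maxT) maxT = T[j];
    }
    if (sumT == 0) { mhat[w] = NA_REAL; alpha[w] = NA_REAL; ok[w] = false; continue; }
    double mh = (double)sumM / (double)sumT;
    // guard the constrained-mean parameterization at the boundaries
    if (mh < 1e-4) mh = 1e-4;
    if (mh > 1.0 - 1e-4) mh = 1.0 - 1e-4;
    std::vector<double> cntM(maxT, 0.0), cntU(maxT, 0.0), cntT(maxT, 0.0);
    for (int j = s; j <= e; ++j) {
      for (int i = 0; i < M[j]; ++i) cntM[i] += 1.0;
      for (int i = 0; i < T[j] - M[j]; ++i) cntU[i] += 1.0;
      for (int i = 0; i < T[j]; ++i) cntT[i] += 1.0;
    }
    mhat[w] = mh;
    alpha[w] = maximize_alpha(mh, cntM, cntU, cntT,
                              log_alpha_min, log_alpha_max, tol);
    ok[w] = true;
  }
  return List::create(_["mhat"] = mhat, _["alpha"] = alpha, _["ok"] = ok);
}
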