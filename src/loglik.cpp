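#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Log-likelihood of one idealized dwell sequence under the aggregated
// Markov model: the row vector pi_C is propagated through alternating
// factors exp(Q_CC t_c) Q_CO exp(Q_OO t_o) Q_OC ..., with the final open
// dwell contributing only its survival factor (censored).  The state
// vector is renormalized after every factor and the log norms accumulated,
// so arbitrarily long records cannot underflow.
//
// The sub-generator exponentials use the spectral form
//   exp(Q_AA t) = D^{-1/2} U exp(Lambda t) U^T D^{1/2},
// valid because the generator satisfies detailed balance with respect to
// the occupancy vector z (D = diag(z_A)), making D^{1/2} Q_AA D^{-1/2}
// symmetric.  R supplies U, Lambda and sqrt(z_A) per block.
//
// [[Rcpp::export]]
double cpp_loglik_dwells(NumericVector piC,
                         NumericVector dC, NumericMatrix Uc, NumericVector lamC,
                         NumericMatrix Qco,
                         NumericVector dO, NumericMatrix Uo, NumericVector lamO,
                         NumericMatrix Qoc,
                         NumericVector tc, NumericVector to) {
  const int nC = dC.size(), nO = dO.size();
  const int npair = tc.size();
  if (to.size() != npair) stop("tc and to must have equal length");
  if (npair == 0) stop("empty dwell sequence");

  std::vector<double> v(piC.begin(), piC.end());
  std::vector<double> w(std::max(nC, nO)), a(std::max(nC, nO));
  double loglik = 0.0;

  // v <- v * exp(Q_AA t) using the spectral factors, then renormalize
  auto propagate = [&](std::vector<double> &vv, const NumericVector &d,
                       const NumericMatrix &U, const NumericVector &lam,
                       int n, double t) {
    for (int i = 0; i < n; ++i) w[i] = vv[i] / d[i];
    for (int k = 0; k < n; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * U(i, k);
      a[k] = s * std::exp(lam[k] * t);
    }
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < n; ++k) s += a[k] * U(i, k);
      vv[i] = s * d[i];
    }
  };

  auto renorm = [&](std::vector<double> &vv, int n) -> bool {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += std::fabs(vv[i]);
    if (!std::isfinite(s) || s <= 0.0) return false;
    for (int i = 0; i < n; ++i) vv[i] /= s;
    loglik += std::log(s);
    return true;
  };

  std::vector<double> vo(nO);
  for (int p = 0; p < npair; ++p) {
    propagate(v, dC, Uc, lamC, nC, tc[p]);
    if (!renorm(v, nC)) return R_NegInf;
    for (int k = 0; k < nO; ++k) {
      double s = 0.0;
      for (int i = 0; i < nC; ++i) s += v[i] * Qco(i, k);
      vo[k] = s;
    }
    if (!renorm(vo, nO)) return R_NegInf;
    propagate(vo, dO, Uo, lamO, nO, to[p]);
    if (p + 1 < npair) {
      if (!renorm(vo, nO)) return R_NegInf;
      for (int i = 0; i < nC; ++i) {
        double s = 0.0;
        for (int k = 0; k < nO; ++k) s += vo[k] * Qoc(k, i);
        v[i] = s;
      }
      if (!renorm(v, nC)) return R_NegInf;
    }
  }

  // censored final open dwell: survival mass only
  double tail = 0.0;
  for (int k = 0; k < nO; ++k) tail += vo[k];
  if (!std::isfinite(tail) || tail <= 0.0) return R_NegInf;
  return loglik + std::log(tail);
}
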