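// EM for an exponential mixture on nonnegative data. Compiled because the
// bootstrap refits this model tens of thousands of times during model
// selection.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".expmix_em")]]
List expmix_em(NumericVector s, NumericVector tau0, NumericVector w0,
               double tol, int max_iter) {
  const int n = s.size();
  const int K = tau0.size();
  std::vector<double> tau(tau0.begin(), tau0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> nk(K), sk(K), p(K);
  double ll_old = -std::numeric_limits<double>::infinity();
  double ll = ll_old;
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    for (int k = 0; k < K; ++k) { nk[k] = 0.0; sk[k] = 0.0; }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      // log densities with running max for stable normalization
      double m = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        p[k] = std::log(w[k]) - std::log(tau[k]) - s[i] / tau[k];
        if (p[k] > m) m = p[k];
      }
      double rs = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = std::exp(p[k] - m);
        rs += p[k];
      }
      ll += m + std::log(rs);
      for (int k = 0; k < K; ++k) {
        const double r = p[k] / rs;
        nk[k] += r;
        sk[k] += r * s[i];
      }
    }
    for (int k = 0; k < K; ++k) {
      w[k] = nk[k] / n;
      tau[k] = std::max(sk[k] / std::max(nk[k], 1e-300), 1e-9);
    }
    if (it > 0 && std::isfinite(ll) && ll - ll_old < tol) {
      converged = true;
      ll_old = ll;
      break;
    }
    ll_old = ll;
  }
  return List::create(_["tau"] = NumericVector(tau.begin(), tau.end()),
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["loglik"] = ll_old, _["converged"] = converged);
}
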