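// Two-state Gaussian hidden Markov model: scaled forward-backward
// (Baum-Welch) training and Viterbi decoding. Kept in compiled code because
// idealization runs over hundreds of traces with thousands of frames each.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double dnorm_safe(double x, double mu, double var) {
  const double v = var > 1e-12 ? var : 1e-12;
  const double z = x - mu;
  return std::exp(-0.5 * z * z / v) / std::sqrt(2.0 * M_PI * v);
}

// [[Rcpp::export(name = ".hmm2_em")]]
List hmm2_em(NumericVector y, NumericVector mu0, NumericVector var0,
             NumericMatrix trans0, NumericVector init0,
             int max_iter, double tol) {
  const int n = y.size();
  std::vector<double> mu{mu0[0], mu0[1]}, var{var0[0], var0[1]};
  double A[2][2] = {{trans0(0, 0), trans0(0, 1)}, {trans0(1, 0), trans0(1, 1)}};
  double pi0[2] = {init0[0], init0[1]};

  NumericMatrix alpha(n, 2), beta(n, 2), gamma(n, 2);
  std::vector<double> scale(n);
  double loglik = R_NegInf;
  NumericVector ll_trace(max_iter, NA_REAL);
  int it = 0;
  bool converged = false;

  for (it = 0; it < max_iter; ++it) {
    // forward with scaling
    for (int s = 0; s < 2; ++s)
      alpha(0, s) = pi0[s] * dnorm_safe(y[0], mu[s], var[s]);
    scale[0] = alpha(0, 0) + alpha(0, 1);
    if (scale[0] <= 0) scale[0] = 1e-300;
    alpha(0, 0) /= scale[0];
    alpha(0, 1) /= scale[0];
    for (int t = 1; t < n; ++t) {
      for (int s = 0; s < 2; ++s) {
        double a = alpha(t - 1, 0) * A[0][s] + alpha(t - 1, 1) * A[1][s];
        alpha(t, s) = a * dnorm_safe(y[t], mu[s], var[s]);
      }
      scale[t] = alpha(t, 0) + alpha(t, 1);
      if (scale[t] <= 0) scale[t] = 1e-300;
      alpha(t, 0) /= scale[t];
      alpha(t, 1) /= scale[t];
    }
    double ll = 0.0;
    for (int t = 0; t < n; ++t) ll += std::log(scale[t]);
    ll_trace[it] = ll;

    // backward
    beta(n - 1, 0) = beta(n - 1, 1) = 1.0;
    for (int t = n - 2; t >= 0; --t) {
      for (int s = 0; s < 2; ++s) {
        double b = 0.0;
        for (int r = 0; r < 2; ++r)
          b += A[s][r] * dnorm_safe(y[t + 1], mu[r], var[r]) * beta(t + 1, r);
        beta(t, s) = b / scale[t + 1];
      }
    }
    // state posteriors and expected transitions
    double xi[2][2] = {{0, 0}, {0, 0}};
    for (int t = 0; t < n; ++t) {
      double g0 = alpha(t, 0) * beta(t, 0);
      double g1 = alpha(t, 1) * beta(t, 1);
      double gs = g0 + g1;
      gamma(t, 0) = g0 / gs;
      gamma(t, 1) = g1 / gs;
    }
    for (int t = 0; t + 1 < n; ++t) {
      for (int s = 0; s < 2; ++s)
        for (int r = 0; r < 2; ++r)
          xi[s][r] += alpha(t, s) * A[s][r] *
                      dnorm_safe(y[t + 1], mu[r], var[r]) * beta(t + 1, r) /
                      scale[t + 1];
    }
    // M-step
    for (int s = 0; s < 2; ++s) {
      double rowsum = xi[s][0] + xi[s][1];
      if (rowsum > 0) {
        A[s][0] = xi[s][0] / rowsum;
        A[s][1] = xi[s][1] / rowsum;
      }
      pi0[s] = gamma(0, s);
      double w = 0.0, m = 0.0;
      for (int t = 0; t < n; ++t) {
        w += gamma(t, s);
        m += gamma(t, s) * y[t];
      }
      if (w > 1e-12) {
        mu[s] = m / w;
        double v = 0.0;
        for (int t = 0; t < n; ++t) {
          double z = y[t] - mu[s];
          v += gamma(t, s) * z * z;
        }
        var[s] = std::max(v / w, 1e-12);
      }
    }
    if (it > 0 && ll - loglik < tol && ll >= loglik) {
      loglik = ll;
      converged = true;
      ++it;
      break;
    }
    loglik = ll;
  }

  NumericMatrix Aout(2, 2);
  for (int s = 0; s < 2; ++s)
    for (int r = 0; r < 2; ++r) Aout(s, r) = A[s][r];
  return List::create(
      _["means"] = NumericVector::create(mu[0], mu[1]),
      _["vars"] = NumericVector::create(var[0], var[1]),
      _["trans"] = Aout,
      _["init"] = NumericVector::create(pi0[0], pi0[1]),
      _["loglik"] = loglik,
      _["loglik_trace"] = ll_trace[Range(0, std::max(it - 1, 0))],
      _["converged"] = converged,
      _["posterior"] = gamma);
}

// [[Rcpp::export(name = ".hmm2_viterbi")]]
IntegerVector hmm2_viterbi(NumericVector y, NumericVector mu,
                           NumericVector var, NumericMatrix trans,
                           NumericVector init) {
  const int n = y.size();
  std::vector<std::array<double, 2>> delta(n);
  std::vector<std::array<int, 2>> psi(n);
  const double tiny = -1e300;
  auto lg = [](double p) { return p > 0 ? std::log(p) : -1e300; };
  for (int s = 0; s < 2; ++s)
    delta[0][s] = lg(init[s]) + std::log(dnorm_safe(y[0], mu[s], var[s]));
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < 2; ++s) {
      double best = tiny;
      int arg = 0;
      for (int r = 0; r < 2; ++r) {
        double v = delta[t - 1][r] + lg(trans(r, s));
        if (v > best) { best = v; arg = r; }
      }
      delta[t][s] = best + std::log(dnorm_safe(y[t], mu[s], var[s]));
      psi[t][s] = arg;
    }
  }
  IntegerVector path(n);
  path[n - 1] = delta[n - 1][1] > delta[n - 1][0] ? 1 : 0;
  for (int t = n - 2; t >= 0; --t) path[t] = psi[t + 1][path[t + 1]];
  return path;
}
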