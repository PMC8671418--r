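// Baum-Welch / forward-backward / Viterbi for a K-state homogeneous
// Gaussian hidden Markov model. Used on log1p-transformed 1-min activity
// counts, where a plain R implementation is too slow for multi-restart EM
// on multi-day recordings.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Scaled forward-backward. Fills gamma (T x K posterior), accumulates
// expected transition counts in xi_sum (K x K), returns log-likelihood.
static double forward_backward(const NumericVector& x,
                               const NumericVector& mu,
                               const NumericVector& sigma,
                               const NumericMatrix& trans,
                               const NumericVector& init,
                               NumericMatrix& gamma,
                               NumericMatrix& xi_sum) {
  const int T = x.size(), K = mu.size();
  NumericMatrix b(T, K);     // scaled emission likelihoods
  NumericVector mrow(T);
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double z = (x[t] - mu[k]) / sigma[k];
      double ld = -0.5 * (LOG2PI + z * z) - std::log(sigma[k]);
      b(t, k) = ld;
      if (ld > m) m = ld;
    }
    mrow[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(b(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double ll = 0.0;

  for (int k = 0; k < K; ++k) alpha(0, k) = init[k] * b(0, k);
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += alpha(0, k);
  if (s <= 0) return R_NegInf;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      a *= b(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) return R_NegInf;
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + mrow[t];

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double v = 0.0;
      for (int k = 0; k < K; ++k)
        v += trans(j, k) * b(t + 1, k) * beta(t + 1, k);
      beta(t, j) = v / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double s2 = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s2 += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s2;
  }

  std::fill(xi_sum.begin(), xi_sum.end(), 0.0);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        xi_sum(j, k) += alpha(t, j) * trans(j, k) * b(t + 1, k) *
          beta(t + 1, k) / c[t + 1];
      }
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".hmm_em_cpp")]]
List hmm_em_cpp(NumericVector x, NumericVector mu0, NumericVector sigma0,
                NumericMatrix trans0, NumericVector init0,
                int max_iter, double tol, double sd_floor) {
  const int T = x.size(), K = mu0.size();
  NumericVector mu = clone(mu0), sigma = clone(sigma0), init = clone(init0);
  NumericMatrix trans = clone(trans0);
  NumericMatrix gamma(T, K), xi_sum(K, K);

  double ll_old = R_NegInf, ll = R_NegInf;
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    ll = forward_backward(x, mu, sigma, trans, init, gamma, xi_sum);
    if (!R_finite(ll)) break;
    if (iter > 0) {
      double rel = std::fabs(ll - ll_old) /
        (std::fabs(ll_old) > 1e-300 ? std::fabs(ll_old) : 1.0);
      if (rel < tol) { converged = true; break; }
    }
    ll_old = ll;

    // M-step
    for (int k = 0; k < K; ++k) init[k] = gamma(0, k);
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += xi_sum(j, k);
      for (int k = 0; k < K; ++k)
        trans(j, k) = rs > 0 ? xi_sum(j, k) / rs : (j == k ? 1.0 : 0.0);
    }
    for (int k = 0; k < K; ++k) {
      double w = 0.0, wx = 0.0;
      for (int t = 0; t < T; ++t) { w += gamma(t, k); wx += gamma(t, k) * x[t]; }
      if (w <= 0) { continue; }
      double m = wx / w, wss = 0.0;
      for (int t = 0; t < T; ++t) {
        double d = x[t] - m;
        wss += gamma(t, k) * d * d;
      }
      mu[k] = m;
      sigma[k] = std::sqrt(wss / w);
      if (sigma[k] < sd_floor) sigma[k] = sd_floor;
    }
  }

  return List::create(_["means"] = mu, _["sds"] = sigma, _["trans"] = trans,
                      _["init"] = init, _["loglik"] = ll,
                      _["n_iter"] = iter, _["converged"] = converged);
}

// [[Rcpp::export(name = ".hmm_posterior_cpp")]]
List hmm_posterior_cpp(NumericVector x, NumericVector mu, NumericVector sigma,
                       NumericMatrix trans, NumericVector init) {
  const int T = x.size(), K = mu.size();
  NumericMatrix gamma(T, K), xi_sum(K, K);
  double ll = forward_backward(x, mu, sigma, trans, init, gamma, xi_sum);
  return List::create(_["gamma"] = gamma, _["loglik"] = ll);
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector mu,
                              NumericVector sigma, NumericMatrix trans,
                              NumericVector init) {
  const int T = x.size(), K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix ltrans(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      ltrans(j, k) = trans(j, k) > 0 ? std::log(trans(j, k)) : R_NegInf;

  for (int k = 0; k < K; ++k) {
    double z = (x[0] - mu[k]) / sigma[k];
    double ld = -0.5 * (LOG2PI + z * z) - std::log(sigma[k]);
    delta(0, k) = (init[k] > 0 ? std::log(init[k]) : R_NegInf) + ld;
  }
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + ltrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      double z = (x[t] - mu[k]) / sigma[k];
      delta(t, k) = best - 0.5 * (LOG2PI + z * z) - std::log(sigma[k]);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;   // 1-based states
}
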