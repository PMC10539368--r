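#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Negative marginal log-likelihood of a random-intercept logistic model,
// integrated per cluster by adaptive Gauss-Hermite quadrature. Clusters
// are summarized by (group indicator x, trials n, successes y) — valid
// because the only covariate is cluster-level. The binomial coefficient
// is omitted (constant in the parameters).
//
// par = (b0, beta, log_sigma) or (b0, log_sigma) when include_group is
// false; z, w are Gauss-Hermite nodes/weights for int e^{-z^2} f(z) dz.
// [[Rcpp::export]]
double glmm_agq_nll(NumericVector par, NumericVector x, NumericVector n,
                    NumericVector y, NumericVector z, NumericVector w,
                    bool include_group) {
  const double b0 = par[0];
  const double beta = include_group ? par[1] : 0.0;
  const double logsig = par[include_group ? 2 : 1];
  const double sig = std::exp(logsig);
  const double sig2 = sig * sig;
  const int m = x.size(), K = z.size();
  const double lognorm = -logsig - 0.5 * std::log(2.0 * M_PI);
  std::vector<double> terms(K);
  double ll = 0.0;
  for (int i = 0; i < m; ++i) {
    const double fix = b0 + beta * x[i];
    // Newton search for the per-cluster posterior mode
    double b = 0.0, h = 1.0;
    for (int it = 0; it < 50; ++it) {
      double eta = fix + b;
      double p = 1.0 / (1.0 + std::exp(-eta));
      double g = y[i] - n[i] * p - b / sig2;
      h = n[i] * p * (1.0 - p) + 1.0 / sig2;
      double step = g / h;
      b += step;
      if (std::fabs(step) < 1e-11) break;
    }
    {
      double eta = fix + b;
      double p = 1.0 / (1.0 + std::exp(-eta));
      h = n[i] * p * (1.0 - p) + 1.0 / sig2;
    }
    const double s = 1.0 / std::sqrt(h);
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double bk = b + M_SQRT2 * s * z[k];
      double eta = fix + bk;
      double log1pe = eta > 30.0 ? eta : std::log1p(std::exp(eta));
      double lg = y[i] * eta - n[i] * log1pe -
        0.5 * bk * bk / sig2 + lognorm;
      double term = std::log(w[k]) + z[k] * z[k] + lg;
      terms[k] = term;
      if (term > mx) mx = term;
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(terms[k] - mx);
    ll += std::log(M_SQRT2 * s) + mx + std::log(sum);
  }
  return -ll;
}
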