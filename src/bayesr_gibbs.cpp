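// Gibbs sampler for the BayesR model: per-SNP effects drawn from a
// four-component normal mixture N(0, gamma_k * sigma2_g) with
// gamma = (0, 1e-4, 1e-3, 1e-2), Dirichlet(1,1,1,1) prior on the mixture
// proportions, and scaled-inverse-chi-square conditionals for sigma2_g and
// sigma2_e. Uses R's RNG so chains are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List bayesr_gibbs(NumericVector y, NumericMatrix Z, NumericVector scales,
                  int n_iter, int burn_in, int thin,
                  double nu0, double S0g, double S0e) {
  const int n = Z.nrow();
  const int m = Z.ncol();
  const int K = scales.size();

  const double* Zp = Z.begin(); // column-major
  std::vector<double> zz(m);
  for (int j = 0; j < m; ++j) {
    const double* zj = Zp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += zj[i] * zj[i];
    zz[j] = s;
  }

  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);

  std::vector<double> beta(m, 0.0);
  std::vector<int> comp(m, 0);
  std::vector<double> r(n);
  double mu = my;
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;
  double sigma2g = vy / 2.0, sigma2e = vy / 2.0;
  std::vector<double> pi(K, 1.0 / K);

  std::vector<double> beta_sum(m, 0.0);
  std::vector<double> pi_sum(K, 0.0);
  double s2g_sum = 0.0, s2e_sum = 0.0;
  int n_saved = 0;

  int n_save_max = (n_iter - burn_in + thin - 1) / thin;
  NumericMatrix trace(n_save_max, 3 + 2 * K); // s2g, s2e, loglik, pi[], counts[]

  std::vector<double> logl(K), prob(K);
  std::vector<int> counts(K);

  for (int it = 1; it <= n_iter; ++it) {
    // intercept (flat prior)
    double rs = 0.0;
    for (int i = 0; i < n; ++i) rs += r[i];
    double mu_new = R::rnorm(mu + rs / n, std::sqrt(sigma2e / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) r[i] -= dmu;
    mu = mu_new;

    std::fill(counts.begin(), counts.end(), 0);
    for (int j = 0; j < m; ++j) {
      const double old = beta[j];
      const double* zj = Zp + (size_t)j * n;
      double zr = 0.0;
      for (int i = 0; i < n; ++i) zr += zj[i] * r[i];
      const double rhs = zr + zz[j] * old;

      // component indicator: log pi_k + Gaussian marginal likelihood of rhs
      double lmax = R_NegInf;
      for (int k = 0; k < K; ++k) {
        if (scales[k] <= 0.0) {
          logl[k] = std::log(pi[k]);
        } else {
          const double v = scales[k] * sigma2g;
          const double den = zz[j] * v + sigma2e;
          logl[k] = std::log(pi[k]) - 0.5 * std::log(den / sigma2e)
                    + 0.5 * rhs * rhs * v / (sigma2e * den);
        }
        if (logl[k] > lmax) lmax = logl[k];
      }
      double psum = 0.0;
      for (int k = 0; k < K; ++k) { prob[k] = std::exp(logl[k] - lmax); psum += prob[k]; }
      double u = R::runif(0.0, 1.0) * psum;
      int k = 0;
      double acc = prob[0];
      while (k < K - 1 && u > acc) acc += prob[++k];
      counts[k] += 1;
      comp[j] = k;

      // effect draw conditional on the indicator
      double bnew = 0.0;
      if (scales[k] > 0.0) {
        const double v = scales[k] * sigma2g;
        const double vpost = sigma2e * v / (zz[j] * v + sigma2e);
        const double mpost = rhs * v / (zz[j] * v + sigma2e);
        bnew = R::rnorm(mpost, std::sqrt(vpost));
      }
      if (bnew != old) {
        const double d = old - bnew;
        for (int i = 0; i < n; ++i) r[i] += zj[i] * d;
        beta[j] = bnew;
      }
    }

    // mixture proportions ~ Dirichlet(1 + counts)
    double gsum = 0.0;
    for (int k = 0; k < K; ++k) { pi[k] = R::rgamma(1.0 + counts[k], 1.0); gsum += pi[k]; }
    for (int k = 0; k < K; ++k) pi[k] /= gsum;

    // sigma2_g | beta, indicators: scaled-inverse-chi-square
    double ssb = 0.0;
    int nnz = 0;
    for (int j = 0; j < m; ++j) {
      if (comp[j] > 0 && scales[comp[j]] > 0.0) {
        ssb += beta[j] * beta[j] / scales[comp[j]];
        ++nnz;
      }
    }
    sigma2g = (ssb + nu0 * S0g) / R::rchisq(nu0 + nnz);

    // sigma2_e
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    sigma2e = (rss + nu0 * S0e) / R::rchisq(nu0 + n);
    if (!R_finite(sigma2e) || sigma2e <= 0.0 || !R_finite(sigma2g)) {
      stop("BayesR chain diverged at iteration %d (sigma2_e = %g, sigma2_g = %g)",
           it, sigma2e, sigma2g);
    }

    double loglik = -0.5 * n * std::log(2.0 * M_PI * sigma2e)
                    - 0.5 * rss / sigma2e;

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) beta_sum[j] += beta[j];
      for (int k = 0; k < K; ++k) pi_sum[k] += pi[k];
      s2g_sum += sigma2g;
      s2e_sum += sigma2e;
      trace(n_saved, 0) = sigma2g;
      trace(n_saved, 1) = sigma2e;
      trace(n_saved, 2) = loglik;
      for (int k = 0; k < K; ++k) {
        trace(n_saved, 3 + k) = pi[k];
        trace(n_saved, 3 + K + k) = counts[k];
      }
      ++n_saved;
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector beta_mean(m), pi_mean(K);
  for (int j = 0; j < m; ++j) beta_mean[j] = beta_sum[j] / n_saved;
  for (int k = 0; k < K; ++k) pi_mean[k] = pi_sum[k] / n_saved;
  NumericVector r_out(n), beta_out(m);
  for (int i = 0; i < n; ++i) r_out[i] = r[i];
  for (int j = 0; j < m; ++j) beta_out[j] = beta[j];

  return List::create(
    _["beta_mean"] = beta_mean,
    _["pi_mean"] = pi_mean,
    _["sigma2_g_mean"] = s2g_sum / n_saved,
    _["sigma2_e_mean"] = s2e_sum / n_saved,
    _["trace"] = trace(Range(0, n_saved - 1), _),
    _["beta_final"] = beta_out,
    _["residual_final"] = r_out,
    _["mu_final"] = mu,
    _["n_saved"] = n_saved);
}
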