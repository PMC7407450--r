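#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for Bayesian whole-genome probit regression with
// latent-variable augmentation. The residual (latent) variance is fixed at
// 1 (not likelihood-identified) and the threshold is fixed at 0 with a
// free intercept. Model codes: 1 BRR, 2 Bayesian LASSO, 3 BayesA,
// 4 BayesB, 5 BayesCpi. Uses R's RNG, so set.seed() on the R side makes
// chains reproducible.

static inline double rtnorm(double eta, int y1) {
  // N(eta, 1) truncated to (0, Inf) if y1 else (-Inf, 0]; tail-robust via
  // log-scale inverse CDF
  double u = R::runif(0.0, 1.0);
  if (u <= 0.0) u = 1e-300;
  if (y1) {
    // mass above the truncation point -eta (on the z = l - eta scale)
    double logp = std::log(u) + R::pnorm(-eta, 0.0, 1.0, 0, 1);
    double z = R::qnorm(logp, 0.0, 1.0, 0, 1); // upper-tail quantile
    return eta + z;
  } else {
    double logp = std::log(u) + R::pnorm(-eta, 0.0, 1.0, 1, 1);
    double z = R::qnorm(logp, 0.0, 1.0, 1, 1);
    return eta + z;
  }
}

static inline double rscinv_chisq(double df, double dfS) {
  // draw from scaled-inverse-chi-square: dfS / chisq(df)
  double c = R::rchisq(df);
  if (c < 1e-12) c = 1e-12;
  return dfS / c;
}

static inline double rinvgauss(double mu, double lambda) {
  // Michael, Schucany & Haas
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = R::runif(0.0, 1.0);
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".gibbs_probit")]]
List gibbs_probit(const NumericMatrix& M, const NumericMatrix& X,
                  const IntegerVector& y, int model,
                  int n_iter, int burn_in, int thin,
                  double df0, double S0, double pi0, double P0,
                  double l_shape, double l_rate, double lambda2_init,
                  double fixed_marker_var) {
  const int n = y.size();
  const int p = M.ncol();
  const int q = X.ncol();

  std::vector<double> cxx(p), xcxx(q);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    cxx[j] = s;
  }
  for (int k = 0; k < q; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xcxx[k] = s;
  }

  int ncase = 0;
  for (int i = 0; i < n; ++i) ncase += y[i];
  double mu = R::qnorm(std::min(0.999, std::max(0.001, (double)ncase / n)),
                       0.0, 1.0, 1, 0);
  std::vector<double> b(q, 0.0), alpha(p, 0.0), l(n), e(n);
  std::vector<int> delta(p, 0);
  double pi = pi0;                       // P(SNP has no effect)
  double sig_common = (fixed_marker_var > 0.0)
    ? fixed_marker_var : S0 * df0 / (df0 + 2.0);
  std::vector<double> sig_j(p, sig_common), tau2(p, 1.0);
  double lambda2 = lambda2_init;
  if (model == 2) for (int j = 0; j < p; ++j) tau2[j] = 2.0 / lambda2;

  for (int i = 0; i < n; ++i) {
    l[i] = y[i] ? 0.5 : -0.5;
    e[i] = l[i] - mu;
  }

  const int n_store_max = (n_iter - burn_in + thin - 1) / thin;
  NumericVector mu_sum(1), pi_sum(1);
  std::vector<double> b_sum(q, 0.0), b_sq(q, 0.0);
  std::vector<double> a_sum(p, 0.0), a_sq(p, 0.0), d_sum(p, 0.0);
  std::vector<double> prob_sum(n, 0.0);
  NumericMatrix trace(n_store_max, 4); // mu, pi, mean marker var, lambda2
  double mu_s = 0.0, mu_s2 = 0.0, pi_s = 0.0;
  int n_store = 0;

  for (int it = 0; it < n_iter; ++it) {
    // 1. latent variable
    for (int i = 0; i < n; ++i) {
      double eta = l[i] - e[i];
      l[i] = rtnorm(eta, y[i]);
      e[i] = l[i] - eta;
    }
    // 2. intercept (flat prior)
    {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += e[i];
      m /= n;
      double mu_new = mu + m + R::norm_rand() / std::sqrt((double)n);
      double dmu = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= dmu;
      mu = mu_new;
    }
    // 3. covariate effects (flat prior)
    for (int k = 0; k < q; ++k) {
      if (xcxx[k] < 1e-12) continue;
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += X(i, k) * e[i];
      r += b[k] * xcxx[k];
      double bn = r / xcxx[k] + R::norm_rand() / std::sqrt(xcxx[k]);
      double db = bn - b[k];
      for (int i = 0; i < n; ++i) e[i] -= X(i, k) * db;
      b[k] = bn;
    }
    // 4. marker effects
    if (model == 1 || model == 2 || model == 3) {
      for (int j = 0; j < p; ++j) {
        if (cxx[j] < 1e-12) { alpha[j] = 0.0; continue; }
        double v = (model == 1) ? sig_common : (model == 2 ? tau2[j] : sig_j[j]);
        if (v < 1e-12) v = 1e-12;
        double r = 0.0;
        for (int i = 0; i < n; ++i) r += M(i, j) * e[i];
        r += alpha[j] * cxx[j];
        double C = cxx[j] + 1.0 / v;
        double an = r / C + R::norm_rand() / std::sqrt(C);
        double da = an - alpha[j];
        for (int i = 0; i < n; ++i) e[i] -= M(i, j) * da;
        alpha[j] = an;
        delta[j] = 1;
      }
    } else { // BayesB / BayesCpi: spike-and-slab
      int k_in = 0;
      double ss_in = 0.0;
      for (int j = 0; j < p; ++j) {
        if (cxx[j] < 1e-12) { alpha[j] = 0.0; delta[j] = 0; continue; }
        double v = (model == 4) ? sig_j[j] : sig_common;
        if (v < 1e-12) v = 1e-12;
        double r = 0.0;
        for (int i = 0; i < n; ++i) r += M(i, j) * e[i];
        r += alpha[j] * cxx[j];
        double C = cxx[j] + 1.0 / v;
        double logodds = std::log((1.0 - pi) / pi) -
          0.5 * std::log(v * C) + r * r / (2.0 * C);
        double pincl = 1.0 / (1.0 + std::exp(-logodds));
        double a_old = alpha[j];
        if (R::runif(0.0, 1.0) < pincl) {
          double an = r / C + R::norm_rand() / std::sqrt(C);
          alpha[j] = an;
          delta[j] = 1;
          ++k_in;
          ss_in += an * an;
        } else {
          alpha[j] = 0.0;
          delta[j] = 0;
        }
        double da = alpha[j] - a_old;
        if (da != 0.0) for (int i = 0; i < n; ++i) e[i] -= M(i, j) * da;
      }
      // pi ~ Beta full conditional (pi = prob of NO effect)
      pi = R::rbeta(P0 * pi0 + (p - k_in), P0 * (1.0 - pi0) + k_in);
      if (pi < 1e-6) pi = 1e-6;
      if (pi > 1.0 - 1e-6) pi = 1.0 - 1e-6;
      if (model == 5 && fixed_marker_var <= 0.0) {
        sig_common = rscinv_chisq(df0 + k_in, df0 * S0 + ss_in);
      }
    }
    // 5. hyperparameters
    if (model == 1 && fixed_marker_var <= 0.0) {
      double ss = 0.0;
      for (int j = 0; j < p; ++j) ss += alpha[j] * alpha[j];
      sig_common = rscinv_chisq(df0 + p, df0 * S0 + ss);
    } else if (model == 3) {
      for (int j = 0; j < p; ++j)
        sig_j[j] = rscinv_chisq(df0 + 1.0, df0 * S0 + alpha[j] * alpha[j]);
    } else if (model == 4) {
      for (int j = 0; j < p; ++j) {
        if (delta[j]) sig_j[j] = rscinv_chisq(df0 + 1.0, df0 * S0 + alpha[j] * alpha[j]);
        else          sig_j[j] = rscinv_chisq(df0, df0 * S0);
      }
    } else if (model == 2) {
      double tsum = 0.0;
      for (int j = 0; j < p; ++j) {
        double aj = std::fabs(alpha[j]);
        if (aj < 1e-10) aj = 1e-10;
        double inv_tau2 = rinvgauss(std::sqrt(lambda2) / aj, lambda2);
        if (inv_tau2 < 1e-12) inv_tau2 = 1e-12;
        tau2[j] = 1.0 / inv_tau2;
        tsum += tau2[j];
      }
      lambda2 = R::rgamma(l_shape + p, 1.0 / (l_rate + tsum / 2.0));
      if (lambda2 < 1e-10) lambda2 = 1e-10;
    }
    // 6. store
    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      mu_s += mu; mu_s2 += mu * mu; pi_s += pi;
      for (int k = 0; k < q; ++k) { b_sum[k] += b[k]; b_sq[k] += b[k] * b[k]; }
      double msv = 0.0;
      for (int j = 0; j < p; ++j) {
        a_sum[j] += alpha[j]; a_sq[j] += alpha[j] * alpha[j];
        d_sum[j] += delta[j];
        msv += (model == 3 || model == 4) ? sig_j[j]
             : (model == 2 ? tau2[j] : sig_common);
      }
      for (int i = 0; i < n; ++i)
        prob_sum[i] += R::pnorm(l[i] - e[i], 0.0, 1.0, 1, 0);
      trace(n_store, 0) = mu;
      trace(n_store, 1) = pi;
      trace(n_store, 2) = (p > 0) ? msv / p : 0.0;
      trace(n_store, 3) = lambda2;
      ++n_store;
    }
  }

  const double ns = std::max(1, n_store);
  NumericVector alpha_mean(p), alpha_sd(p), delta_mean(p);
  for (int j = 0; j < p; ++j) {
    alpha_mean[j] = a_sum[j] / ns;
    double v = a_sq[j] / ns - alpha_mean[j] * alpha_mean[j];
    alpha_sd[j] = std::sqrt(std::max(0.0, v));
    delta_mean[j] = d_sum[j] / ns;
  }
  NumericVector b_mean(q), b_sd(q);
  for (int k = 0; k < q; ++k) {
    b_mean[k] = b_sum[k] / ns;
    double v = b_sq[k] / ns - b_mean[k] * b_mean[k];
    b_sd[k] = std::sqrt(std::max(0.0, v));
  }
  NumericVector prob_mean(n);
  for (int i = 0; i < n; ++i) prob_mean[i] = prob_sum[i] / ns;
  double mu_mean = mu_s / ns;
  double mu_sd = std::sqrt(std::max(0.0, mu_s2 / ns - mu_mean * mu_mean));

  return List::create(
    _["mu_mean"] = mu_mean, _["mu_sd"] = mu_sd,
    _["b_mean"] = b_mean, _["b_sd"] = b_sd,
    _["alpha_mean"] = alpha_mean, _["alpha_sd"] = alpha_sd,
    _["delta_mean"] = delta_mean, _["pi_mean"] = pi_s / ns,
    _["prob_mean"] = prob_mean, _["trace"] = trace,
    _["n_samples"] = n_store);
}
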