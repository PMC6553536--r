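// Gibbs samplers for Bayesian whole-genome regression:
//   y = mu + Z a + e
// method 0 = BayesA   (marker-specific scaled-inv-chi2 variances)
// method 1 = BayesB   (point mass at zero with probability pi)
// method 2 = Bayesian lasso (Park & Casella; double-exponential shrinkage)
// Uses R's RNG throughout so chains are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// inverse-Gaussian sampler (Michael, Schucany & Haas 1976)
static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
             std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// scaled-inverse-chi-squared draw: S * df / chi2_df
static double rscinvchi2(double df, double S) {
  return S * df / R::rchisq(df);
}

// [[Rcpp::export(name = ".wgr_gibbs")]]
List wgr_gibbs(NumericVector y, NumericMatrix Z, int method,
               int n_iter, int burn_in, int thin,
               double pi_zero, double df_marker, double scale_marker,
               double df_e, double scale_e,
               double lasso_rate, double lasso_shape,
               double fixed_marker_var) {
  int n = y.size(), p = Z.ncol();
  if (Z.nrow() != n) stop("Z rows must match y");
  if (burn_in >= n_iter) stop("burn_in must be below n_iter");

  std::vector<double> zsq(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zsq[j] = s;
  }

  double mu = mean(y);
  std::vector<double> a(p, 0.0), s2a(p), tau2(p, 1.0);
  double init_var = (fixed_marker_var > 0.0) ? fixed_marker_var
                                             : scale_marker;
  for (int j = 0; j < p; ++j) s2a[j] = init_var;
  double s2e = scale_e > 0 ? scale_e : 1.0;
  double lambda2 = 1.0;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> a_sum(p, 0.0), s2a_sum(p, 0.0);
  std::vector<double> incl_sum(p, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0, lambda2_sum = 0.0;
  int n_kept = 0;
  NumericVector s2e_trace((n_iter - burn_in + thin - 1) / thin);

  for (int it = 0; it < n_iter; ++it) {
    // intercept (flat prior)
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i] + mu;
    double mu_new = esum / n + norm_rand() * std::sqrt(s2e / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // marker effects
    for (int j = 0; j < p; ++j) {
      if (zsq[j] <= 0.0) { a[j] = 0.0; continue; }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      rhs += zsq[j] * a[j];
      double a_old = a[j], a_new;

      if (method == 2) {          // Bayesian lasso: a_j ~ N(0, s2e * tau2_j)
        double c = zsq[j] + 1.0 / tau2[j];
        a_new = rhs / c + norm_rand() * std::sqrt(s2e / c);
      } else if (method == 1) {   // BayesB: spike-and-slab
        double v0 = zsq[j] * s2e;
        double v1 = zsq[j] * s2e + zsq[j] * zsq[j] * s2a[j];
        double lf1 = -0.5 * (std::log(v1) + rhs * rhs / v1);
        double lf0 = -0.5 * (std::log(v0) + rhs * rhs / v0);
        double lodds = std::log(1.0 - pi_zero) - std::log(pi_zero) + lf1 - lf0;
        double prob = 1.0 / (1.0 + std::exp(-lodds));
        if (unif_rand() < prob) {
          double c = zsq[j] + s2e / s2a[j];
          a_new = rhs / c + norm_rand() * std::sqrt(s2e / c);
          incl_sum[j] += (it >= burn_in && (it - burn_in) % thin == 0);
        } else {
          a_new = 0.0;
        }
      } else {                    // BayesA: normal with marker variance
        double c = zsq[j] + s2e / s2a[j];
        a_new = rhs / c + norm_rand() * std::sqrt(s2e / c);
      }
      if (a_new != a_old) {
        for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * (a_new - a_old);
        a[j] = a_new;
      }

      // marker-variance updates
      if (fixed_marker_var <= 0.0) {
        if (method == 0 || method == 1) {
          s2a[j] = rscinvchi2(df_marker + 1.0,
                              (scale_marker * df_marker + a[j] * a[j]) /
                              (df_marker + 1.0));
        } else {
          double aj2 = a[j] * a[j];
          if (aj2 < 1e-12) aj2 = 1e-12;
          double inv = rinvgauss(std::sqrt(lambda2 * s2e / aj2), lambda2);
          if (inv < 1e-12) inv = 1e-12;
          tau2[j] = 1.0 / inv;
        }
      }
    }

    // lasso regularization parameter
    if (method == 2 && fixed_marker_var <= 0.0) {
      double tsum = 0.0;
      for (int j = 0; j < p; ++j) tsum += tau2[j];
      lambda2 = R::rgamma(lasso_shape + p, 1.0 / (lasso_rate + tsum / 2.0));
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + scale_e * df_e) / R::rchisq(n + df_e);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        a_sum[j] += a[j];
        s2a_sum[j] += (method == 2) ? s2e * tau2[j] : s2a[j];
      }
      mu_sum += mu; s2e_sum += s2e; lambda2_sum += lambda2;
      s2e_trace[n_kept] = s2e;
      ++n_kept;
    }
  }

  NumericVector a_mean(p), s2a_mean(p), incl(p);
  for (int j = 0; j < p; ++j) {
    a_mean[j] = a_sum[j] / n_kept;
    s2a_mean[j] = s2a_sum[j] / n_kept;
    incl[j] = incl_sum[j] / n_kept;
  }
  return List::create(
    _["effects"] = a_mean, _["marker_var"] = s2a_mean,
    _["mu"] = mu_sum / n_kept, _["s2e"] = s2e_sum / n_kept,
    _["lambda2"] = lambda2_sum / n_kept, _["inclusion"] = incl,
    _["s2e_trace"] = s2e_trace, _["n_kept"] = n_kept);
}
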