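#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs samplers for whole-genome marker-effect regression.
//
// Model: y_i = mu + sum_k Z_ik alpha_k + e_i,  e_i ~ N(0, w_i * sigma2_e),
// with w_i a known relative residual weight (1 for an individual record;
// (0.5 sigma2_a + sigma2_e/n)/sigma2_e for a family mean of n sibs).
//
// method 0 (BayesA): every locus has its own variance sigma2_k with a
//   scaled-inverse-chi-square(nu_a, scale_a) prior; all loci fitted.
// method 1 (BayesCpi): per-locus inclusion indicator delta_k, common effect
//   variance sigma2_alpha ~ scaled-inv-chi-square(nu_a, scale_a), and
//   pi ~ Uniform(0,1) sampled from its Beta full conditional
//   Beta(m - m_in + 1, m_in + 1), m_in = number of included loci.
//
// The residual vector r = y - mu - Z alpha is updated in place after every
// locus, so one sweep costs O(n m).  Draws use R's RNG, so chains are
// reproducible under set.seed().

static inline double rinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export]]
List wgr_gibbs_cpp(NumericVector y, NumericMatrix Z, NumericVector w,
                   int method, int niter, int burnin, int thin,
                   double nu_a, double scale_a,
                   double pi_init, bool estimate_pi,
                   double nu_e, double scale_e, double sigma2e_init) {
  const int n = y.size();
  const int m = Z.ncol();

  std::vector<double> alpha(m, 0.0);
  std::vector<int> delta(m, method == 1 ? 0 : 1);
  std::vector<double> sig2k(m, scale_a); // BayesA locus variances
  double sigma2_alpha = scale_a;         // BayesCpi common variance
  double pi = pi_init;
  double sigma2e = sigma2e_init;
  double mu = 0.0;

  std::vector<double> winv(n);
  double sw = 0.0;
  for (int i = 0; i < n; ++i) {
    winv[i] = 1.0 / w[i];
    sw += winv[i];
  }
  // start from mu = weighted mean
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i] * winv[i];
  mu = ybar / sw;

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  // weighted sum of squares per locus
  std::vector<double> zz(m);
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      const double z = Z(i, k);
      s += z * z * winv[i];
    }
    zz[k] = s;
  }

  std::vector<double> sum_a(m, 0.0), sumsq_a(m, 0.0), sum_d(m, 0.0);
  std::vector<double> keep_pi, keep_s2e, keep_s2a;
  int nkeep = 0;

  for (int it = 1; it <= niter; ++it) {
    // --- locus effects ---
    for (int k = 0; k < m; ++k) {
      if (zz[k] <= 0.0) { alpha[k] = 0.0; delta[k] = 0; continue; } // monomorphic
      const double a_old = alpha[k];
      // rhs on the "residual + own effect" vector, without forming it
      double zr = 0.0;
      for (int i = 0; i < n; ++i) zr += Z(i, k) * r[i] * winv[i];
      const double rhs = (zr + zz[k] * a_old) / sigma2e;

      if (method == 0) { // BayesA: always in
        const double C = zz[k] / sigma2e + 1.0 / sig2k[k];
        const double a_new = rhs / C + R::norm_rand() / std::sqrt(C);
        const double d = a_new - a_old;
        if (d != 0.0) for (int i = 0; i < n; ++i) r[i] -= Z(i, k) * d;
        alpha[k] = a_new;
        sig2k[k] = rinvchisq(nu_a + 1.0, (nu_a * scale_a + a_new * a_new) / (nu_a + 1.0));
      } else { // BayesCpi
        double a_new = 0.0;
        int d_new = 0;
        if (pi < 1.0) {
          const double C = zz[k] / sigma2e + 1.0 / sigma2_alpha;
          // log Bayes factor inclusion vs exclusion
          const double logbf = -0.5 * std::log(sigma2_alpha * C) + 0.5 * rhs * rhs / C;
          const double logodds = std::log1p(-pi) - std::log(pi) + logbf;
          const double pin = 1.0 / (1.0 + std::exp(-logodds));
          if (R::unif_rand() < pin) {
            d_new = 1;
            a_new = rhs / C + R::norm_rand() / std::sqrt(C);
          }
        }
        const double d = a_new - a_old;
        if (d != 0.0) for (int i = 0; i < n; ++i) r[i] -= Z(i, k) * d;
        alpha[k] = a_new;
        delta[k] = d_new;
      }
    }

    // --- common effect variance and pi (BayesCpi) ---
    if (method == 1) {
      int m_in = 0;
      double ssa = 0.0;
      for (int k = 0; k < m; ++k)
        if (delta[k]) { ++m_in; ssa += alpha[k] * alpha[k]; }
      sigma2_alpha = rinvchisq(nu_a + m_in, (nu_a * scale_a + ssa) / (nu_a + m_in));
      if (estimate_pi)
        pi = R::rbeta((double)(m - m_in) + 1.0, (double)m_in + 1.0);
    }

    // --- intercept ---
    {
      double sr = 0.0;
      for (int i = 0; i < n; ++i) sr += r[i] * winv[i];
      const double mu_new = mu + sr / sw + R::norm_rand() * std::sqrt(sigma2e / sw);
      const double d = mu_new - mu;
      for (int i = 0; i < n; ++i) r[i] -= d;
      mu = mu_new;
    }

    // --- residual variance ---
    {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += r[i] * r[i] * winv[i];
      sigma2e = rinvchisq(nu_e + n, (nu_e * scale_e + sse) / (nu_e + n));
    }

    // --- accumulate posterior summaries ---
    if (it > burnin && ((it - burnin) % thin == 0)) {
      ++nkeep;
      for (int k = 0; k < m; ++k) {
        sum_a[k] += alpha[k];
        sumsq_a[k] += alpha[k] * alpha[k];
        sum_d[k] += delta[k];
      }
      keep_pi.push_back(pi);
      keep_s2e.push_back(sigma2e);
      keep_s2a.push_back(method == 1 ? sigma2_alpha : NA_REAL);
    }
  }

  NumericVector am(m), asd(m), ip(m);
  for (int k = 0; k < m; ++k) {
    am[k] = sum_a[k] / nkeep;
    const double v = sumsq_a[k] / nkeep - am[k] * am[k];
    asd[k] = std::sqrt(v > 0.0 ? v : 0.0);
    ip[k] = sum_d[k] / nkeep;
  }
  return List::create(
      _["alpha_mean"] = am, _["alpha_sd"] = asd, _["inclusion_prob"] = ip,
      _["pi_samples"] = wrap(keep_pi), _["sigma2e_samples"] = wrap(keep_s2e),
      _["sigma2alpha_samples"] = wrap(keep_s2a), _["n_samples"] = nkeep);
}
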