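// Gibbs samplers for the Bayesian-alphabet whole-genome regression models:
// Bayesian ridge regression (BRR), Bayes A, Bayes B, Bayes C-pi and the
// Bayesian LASSO.  All models share the structure
//   y = mu + Z beta + e,  e ~ N(0, I sigma2_e)
// and differ only in the hierarchical prior on the marker effects beta.
// pi is the probability that a marker has ZERO effect (spike mass).
//
// Uses R's RNG so chains are reproducible from set.seed() on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// scaled-inverse-chi-square draw: (ss + nu*S) / chisq(nu + k)
static inline double rsichisq(double ss, double nu, double S, double k) {
  return (ss + nu * S) / R::rchisq(nu + k);
}

// inverse-Gaussian draw (Michael, Schucany & Haas)
static inline double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// method codes: 0 = brr, 1 = bayesA, 2 = bayesB, 3 = bayesCpi, 4 = blasso
// [[Rcpp::export(name = ".gibbs_wgr_cpp")]]
List gibbs_wgr_cpp(NumericVector y, NumericMatrix Z, int method,
                   int burnin, int niter, int thin, List hyper,
                   bool keep_samples) {
  RNGScope scope;
  const int n = Z.nrow(), m = Z.ncol();
  const double nu_b = as<double>(hyper["nu_beta"]);
  const double S_b = as<double>(hyper["S_beta"]);
  const double nu_e = as<double>(hyper["nu_e"]);
  const double S_e = as<double>(hyper["S_e"]);
  const double pi_a = as<double>(hyper["pi_a"]);   // prior count: zero
  const double pi_b = as<double>(hyper["pi_b"]);   // prior count: nonzero
  const double lam_shape = as<double>(hyper["lambda_shape"]);
  const double lam_rate = as<double>(hyper["lambda_rate"]);
  const double fix_sigma_beta = as<double>(hyper["fix_sigma_beta"]); // <=0: free
  const double fix_sigma_e = as<double>(hyper["fix_sigma_e"]);       // <=0: free
  const double fix_lambda2 = as<double>(hyper["fix_lambda2"]);       // <=0: free
  const double fix_pi = as<double>(hyper["fix_pi"]);                 // <0: free

  // precompute column sums of squares
  std::vector<double> zz(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zz[j] = s;
  }

  // state
  double ybar = mean(y);
  double mu = ybar;
  double vy = 0.0;
  for (int i = 0; i < n; ++i) vy += (y[i] - ybar) * (y[i] - ybar);
  vy /= std::max(n - 1, 1);
  if (vy <= 0.0) vy = 1e-8;

  std::vector<double> beta(m, 0.0);
  std::vector<int> incl(m, 1);
  std::vector<double> s2j(m, S_b > 0 ? S_b : vy / m); // per-marker variances
  std::vector<double> tau2(m, 1.0);
  double sigma2_beta = S_b > 0 ? S_b : vy / m;
  double sigma2_e = fix_sigma_e > 0 ? fix_sigma_e : vy / 2.0;
  if (fix_sigma_beta > 0) sigma2_beta = fix_sigma_beta;
  double lambda2 = fix_lambda2 > 0 ? fix_lambda2
                                   : std::max(lam_shape / std::max(lam_rate, 1e-12), 1.0);
  double pi = fix_pi >= 0 ? fix_pi : 0.5;
  const bool spike = (method == 2 || method == 3);

  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  // accumulators
  std::vector<double> beta_sum(m, 0.0), beta_sq(m, 0.0), incl_sum(m, 0.0);
  std::vector<double> s2j_sum(m, 0.0);
  double mu_sum = 0, se_sum = 0, sb_sum = 0, pi_sum = 0, lam_sum = 0,
         h2_sum = 0, vg_sum = 0;
  int nsave = 0;
  int total = burnin + niter;
  int nkeep = niter / thin + 1;
  NumericVector se_samp(nkeep), vg_samp(nkeep);
  NumericMatrix beta_samp(keep_samples ? nkeep : 1,
                          keep_samples ? m : 1);

  for (int it = 0; it < total; ++it) {
    // intercept
    double rsum = 0.0;
    for (int i = 0; i < n; ++i) rsum += e[i] + mu;
    double mu_new = R::rnorm(rsum / n, std::sqrt(sigma2_e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // marker effects
    for (int j = 0; j < m; ++j) {
      if (zz[j] <= 0.0) { beta[j] = 0.0; incl[j] = 0; continue; }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      rhs += zz[j] * beta[j];  // partial residual r = e + z_j beta_j

      double varj;
      switch (method) {
        case 0: varj = sigma2_beta; break;                  // brr
        case 1: varj = s2j[j]; break;                       // bayesA
        case 2: varj = s2j[j]; break;                       // bayesB
        case 3: varj = sigma2_beta; break;                  // bayesCpi
        default: varj = sigma2_e * tau2[j]; break;          // blasso
      }
      double bold = beta[j], bnew;
      if (spike) {
        double v1 = sigma2_e + zz[j] * varj;
        double logbf = 0.5 * (std::log(sigma2_e / v1) +
                              rhs * rhs * varj / (sigma2_e * v1));
        // p(included) with pi = P(zero effect)
        double lo = std::log1p(-std::min(pi, 1.0 - 1e-12)) + logbf;
        double le = std::log(std::max(pi, 1e-12));
        double pin = 1.0 / (1.0 + std::exp(le - lo));
        if (R::unif_rand() < pin) {
          incl[j] = 1;
          double prec = zz[j] / sigma2_e + 1.0 / varj;
          bnew = R::rnorm((rhs / sigma2_e) / prec, std::sqrt(1.0 / prec));
        } else {
          incl[j] = 0;
          bnew = 0.0;
        }
      } else {
        double prec = zz[j] / sigma2_e + 1.0 / varj;
        bnew = R::rnorm((rhs / sigma2_e) / prec, std::sqrt(1.0 / prec));
      }
      if (bnew != bold)
        for (int i = 0; i < n; ++i) e[i] += Z(i, j) * (bold - bnew);
      beta[j] = bnew;
    }

    // prior-variance updates
    if (method == 1) {                       // bayesA: per-marker
      for (int j = 0; j < m; ++j)
        s2j[j] = rsichisq(beta[j] * beta[j], nu_b, S_b, 1.0);
    } else if (method == 2) {                // bayesB
      for (int j = 0; j < m; ++j)
        s2j[j] = incl[j] ? rsichisq(beta[j] * beta[j], nu_b, S_b, 1.0)
                         : rsichisq(0.0, nu_b, S_b, 0.0);  // prior draw
    } else if (method == 0 && fix_sigma_beta <= 0) {  // brr: common
      double ss = 0.0;
      for (int j = 0; j < m; ++j) ss += beta[j] * beta[j];
      sigma2_beta = rsichisq(ss, nu_b, S_b, (double)m);
    } else if (method == 3) {                // bayesCpi: common over included
      double ss = 0.0; int min_ = 0;
      for (int j = 0; j < m; ++j)
        if (incl[j]) { ss += beta[j] * beta[j]; ++min_; }
      sigma2_beta = rsichisq(ss, nu_b, S_b, (double)min_);
    } else if (method == 4) {                // blasso
      double tsum = 0.0;
      for (int j = 0; j < m; ++j) {
        double b2 = std::max(beta[j] * beta[j], 1e-12);
        double mu_ig = std::sqrt(lambda2 * sigma2_e / b2);
        if (mu_ig > 1e8) mu_ig = 1e8;
        double it2 = rinvgauss(mu_ig, lambda2);
        tau2[j] = 1.0 / it2;
        tsum += tau2[j];
      }
      if (fix_lambda2 <= 0)
        lambda2 = R::rgamma(lam_shape + m, 1.0 / (lam_rate + tsum / 2.0));
    }

    // pi update (spike models)
    if (spike && fix_pi < 0) {
      int m1 = 0;
      for (int j = 0; j < m; ++j) m1 += incl[j];
      pi = R::rbeta(pi_a + (m - m1), pi_b + m1);
    }

    // residual variance
    if (fix_sigma_e <= 0) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += e[i] * e[i];
      double k = (double)n;
      if (method == 4) {  // beta | sigma2_e in the blasso hierarchy
        for (int j = 0; j < m; ++j) ss += beta[j] * beta[j] / tau2[j];
        k += (double)m;
      }
      sigma2_e = rsichisq(ss, nu_e, S_e, k);
    }

    // save
    if (it >= burnin && ((it - burnin) % thin == 0)) {
      double gbar = 0.0, gss = 0.0;
      std::vector<double> g(n, 0.0);
      for (int j = 0; j < m; ++j) {
        if (beta[j] == 0.0) continue;
        for (int i = 0; i < n; ++i) g[i] += Z(i, j) * beta[j];
      }
      for (int i = 0; i < n; ++i) gbar += g[i];
      gbar /= n;
      for (int i = 0; i < n; ++i) gss += (g[i] - gbar) * (g[i] - gbar);
      double vg = n > 1 ? gss / (n - 1) : 0.0;

      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        beta_sq[j] += beta[j] * beta[j];
        incl_sum[j] += incl[j];
        s2j_sum[j] += s2j[j];
      }
      mu_sum += mu; se_sum += sigma2_e; sb_sum += sigma2_beta;
      pi_sum += pi; lam_sum += lambda2;
      vg_sum += vg;
      h2_sum += vg / std::max(vg + sigma2_e, 1e-300);
      if (nsave < nkeep) {
        se_samp[nsave] = sigma2_e;
        vg_samp[nsave] = vg;
        if (keep_samples)
          for (int j = 0; j < m; ++j) beta_samp(nsave, j) = beta[j];
      }
      ++nsave;
    }
  }

  if (nsave == 0) stop("no saved iterations (check burnin/niter/thin)");
  NumericVector bhat(m), bsd(m), pincl(m), s2jm(m);
  for (int j = 0; j < m; ++j) {
    bhat[j] = beta_sum[j] / nsave;
    double v = beta_sq[j] / nsave - bhat[j] * bhat[j];
    bsd[j] = std::sqrt(std::max(v, 0.0));
    pincl[j] = incl_sum[j] / nsave;
    s2jm[j] = s2j_sum[j] / nsave;
  }
  int kept = std::min(nsave, nkeep);
  return List::create(
      _["mu"] = mu_sum / nsave, _["beta"] = bhat, _["beta_sd"] = bsd,
      _["prob_included"] = pincl, _["sigma2_j"] = s2jm,
      _["sigma2_e"] = se_sum / nsave, _["sigma2_beta"] = sb_sum / nsave,
      _["pi_hat"] = pi_sum / nsave, _["lambda2"] = lam_sum / nsave,
      _["var_g"] = vg_sum / nsave, _["h2_hat"] = h2_sum / nsave,
      _["n_saved"] = nsave,
      _["sigma2_e_samples"] = se_samp[Range(0, kept - 1)],
      _["var_g_samples"] = vg_samp[Range(0, kept - 1)],
      _["beta_samples"] = keep_samples ? beta_samp : NumericMatrix(0, 0));
}
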