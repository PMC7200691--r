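// Gibbs sampler for the Bayesian sparse linear mixed model on a
// column-standardized genotype matrix and a centered, covariate-adjusted
// phenotype.
//
// Model:  y = X b + e,  e ~ N(0, se2 I)
//   b_j ~ (1 - pi) N(0, s12)  +  pi N(0, s22),   s22 >= s12
// The "spike" N(0, s12) carries the dense polygenic background (the random
// effect u = X a with a_j ~ N(0, s12) has exactly the genomic-relatedness
// covariance s1s2 * XX'); the slab adds the large sparse effects. pi has the
// prior proportional to 1/pi on [1/p, 1] (log-uniform on the expected
// included count), which is conjugate: pi | k ~ Beta(k, p - k + 1) truncated.
//
// One sampling step = one full systematic-scan Gibbs sweep over all p SNPs
// (rank-one residual updates) followed by conjugate updates of s12, s22,
// se2 and pi. Uses R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".bslmm_gibbs")]]
List bslmm_gibbs(const arma::mat& X, const arma::vec& y,
                 int n_steps, int burn_in,
                 bool slab, double pi_init,
                 double s1_init, double s2_init, double se_init) {
  const int n = X.n_rows, p = X.n_cols;
  const double vy = arma::var(y);

  arma::vec xx(p);
  for (int j = 0; j < p; ++j) xx(j) = arma::dot(X.col(j), X.col(j));

  arma::vec b(p, arma::fill::zeros);
  arma::ivec delta(p, arma::fill::zeros);
  arma::vec r = y;

  double s1 = s1_init, s2 = s2_init, se = se_init, pi = pi_init;
  const double pi_min = 1.0 / p;

  // weak conjugate priors; spike prior mean keeps p * s1 at ~10% of var(y)
  const double a_e = 2.0, b_e = 0.5 * vy;
  const double a_1 = 2.0, b_1 = 0.1 * vy / p;
  const double a_2 = 2.0, b_2 = 0.1 * vy;

  const int n_keep = n_steps - burn_in;
  arma::vec pve_chain(n_keep), s1_chain(n_keep), s2_chain(n_keep),
      se_chain(n_keep), pi_chain(n_keep);
  arma::ivec ninc_chain(n_keep);
  arma::vec alpha_sum(p, arma::fill::zeros), beta_sum(p, arma::fill::zeros);
  arma::ivec inc_count(p, arma::fill::zeros);

  for (int step = 0; step < n_steps; ++step) {
    for (int j = 0; j < p; ++j) {
      if (xx(j) <= 0) { b(j) = 0; delta(j) = 0; continue; }
      const arma::vec xj(const_cast<double*>(X.colptr(j)), n, false, true);
      double bj = b(j);
      // d = x_j' (r + x_j b_j) without forming the excluded residual
      double d = arma::dot(xj, r) + xx(j) * bj;

      const double v1 = 1.0 / (xx(j) / se + 1.0 / s1);
      const double m1 = v1 * d / se;
      double lw1 = std::log(1.0 - pi) + 0.5 * (std::log(v1) - std::log(s1)) +
                   0.5 * m1 * m1 / v1;
      int dj = 0;
      double m = m1, v = v1;
      if (slab) {
        const double v2 = 1.0 / (xx(j) / se + 1.0 / s2);
        const double m2 = v2 * d / se;
        double lw2 = std::log(pi) + 0.5 * (std::log(v2) - std::log(s2)) +
                     0.5 * m2 * m2 / v2;
        const double mx = std::max(lw1, lw2);
        const double p2 = std::exp(lw2 - mx) /
                          (std::exp(lw1 - mx) + std::exp(lw2 - mx));
        if (R::unif_rand() < p2) { dj = 1; m = m2; v = v2; }
      }
      const double bnew = m + std::sqrt(v) * R::norm_rand();
      const double diff = bnew - bj;
      if (diff != 0.0) r -= diff * xj;
      b(j) = bnew;
      delta(j) = dj;
    }

    // hyperparameters
    int k = 0;
    double ss_spike = 0.0, ss_slab = 0.0;
    for (int j = 0; j < p; ++j) {
      if (delta(j) == 1) { ++k; ss_slab += b(j) * b(j); }
      else ss_spike += b(j) * b(j);
    }
    se = rinvgamma(a_e + 0.5 * n, b_e + 0.5 * arma::dot(r, r));
    s1 = rinvgamma(a_1 + 0.5 * (p - k), b_1 + 0.5 * ss_spike);
    if (slab) {
      s2 = rinvgamma(a_2 + 0.5 * k, b_2 + 0.5 * ss_slab);
      if (s2 < s1) s2 = s1;  // ordering constraint: slab at least as wide
      // pi | k ~ Beta(k, p - k + 1) truncated to [1/p, 1]
      double lo = R::pbeta(pi_min, std::max(k, 1) , p - k + 1, 1, 0);
      double u = lo + R::unif_rand() * (1.0 - lo);
      pi = R::qbeta(u, std::max(k, 1), p - k + 1, 1, 0);
      if (pi < pi_min) pi = pi_min;
      if (pi > 1.0 - 1e-12) pi = 1.0 - 1e-12;
    }

    if (step >= burn_in) {
      const int t = step - burn_in;
      // PVE of this step: var(Xb)/var(y) on the observed sample
      arma::vec fit = y - r;
      pve_chain(t) = arma::var(fit) / vy;
      ninc_chain(t) = k;
      s1_chain(t) = s1; s2_chain(t) = s2; se_chain(t) = se; pi_chain(t) = pi;
      const double split = (s2 > 0) ? s1 / s2 : 1.0;
      for (int j = 0; j < p; ++j) {
        if (delta(j) == 1) {
          alpha_sum(j) += b(j) * split;
          beta_sum(j) += b(j) * (1.0 - split);
          inc_count(j) += 1;
        } else {
          alpha_sum(j) += b(j);
        }
      }
    }
  }

  arma::vec alpha = alpha_sum / n_keep;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec gamma(p);
  for (int j = 0; j < p; ++j) {
    gamma(j) = static_cast<double>(inc_count(j)) / n_keep;
    if (inc_count(j) > 0) beta(j) = beta_sum(j) / inc_count(j);
  }

  return List::create(
      _["alpha"] = alpha, _["beta"] = beta, _["gamma"] = gamma,
      _["pve"] = pve_chain, _["n_included"] = ninc_chain,
      _["s1"] = s1_chain, _["s2"] = s2_chain, _["se"] = se_chain,
      _["pi"] = pi_chain);
}
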