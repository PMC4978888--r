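// Gibbs samplers for whole-genome marker regression.
//
// Both samplers share the linear predictor y = F a + X b + e with flat-prior
// fixed effects a (trial / maturity-group / covariate columns plus intercept)
// and marker effects b on (centered) allele dosages X. Residuals are iid
// normal. They use R's RNG, so set.seed() on the R side makes every run
// bit-reproducible.
//
// Scaled inverse chi-squared convention: chi^-2(df, S) is sampled as
// S / rchisq(df), and the full conditional of a variance with sum of squares
// SS on n draws is (S + SS) / rchisq(df + n); the prior mode is S / (df + 2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvgauss(double mu, double lambda) {
  // Michael-Schucany-Haas
  double v = norm_rand();
  double y = v * v;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static void update_fixed(const arma::mat& F, const arma::vec& ftf,
                         arma::vec& alpha, arma::vec& e, double sigma2_e) {
  for (arma::uword j = 0; j < F.n_cols; ++j) {
    double rhs = arma::dot(F.col(j), e) + ftf(j) * alpha(j);
    double mean = rhs / ftf(j);
    double newa = mean + std::sqrt(sigma2_e / ftf(j)) * norm_rand();
    e += F.col(j) * (alpha(j) - newa);
    alpha(j) = newa;
  }
}

// [[Rcpp::export(name = ".bayes_b_gibbs")]]
List bayes_b_gibbs(const arma::vec& y, const arma::mat& X, const arma::mat& F,
                   int niter, int burnin, int thin,
                   double df_b, double S_b, double pi0, double p0,
                   double df_eps, double S_eps,
                   bool pi_fixed, double pi_value) {
  RNGScope scope;
  const arma::uword n = y.n_elem, p = X.n_cols, q = F.n_cols;
  arma::vec xtx(p), ftf(q);
  for (arma::uword l = 0; l < p; ++l) xtx(l) = arma::dot(X.col(l), X.col(l));
  for (arma::uword j = 0; j < q; ++j) ftf(j) = arma::dot(F.col(j), F.col(j));
  if (xtx.min() <= 0.0) stop("constant marker column in Bayes B design");

  arma::vec b(p, arma::fill::zeros), sigma2_b(p);
  sigma2_b.fill(S_b / std::max(df_b, 1.0));
  arma::uvec delta(p, arma::fill::zeros);
  arma::vec alpha(q, arma::fill::zeros);
  double pi = pi_fixed ? pi_value : pi0;
  double sigma2_e = arma::var(y);
  if (sigma2_e <= 0) sigma2_e = 1e-6;
  arma::vec e = y - F * alpha;

  arma::vec b_sum(p, arma::fill::zeros), pip(p, arma::fill::zeros),
      alpha_sum(q, arma::fill::zeros);
  double se_sum = 0, se_sumsq = 0, pi_sum = 0;
  int nsave = 0;

  for (int it = 1; it <= niter; ++it) {
    update_fixed(F, ftf, alpha, e, sigma2_e);

    double log_prior_odds = (pi >= 1.0) ? -INFINITY
                          : (pi <= 0.0) ? INFINITY
                          : std::log1p(-pi) - std::log(pi);
    int n_in = 0;
    for (arma::uword l = 0; l < p; ++l) {
      double r = arma::dot(X.col(l), e) + xtx(l) * b(l);
      double v0 = xtx(l) * sigma2_e;
      double v1 = v0 + xtx(l) * xtx(l) * sigma2_b(l);
      double log_odds = log_prior_odds +
          0.5 * (std::log(v0 / v1) + r * r * (1.0 / v0 - 1.0 / v1));
      double prob1 = 1.0 / (1.0 + std::exp(-log_odds));
      double b_new = 0.0;
      unsigned int d_new = 0;
      if (unif_rand() < prob1) {
        d_new = 1;
        ++n_in;
        double c = xtx(l) + sigma2_e / sigma2_b(l);
        b_new = r / c + std::sqrt(sigma2_e / c) * norm_rand();
      }
      if (b(l) != b_new) e += X.col(l) * (b(l) - b_new);
      b(l) = b_new;
      delta(l) = d_new;
      // marker variance: conjugate scaled-inv-chisq (prior draw when excluded)
      double ss = d_new ? b_new * b_new : 0.0;
      sigma2_b(l) = (S_b + ss) / R::rchisq(df_b + d_new);
    }

    if (!pi_fixed) {
      // pi is the NULL proportion; beta prior with mean pi0, concentration p0
      double a_post = pi0 * p0 + (double)(p - n_in);
      double b_post = (1.0 - pi0) * p0 + (double)n_in;
      pi = R::rbeta(a_post, b_post);
    }

    sigma2_e = (S_eps + arma::dot(e, e)) / R::rchisq(df_eps + (double)n);
    if (!std::isfinite(sigma2_e) || sigma2_e <= 0.0)
      stop("divergent chain at iteration %d (non-finite residual variance)", it);

    if (it > burnin && ((it - burnin) % thin == 0)) {
      ++nsave;
      b_sum += b;
      for (arma::uword l = 0; l < p; ++l) pip(l) += delta(l);
      alpha_sum += alpha;
      se_sum += sigma2_e;
      se_sumsq += sigma2_e * sigma2_e;
      pi_sum += pi;
    }
  }
  if (nsave == 0) stop("no posterior samples saved: check iterations/burnin/thin");

  return List::create(
      _["b"] = b_sum / nsave, _["pip"] = pip / nsave,
      _["alpha"] = alpha_sum / nsave,
      _["sigma2_e"] = se_sum / nsave,
      _["sigma2_e_sd"] = std::sqrt(std::max(se_sumsq / nsave - (se_sum / nsave) * (se_sum / nsave), 0.0)),
      _["pi"] = pi_sum / nsave, _["n_saved"] = nsave);
}

// [[Rcpp::export(name = ".bayes_lasso_gibbs")]]
List bayes_lasso_gibbs(const arma::vec& y, const arma::mat& X, const arma::mat& F,
                       int niter, int burnin, int thin,
                       double lambda2_init, double lambda_shape, double lambda_rate,
                       bool lambda_fixed,
                       double df_eps, double S_eps) {
  RNGScope scope;
  const arma::uword n = y.n_elem, p = X.n_cols, q = F.n_cols;
  arma::vec xtx(p), ftf(q);
  for (arma::uword l = 0; l < p; ++l) xtx(l) = arma::dot(X.col(l), X.col(l));
  for (arma::uword j = 0; j < q; ++j) ftf(j) = arma::dot(F.col(j), F.col(j));
  if (xtx.min() <= 0.0) stop("constant marker column in Bayesian LASSO design");

  arma::vec b(p, arma::fill::zeros), tau2(p, arma::fill::ones);
  arma::vec alpha(q, arma::fill::zeros);
  double lambda2 = lambda2_init;
  double sigma2_e = arma::var(y);
  if (sigma2_e <= 0) sigma2_e = 1e-6;
  arma::vec e = y - F * alpha;

  arma::vec b_sum(p, arma::fill::zeros), alpha_sum(q, arma::fill::zeros);
  double se_sum = 0, se_sumsq = 0, l2_sum = 0;
  int nsave = 0;

  for (int it = 1; it <= niter; ++it) {
    update_fixed(F, ftf, alpha, e, sigma2_e);

    // marker effects: b_l | tau2_l ~ N(0, tau2_l * sigma2_e) (Park-Casella)
    for (arma::uword l = 0; l < p; ++l) {
      double r = arma::dot(X.col(l), e) + xtx(l) * b(l);
      double c = xtx(l) + 1.0 / tau2(l);
      double b_new = r / c + std::sqrt(sigma2_e / c) * norm_rand();
      e += X.col(l) * (b(l) - b_new);
      b(l) = b_new;
      // 1/tau2_l | . ~ inverse-Gaussian(sqrt(lambda2 sigma2_e / b^2), lambda2)
      double b2 = b_new * b_new;
      if (b2 < 1e-12) b2 = 1e-12;
      double inv_tau2 = rinvgauss(std::sqrt(lambda2 * sigma2_e / b2), lambda2);
      tau2(l) = 1.0 / std::max(inv_tau2, 1e-12);
    }

    if (!lambda_fixed) {
      lambda2 = R::rgamma(lambda_shape + (double)p,
                          1.0 / (lambda_rate + 0.5 * arma::accu(tau2)));
      if (lambda2 < 1e-10) lambda2 = 1e-10;
    }

    double ss_b = 0.0;
    for (arma::uword l = 0; l < p; ++l) ss_b += b(l) * b(l) / tau2(l);
    sigma2_e = (S_eps + arma::dot(e, e) + ss_b) /
               R::rchisq(df_eps + (double)n + (double)p);
    if (!std::isfinite(sigma2_e) || sigma2_e <= 0.0)
      stop("divergent chain at iteration %d (non-finite residual variance)", it);

    if (it > burnin && ((it - burnin) % thin == 0)) {
      ++nsave;
      b_sum += b;
      alpha_sum += alpha;
      se_sum += sigma2_e;
      se_sumsq += sigma2_e * sigma2_e;
      l2_sum += lambda2;
    }
  }
  if (nsave == 0) stop("no posterior samples saved: check iterations/burnin/thin");

  return List::create(
      _["b"] = b_sum / nsave, _["alpha"] = alpha_sum / nsave,
      _["sigma2_e"] = se_sum / nsave,
      _["sigma2_e_sd"] = std::sqrt(std::max(se_sumsq / nsave - (se_sum / nsave) * (se_sum / nsave), 0.0)),
      _["lambda2"] = l2_sum / nsave, _["n_saved"] = nsave);
}
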