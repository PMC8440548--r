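// Blocked Gibbs sampler for the Gaussian mixed model
//   y = W theta + e,  theta = (beta, u_1, ..., u_B)
//   u_j ~ N(0, sigma2_j * K_j^{-1})   (K_j is a precision structure,
//                                      e.g. C^{-1} for a phylogenetic block,
//                                      I for an iid species block)
//   e   ~ N(0, sigma2_e * I)
// beta gets a vague normal prior (precision `beta_prec`); all variances get
// inverse-gamma(shape, rate) priors.  (beta, u) are drawn jointly from their
// multivariate-normal full conditional via Cholesky of the mixed-model
// equations; variances from their conjugate inverse-gamma conditionals.
// Uses R's RNG throughout so set.seed() in R controls reproducibility.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // X ~ Gamma(shape, rate) => 1/X ~ InvGamma(shape, rate)
  double g = R::rgamma(shape, 1.0 / rate);
  return 1.0 / g;
}

// [[Rcpp::export(name = ".gibbs_lmm_cpp")]]
List gibbs_lmm_cpp(const arma::vec& y_in,
                   const arma::mat& W,
                   const int p_fixed,
                   const List& block_prec,     // list of precision matrices K_j
                   const arma::vec& prior_shape, // per block, then residual last
                   const arma::vec& prior_rate,
                   const double beta_prec,
                   const int n_iter,
                   const int n_burnin,
                   const int thin,
                   const arma::vec& init_sigma2, // blocks then residual
                   const bool redraw_y) {
  const int n = y_in.n_elem;
  const int q = W.n_cols;
  const int B = block_prec.size();

  std::vector<arma::mat> K(B);
  arma::uvec bstart(B), bsize(B);
  int pos = p_fixed;
  for (int j = 0; j < B; ++j) {
    K[j] = as<arma::mat>(block_prec[j]);
    bstart(j) = pos;
    bsize(j) = K[j].n_rows;
    pos += K[j].n_rows;
  }
  if (pos != q) stop("design columns do not match fixed + random block sizes");

  arma::vec y = y_in;
  arma::mat WtW = W.t() * W;
  arma::vec Wty = W.t() * y;

  arma::vec sigma2 = init_sigma2;  // length B + 1, residual last
  if (sigma2.n_elem != (unsigned)(B + 1)) stop("init_sigma2 must have one entry per block plus residual");

  const int n_keep = (n_iter - n_burnin) / thin;
  if (n_keep < 1) stop("no retained draws: check n_iter, n_burnin, thin");
  arma::mat theta_draws(n_keep, q);
  arma::mat sigma2_draws(n_keep, B + 1);
  arma::vec var_fixed(n_keep);
  arma::vec deviance(n_keep);

  arma::vec theta(q, arma::fill::zeros);
  const double log2pi = std::log(2.0 * M_PI);
  int keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- (beta, u) | sigma2, y ---
    arma::mat P = WtW / sigma2(B);
    for (int k = 0; k < p_fixed; ++k) P(k, k) += beta_prec;
    for (int j = 0; j < B; ++j) {
      P.submat(bstart(j), bstart(j), bstart(j) + bsize(j) - 1,
               bstart(j) + bsize(j) - 1) += K[j] / sigma2(j);
    }
    arma::vec b = Wty / sigma2(B);
    arma::mat U;
    bool ok = arma::chol(U, P);
    if (!ok) { // numerical rescue: small ridge
      P.diag() += 1e-8 * arma::max(P.diag());
      if (!arma::chol(U, P)) stop("Cholesky of full-conditional precision failed");
    }
    arma::vec mu = arma::solve(arma::trimatu(U),
                               arma::solve(arma::trimatl(U.t()), b));
    arma::vec z(q);
    for (int k = 0; k < q; ++k) z(k) = R::norm_rand();
    theta = mu + arma::solve(arma::trimatu(U), z);

    // --- variance components ---
    for (int j = 0; j < B; ++j) {
      arma::vec uj = theta.subvec(bstart(j), bstart(j) + bsize(j) - 1);
      double quad = arma::as_scalar(uj.t() * K[j] * uj);
      sigma2(j) = rinvgamma(prior_shape(j) + 0.5 * bsize(j),
                            prior_rate(j) + 0.5 * quad);
    }
    arma::vec resid = y - W * theta;
    double rss = arma::dot(resid, resid);
    sigma2(B) = rinvgamma(prior_shape(B) + 0.5 * n, prior_rate(B) + 0.5 * rss);
    if (!sigma2.is_finite()) stop("divergent variance draw (non-finite); check data scaling and priors");

    if (redraw_y) { // successive-conditional simulator for sampler validation
      arma::vec eta = W * theta;
      double sde = std::sqrt(sigma2(B));
      for (int i = 0; i < n; ++i) y(i) = eta(i) + sde * R::norm_rand();
      Wty = W.t() * y;
    }

    if (it >= n_burnin && ((it - n_burnin) % thin == 0) && keep < n_keep) {
      theta_draws.row(keep) = theta.t();
      sigma2_draws.row(keep) = sigma2.t();
      arma::vec eta_fixed = W.cols(0, p_fixed - 1) * theta.subvec(0, p_fixed - 1);
      var_fixed(keep) = p_fixed > 1 ? arma::var(eta_fixed) : 0.0;
      arma::vec r = y - W * theta;
      deviance(keep) = n * (log2pi + std::log(sigma2(B))) +
                       arma::dot(r, r) / sigma2(B);
      ++keep;
    }
  }

  return List::create(
    Named("theta") = theta_draws,
    Named("sigma2") = sigma2_draws,
    Named("var_fixed") = var_fixed,
    Named("deviance") = deviance,
    Named("y_final") = y);
}
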