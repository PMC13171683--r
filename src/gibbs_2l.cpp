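#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Kasim-Raudenbush Gibbs sweeps for the two-level normal imputation
// model with heterogeneous within-cluster variances. All randomness is
// pre-drawn in R (z_beta, z_delta, chi_sigma, chi_tau), so the result
// is a pure function of R's RNG stream and agrees with the reference
// R loop to floating-point accuracy. Per-cluster sufficient statistics are precomputed
// by the caller over the observed rows (column 1 of X is the
// intercept):
//   gmat   (J x p*p)  row j = vec(X_j' X_j)
//   xty    (J x p)    row j = X_j' y_j
//   yty_j  (J)        sum of squared y per cluster
//   n_j    (J)        observed rows per cluster
// [[Rcpp::export(name = ".gibbs_2l_run")]]
Rcpp::List gibbs_2l_run(const arma::mat& gmat,
                        const arma::mat& xty,
                        const arma::vec& yty_j,
                        const arma::vec& n_j,
                        const arma::mat& z_beta,
                        const arma::mat& z_delta,
                        const arma::mat& chi_sigma,
                        const arma::vec& chi_tau,
                        const arma::vec& beta_init,
                        double sigma2_pool) {
  const int n_sweeps = z_beta.n_cols;
  const int J = gmat.n_rows;
  const int p = xty.n_cols;
  const uvec has_obs = find(n_j > 0.5);
  const vec sum_y = xty.col(0);
  const mat cs = gmat.cols(0, p - 1);  // X_j' 1

  vec beta = beta_init;
  vec delta(J, fill::zeros);
  vec sigma2(J, fill::value(sigma2_pool));
  double tau2 = 1.0;
  const mat gmat_t = gmat.t();  // p*p x J, reused every sweep
  const mat xty_t = xty.t();    // p x J
  const mat cs_t = cs.t();      // p x J

  for (int s = 0; s < n_sweeps; ++s) {
    // fixed effects | delta, sigma2_j: weighted least squares draw
    vec w(J, fill::zeros);
    for (uword k = 0; k < has_obs.n_elem; ++k) {
      uword j = has_obs(k);
      w(j) = 1.0 / sigma2(j);
    }
    mat a = reshape(gmat_t * w, p, p);
    vec bvec = xty_t * w - cs_t * (w % delta);
    mat ch = chol(a, "upper");
    vec mean_b = solve(trimatu(ch), solve(trimatl(ch.t()), bvec));
    beta = mean_b + solve(trimatu(ch), z_beta.col(s));
    // cluster intercepts | beta, sigma2_j, tau2
    vec resj = sum_y - cs * beta;
    vec prec = n_j / sigma2 + 1.0 / tau2;
    delta = (resj / sigma2) / prec + z_delta.col(s) / sqrt(prec);
    // per-cluster residual variances | beta, delta (vague priors)
    vec quad = gmat * vectorise(beta * beta.t());
    vec ss = yty_j - 2.0 * (xty * beta) + quad - 2.0 * (delta % resj) +
      n_j % square(delta);
    sigma2 = clamp(ss, 1e-10, datum::inf) / chi_sigma.col(s);
    // intercept variance | delta (clusters with observed rows)
    double sd2 = 0.0;
    for (uword k = 0; k < has_obs.n_elem; ++k) {
      double d = delta(has_obs(k));
      sd2 += d * d;
    }
    tau2 = std::max(sd2, 1e-10) / chi_tau(s);
    // clusters without observed rows keep the pooled variance
    for (uword j = 0; j < (uword)J; ++j) {
      if (n_j(j) < 0.5) sigma2(j) = sigma2_pool;
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("delta") = delta,
                            Rcpp::Named("sigma2") = sigma2,
                            Rcpp::Named("tau2") = tau2);
}
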