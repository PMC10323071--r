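// Adaptive blockwise random-walk Metropolis sampler for the spatial TOPALS
// Poisson model. One block = one area's offset vector. Proposal scales adapt
// toward a 0.3 acceptance rate during burn-in and are frozen afterwards.
// Uses R's RNG stream so set.seed() in R governs reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// likelihood terms that depend on alpha_a:
//   sum_x [ D(a,x) * eta(x) - base(a,x) * exp(eta(x)) ],  eta = B * alpha_a
// where base(a,x) = N(a,x) * m_std(x), zero where N == 0 (excluded strata).
static double local_loglik(const arma::rowvec& Drow,
                           const arma::rowvec& baserow,
                           const arma::mat& B,
                           const arma::rowvec& alpha) {
  arma::vec eta = B * alpha.t();
  double ll = arma::dot(Drow.t(), eta) - arma::dot(baserow.t(), arma::exp(eta));
  return ll;
}

// [[Rcpp::export]]
List topals_mcmc_cpp(const arma::mat& D, const arma::mat& N,
                     const arma::mat& B, const arma::vec& log_std,
                     const arma::imat& edges,
                     double tau_spatial, double tau_shape,
                     int iterations, int burn_in, int thin,
                     double init_scale, bool sample_tau) {
  const int nA = D.n_rows, nX = D.n_cols, K = B.n_cols;
  const int nE = edges.n_rows;
  const int n_draws = (iterations - burn_in) / thin;

  arma::mat base = N;
  for (int x = 0; x < nX; ++x) base.col(x) *= std::exp(log_std(x));

  // neighbor lists (edges are 1-based from R)
  std::vector< std::vector<int> > nbr(nA);
  for (int e = 0; e < nE; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    nbr[i].push_back(j);
    nbr[j].push_back(i);
  }

  arma::mat alpha(nA, K, arma::fill::zeros);
  arma::vec cur_ll(nA);
  for (int a = 0; a < nA; ++a)
    cur_ll(a) = local_loglik(D.row(a), base.row(a), B, alpha.row(a));

  arma::vec scale(nA); scale.fill(init_scale);
  arma::vec acc_batch(nA, arma::fill::zeros);
  arma::vec acc_post(nA, arma::fill::zeros);
  const int batch_len = 50;
  int batch_count = 0, post_iters = 0;

  std::vector<double> draws((size_t)n_draws * nA * K);
  std::vector<double> tau_draws;
  if (sample_tau) tau_draws.resize((size_t)n_draws * 2);

  double ts = tau_spatial, th = tau_shape;
  bool finite_ok = true;
  int stored = 0;

  for (int iter = 1; iter <= iterations && finite_ok; ++iter) {
    for (int a = 0; a < nA; ++a) {
      arma::rowvec prop = alpha.row(a);
      for (int k = 0; k < K; ++k) prop(k) += scale(a) * norm_rand();

      double ll_new = local_loglik(D.row(a), base.row(a), B, prop);
      if (!std::isfinite(ll_new)) continue;  // reject wild proposals

      // spatial penalty delta for block a
      double pen_old = 0.0, pen_new = 0.0;
      for (size_t t = 0; t < nbr[a].size(); ++t) {
        int b = nbr[a][t];
        pen_old += arma::accu(arma::square(alpha.row(a) - alpha.row(b)));
        pen_new += arma::accu(arma::square(prop - alpha.row(b)));
      }
      // within-area shape penalty delta
      double sh_old = 0.0, sh_new = 0.0;
      for (int k = 0; k + 1 < K; ++k) {
        sh_old += std::pow(alpha(a, k + 1) - alpha(a, k), 2);
        sh_new += std::pow(prop(k + 1) - prop(k), 2);
      }
      double delta = (ll_new - cur_ll(a))
        - ts / 2.0 * (pen_new - pen_old)
        - th / 2.0 * (sh_new - sh_old);
      if (!std::isfinite(delta)) { finite_ok = false; break; }
      if (std::log(unif_rand()) < delta) {
        alpha.row(a) = prop;
        cur_ll(a) = ll_new;
        acc_batch(a) += 1.0;
        if (iter > burn_in) acc_post(a) += 1.0;
      }
    }
    if (!finite_ok) break;

    if (sample_tau) {
      double ss_sp = 0.0;
      for (int e = 0; e < nE; ++e)
        ss_sp += arma::accu(arma::square(alpha.row(edges(e, 0) - 1) -
                                         alpha.row(edges(e, 1) - 1)));
      double ss_sh = 0.0;
      for (int a = 0; a < nA; ++a)
        for (int k = 0; k + 1 < K; ++k)
          ss_sh += std::pow(alpha(a, k + 1) - alpha(a, k), 2);
      // Gamma(2, rate 0.5) hyperprior; conditional is Gamma(shape, rate)
      ts = R::rgamma(2.0 + nE * K / 2.0, 1.0 / (0.5 + ss_sp / 2.0));
      th = R::rgamma(2.0 + nA * (K - 1) / 2.0, 1.0 / (0.5 + ss_sh / 2.0));
      // area likelihoods unchanged; only prior precisions moved
    }

    if (iter > burn_in) ++post_iters;

    // Robbins-Monro scale adaptation, frozen at the end of burn-in
    if (iter <= burn_in && iter % batch_len == 0) {
      ++batch_count;
      double gamma = 1.0 / std::sqrt((double)batch_count);
      for (int a = 0; a < nA; ++a) {
        double rate = acc_batch(a) / batch_len;
        scale(a) *= std::exp(gamma * (rate - 0.3));
      }
      acc_batch.zeros();
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0 && stored < n_draws) {
      for (int k = 0; k < K; ++k)
        for (int a = 0; a < nA; ++a)
          draws[(size_t)stored + (size_t)n_draws * a +
                (size_t)n_draws * nA * k] = alpha(a, k);
      if (sample_tau) {
        tau_draws[stored] = ts;
        tau_draws[stored + (size_t)n_draws] = th;
      }
      ++stored;
    }
  }

  arma::vec acc_rate = post_iters > 0 ? arma::vec(acc_post / post_iters)
                                      : arma::vec(nA, arma::fill::zeros);
  return List::create(
    _["alpha"] = draws,
    _["acceptance"] = acc_rate,
    _["tau"] = tau_draws,
    _["last_alpha"] = alpha,
    _["finite"] = finite_ok,
    _["scales"] = scale);
}
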