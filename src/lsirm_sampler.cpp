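// Metropolis-Hastings-within-Gibbs sampler for the latent space item
// response model
//
//   logit P(y_ki = 1) = beta_i + theta_k - ||w_i - z_k||
//
// with priors beta_i ~ N(0, tau_beta_sq), theta_k ~ N(0, sigma_sq),
// sigma_sq ~ Inv-Gamma(a_sigma, b_sigma), w_i, z_k ~ MVN(0, I_d).
//
// beta, theta and the rows of W and Z get Gaussian random-walk updates
// (one proposal scale per block, optionally adapted during burn-in);
// sigma_sq gets an exact conjugate Gibbs draw; missing cells are
// re-imputed each sweep from their Bernoulli full conditional.
//
// All randomness goes through R's RNG so chains are reproducible from
// set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double inv_logit_(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// sigma_sq | theta ~ Inv-Gamma(a + N/2, b + sum(theta^2)/2); this exact
// function is the sampler's conjugate update, exported so the update can
// be checked against the analytic full conditional.
static inline double draw_sigma_sq_(const arma::vec& theta,
                                    double a_sigma, double b_sigma) {
  double shape = a_sigma + 0.5 * theta.n_elem;
  double rate  = b_sigma + 0.5 * arma::dot(theta, theta);
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".cpp_sigma_sq_draws")]]
NumericVector cpp_sigma_sq_draws(NumericVector theta, double a_sigma,
                                 double b_sigma, int n_draws) {
  arma::vec th(theta.begin(), theta.size(), false);
  NumericVector out(n_draws);
  for (int s = 0; s < n_draws; ++s) out[s] = draw_sigma_sq_(th, a_sigma, b_sigma);
  return out;
}

// Full log posterior of the current (augmented) state, with all
// normalizing constants, so MAP selection across draws is well defined.
static double log_posterior_(const arma::imat& y, const arma::vec& beta,
                             const arma::vec& theta, double sigma_sq,
                             const arma::mat& W, const arma::mat& Z,
                             const arma::mat& D, double tau_beta_sq,
                             double a_sigma, double b_sigma) {
  const int N = y.n_rows, P = y.n_cols, d = W.n_cols;
  double lp = 0.0;
  for (int i = 0; i < P; ++i) {
    for (int k = 0; k < N; ++k) {
      double eta = beta[i] + theta[k] - D(k, i);
      lp += y(k, i) * eta - log1pexp_(eta);
    }
  }
  for (int i = 0; i < P; ++i)
    lp += R::dnorm(beta[i], 0.0, std::sqrt(tau_beta_sq), 1);
  for (int k = 0; k < N; ++k)
    lp += R::dnorm(theta[k], 0.0, std::sqrt(sigma_sq), 1);
  lp += a_sigma * std::log(b_sigma) - R::lgammafn(a_sigma) -
        (a_sigma + 1.0) * std::log(sigma_sq) - b_sigma / sigma_sq;
  const double ldn = -0.5 * std::log(2.0 * M_PI);
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < d; ++j)
      lp += ldn - 0.5 * W(i, j) * W(i, j);
  for (int k = 0; k < N; ++k)
    for (int j = 0; j < d; ++j)
      lp += ldn - 0.5 * Z(k, j) * Z(k, j);
  return lp;
}

// [[Rcpp::export(name = ".cpp_lsirm_mcmc")]]
List cpp_lsirm_mcmc(IntegerMatrix y_obs, int d, double tau_beta_sq,
                    double a_sigma, double b_sigma, int n_iter, int burnin,
                    int thin, NumericVector jump, bool adapt,
                    NumericVector beta_init, NumericVector theta_init,
                    double sigma_sq_init, NumericMatrix W_init,
                    NumericMatrix Z_init) {
  const int N = y_obs.nrow(), P = y_obs.ncol();
  arma::vec beta(beta_init.begin(), P);
  arma::vec theta(theta_init.begin(), N);
  double sigma_sq = sigma_sq_init;
  arma::mat W(W_init.begin(), P, d);
  arma::mat Z(Z_init.begin(), N, d);

  // working copy of the data; missing cells are imputed each sweep
  arma::imat y(N, P);
  std::vector<int> miss_k, miss_i;
  for (int i = 0; i < P; ++i) {
    for (int k = 0; k < N; ++k) {
      int v = y_obs(k, i);
      if (v == NA_INTEGER) {
        miss_k.push_back(k);
        miss_i.push_back(i);
        y(k, i) = 0;  // overwritten by the first imputation sweep
      } else {
        y(k, i) = v;
      }
    }
  }
  const int M = (int)miss_k.size();

  arma::mat D(N, P);
  for (int i = 0; i < P; ++i)
    for (int k = 0; k < N; ++k)
      D(k, i) = arma::norm(Z.row(k) - W.row(i), 2);

  double jb = jump[0], jt = jump[1], jw = jump[2], jz = jump[3];

  const int n_keep = (n_iter - burnin) / thin;
  arma::mat beta_draws(n_keep, P), theta_draws(n_keep, N);
  arma::vec sigma_draws(n_keep), lp_draws(n_keep);
  arma::cube W_draws(P, d, n_keep), Z_draws(N, d, n_keep);
  IntegerMatrix imp_draws(M > 0 ? n_keep : 0, M);

  // acceptance bookkeeping: window counts (adaptation), post-burn-in totals
  const int win = 50;
  long wb = 0, wt = 0, ww = 0, wz = 0;           // window accepts
  long ab = 0, at = 0, aw = 0, az = 0;           // post-burn-in accepts
  long nb = 0, nt = 0, nw = 0, nz = 0;           // post-burn-in proposals

  arma::vec dnew(N), dznew(P), wprop(d), zprop(d);
  int keep = 0;

  for (int t = 1; t <= n_iter; ++t) {
    const bool post = t > burnin;

    // --- data augmentation for missing responses ---------------------
    for (int m = 0; m < M; ++m) {
      int k = miss_k[m], i = miss_i[m];
      double p = inv_logit_(beta[i] + theta[k] - D(k, i));
      y(k, i) = (unif_rand() < p) ? 1 : 0;
    }

    // --- beta: per-item random walk ----------------------------------
    for (int i = 0; i < P; ++i) {
      double bp = beta[i] + jb * norm_rand();
      double delta = 0.0;
      for (int k = 0; k < N; ++k) {
        double eta = theta[k] - D(k, i);
        delta += y(k, i) * (bp - beta[i]) -
                 log1pexp_(bp + eta) + log1pexp_(beta[i] + eta);
      }
      delta += (beta[i] * beta[i] - bp * bp) / (2.0 * tau_beta_sq);
      if (std::log(unif_rand()) < delta) {
        beta[i] = bp;
        ++wb;
        if (post) ++ab;
      }
      if (post) ++nb;
    }

    // --- theta: per-respondent random walk ---------------------------
    for (int k = 0; k < N; ++k) {
      double tp = theta[k] + jt * norm_rand();
      double delta = 0.0;
      for (int i = 0; i < P; ++i) {
        double eta = beta[i] - D(k, i);
        delta += y(k, i) * (tp - theta[k]) -
                 log1pexp_(tp + eta) + log1pexp_(theta[k] + eta);
      }
      delta += (theta[k] * theta[k] - tp * tp) / (2.0 * sigma_sq);
      if (std::log(unif_rand()) < delta) {
        theta[k] = tp;
        ++wt;
        if (post) ++at;
      }
      if (post) ++nt;
    }

    // --- W rows: random walk in R^d ----------------------------------
    for (int i = 0; i < P; ++i) {
      double pr_old = 0.0, pr_new = 0.0;
      for (int j = 0; j < d; ++j) {
        wprop[j] = W(i, j) + jw * norm_rand();
        pr_old += W(i, j) * W(i, j);
        pr_new += wprop[j] * wprop[j];
      }
      double delta = 0.5 * (pr_old - pr_new);
      for (int k = 0; k < N; ++k) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = Z(k, j) - wprop[j];
          s += diff * diff;
        }
        double dn = std::sqrt(s);
        double eta_new = beta[i] + theta[k] - dn;
        double eta_old = beta[i] + theta[k] - D(k, i);
        delta += y(k, i) * (eta_new - eta_old) -
                 log1pexp_(eta_new) + log1pexp_(eta_old);
        dnew[k] = dn;
      }
      if (std::log(unif_rand()) < delta) {
        for (int j = 0; j < d; ++j) W(i, j) = wprop[j];
        D.col(i) = dnew;
        ++ww;
        if (post) ++aw;
      }
      if (post) ++nw;
    }

    // --- Z rows: random walk in R^d ----------------------------------
    for (int k = 0; k < N; ++k) {
      double pr_old = 0.0, pr_new = 0.0;
      for (int j = 0; j < d; ++j) {
        zprop[j] = Z(k, j) + jz * norm_rand();
        pr_old += Z(k, j) * Z(k, j);
        pr_new += zprop[j] * zprop[j];
      }
      double delta = 0.5 * (pr_old - pr_new);
      for (int i = 0; i < P; ++i) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = zprop[j] - W(i, j);
          s += diff * diff;
        }
        double dn = std::sqrt(s);
        double eta_new = beta[i] + theta[k] - dn;
        double eta_old = beta[i] + theta[k] - D(k, i);
        delta += y(k, i) * (eta_new - eta_old) -
                 log1pexp_(eta_new) + log1pexp_(eta_old);
        dznew[i] = dn;
      }
      if (std::log(unif_rand()) < delta) {
        for (int j = 0; j < d; ++j) Z(k, j) = zprop[j];
        D.row(k) = dznew.t();
        ++wz;
        if (post) ++az;
      }
      if (post) ++nz;
    }

    // --- sigma_sq: conjugate Gibbs -----------------------------------
    sigma_sq = draw_sigma_sq_(theta, a_sigma, b_sigma);

    // --- proposal adaptation during burn-in --------------------------
    if (adapt && !post && (t % win == 0)) {
      double rb = (double)wb / (win * (double)P);
      double rt = (double)wt / (win * (double)N);
      double rw = (double)ww / (win * (double)P);
      double rz = (double)wz / (win * (double)N);
      if (rb < 0.23 || rb > 0.44) jb *= std::exp(rb - 0.335);
      if (rt < 0.23 || rt > 0.44) jt *= std::exp(rt - 0.335);
      if (rw < 0.23 || rw > 0.44) jw *= std::exp(rw - 0.335);
      if (rz < 0.23 || rz > 0.44) jz *= std::exp(rz - 0.335);
      wb = wt = ww = wz = 0;
    }

    // --- retention ---------------------------------------------------
    if (post && ((t - burnin) % thin == 0)) {
      double lp = log_posterior_(y, beta, theta, sigma_sq, W, Z, D,
                                 tau_beta_sq, a_sigma, b_sigma);
      if (!std::isfinite(lp))
        stop("non-finite log-posterior at iteration %d", t);
      beta_draws.row(keep) = beta.t();
      theta_draws.row(keep) = theta.t();
      sigma_draws[keep] = sigma_sq;
      lp_draws[keep] = lp;
      W_draws.slice(keep) = W;
      Z_draws.slice(keep) = Z;
      for (int m = 0; m < M; ++m) imp_draws(keep, m) = y(miss_k[m], miss_i[m]);
      ++keep;
    }
  }

  NumericVector acc = NumericVector::create(
      _["beta"] = nb ? (double)ab / nb : NA_REAL,
      _["theta"] = nt ? (double)at / nt : NA_REAL,
      _["w"] = nw ? (double)aw / nw : NA_REAL,
      _["z"] = nz ? (double)az / nz : NA_REAL);
  NumericVector jumps = NumericVector::create(
      _["beta"] = jb, _["theta"] = jt, _["w"] = jw, _["z"] = jz);
  IntegerMatrix miss_idx(M, 2);
  for (int m = 0; m < M; ++m) {
    miss_idx(m, 0) = miss_k[m] + 1;  // 1-based for R
    miss_idx(m, 1) = miss_i[m] + 1;
  }

  return List::create(
      _["beta"] = wrap(beta_draws), _["theta"] = wrap(theta_draws),
      _["sigma_sq"] = wrap(sigma_draws), _["log_posterior"] = wrap(lp_draws),
      _["W"] = wrap(W_draws), _["Z"] = wrap(Z_draws),
      _["imputed"] = imp_draws, _["missing_index"] = miss_idx,
      _["acceptance"] = acc, _["jumps"] = jumps);
}
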