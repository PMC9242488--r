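#' Prior hyperparameters for the latent space item response model
#'
#' The model priors are beta_i ~ N(0, tau_beta_sq) for the item easiness
#' intercepts, theta_k ~ N(0, sigma_sq) for the respondent traits with a
#' conjugate sigma_sq ~ Inv-Gamma(a_sigma, b_sigma) hyperprior, and standard
#' multivariate normal MVN(0, I_d) priors on the item and respondent
#' positions.
#'
#' @param tau_beta_sq prior variance of the item intercepts (> 0).
#' @param a_sigma,b_sigma inverse-gamma shape and scale of the trait
#'   variance (> 0).
#' @return A list of class `"lsirm_hyper"`.
#' @export
lsirm_hyper <- function(tau_beta_sq = 4, a_sigma = 1, b_sigma = 1) {
  stopifnot(tau_beta_sq > 0, a_sigma > 0, b_sigma > 0)
  structure(list(tau_beta_sq = tau_beta_sq, a_sigma = a_sigma,
                 b_sigma = b_sigma), class = "lsirm_hyper")
}

#' Sampler settings for [lsirm()]
#'
#' Defaults follow the usual long-chain practice for this model: 30000
#' sweeps, the first 5000 discarded as burn-in, every 5th retained sweep
#' kept, giving 5000 posterior draws.
#'
#' @param n_iter total MCMC sweeps.
#' @param burnin sweeps discarded (must be < `n_iter`).
#' @param thin keep every `thin`-th post-burn-in sweep; `(n_iter - burnin)`
#'   must be divisible by `thin`.
#' @param jump_beta,jump_theta,jump_w,jump_z initial Gaussian random-walk
#'   proposal standard deviations per block.
#' @param adapt tune the proposal scales during burn-in toward a 0.23-0.44
#'   acceptance band (frozen afterward)?
#' @return A list of class `"lsirm_control"`.
#' @export
lsirm_control <- function(n_iter = 30000, burnin = 5000, thin = 5,
                          jump_beta = 0.3, jump_theta = 0.5, jump_w = 0.2,
                          jump_z = 0.3, adapt = TRUE) {
  stopifnot(n_iter >= 1, burnin >= 0, burnin < n_iter, thin >= 1,
            jump_beta > 0, jump_theta > 0, jump_w > 0, jump_z > 0)
  if ((n_iter - burnin) %% thin != 0)
    stop("(n_iter - burnin) must be divisible by thin", call. = FALSE)
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin,
                 jump_beta = jump_beta, jump_theta = jump_theta,
                 jump_w = jump_w, jump_z = jump_z, adapt = adapt),
            class = "lsirm_control")
}

#' Success probability of the latent space item response model
#'
#' The model states `logit P(y_ki = 1) = beta_i + theta_k - ||w_i - z_k||`
#' with a Euclidean norm and the distance weight fixed at one: response
#' probability rises with item easiness and respondent trait and falls
#' strictly with the item-respondent distance in the interaction map.
#' Arguments recycle, so matrices of probabilities can be built from
#' parameter vectors and position matrices.
#'
#' @param beta item easiness intercept(s).
#' @param theta respondent trait(s).
#' @param w,z item and respondent positions: d-vectors or (n x d) matrices
#'   with matching d.
#' @return Probabilities in (0, 1).
#' @export
success_probability <- function(beta, theta, w, z) {
  w <- rbind(w)
  z <- rbind(z)
  if (ncol(w) != ncol(z))
    stop("item and respondent positions must share the same latent dimension",
         call. = FALSE)
  n <- max(nrow(w), nrow(z))
  w <- w[rep_len(seq_len(nrow(w)), n), , drop = FALSE]
  z <- z[rep_len(seq_len(nrow(z)), n), , drop = FALSE]
  dist <- sqrt(rowSums((w - z)^2))
  unname(stats::plogis(beta + theta - dist))
}

# N x P matrix of ||w_i - z_k|| distances
latent_distances <- function(W, Z) {
  cw <- rowSums(W^2)
  cz <- rowSums(Z^2)
  d2 <- outer(cz, cw, "+") - 2 * tcrossprod(Z, W)
  sqrt(pmax(d2, 0))
}

#' Bernoulli log-likelihood of the latent space item response model
#'
#' Sum of `y log p + (1 - y) log(1 - p)` over non-missing cells, with `p`
#' from [success_probability()].  Missing cells contribute nothing unless
#' `imputed` supplies values for them.
#'
#' @param beta length-P item intercepts.
#' @param theta length-N respondent traits.
#' @param W P x d item positions.
#' @param Z N x d respondent positions.
#' @param y N x P binary matrix, `NA` for missing; or a [response_matrix()].
#' @param imputed optional vector of 0/1 values for the missing cells, in
#'   column-major order of `which(is.na(y))`.
#' @return Scalar log-likelihood.
#' @export
lsirm_log_likelihood <- function(beta, theta, W, Z, y, imputed = NULL) {
  if (inherits(y, "response_matrix")) y <- y$values
  y <- as.matrix(y)
  W <- rbind(W); Z <- rbind(Z)
  if (length(beta) != ncol(y) || length(theta) != nrow(y) ||
      nrow(W) != ncol(y) || nrow(Z) != nrow(y) || ncol(W) != ncol(Z))
    stop("parameter shapes inconsistent with the data", call. = FALSE)
  if (any(!is.na(y) & !(y %in% c(0, 1))))
    stop("observed responses must be 0, 1 or NA", call. = FALSE)
  if (!is.null(imputed)) {
    miss <- which(is.na(y))
    stopifnot(length(imputed) == length(miss))
    y[miss] <- imputed
  }
  eta <- outer(theta, beta, "+") - latent_distances(W, Z)
  ll <- y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0)
  sum(ll[!is.na(y)])
}

#' Log posterior density of the latent space item response model
#'
#' [lsirm_log_likelihood()] plus the log prior densities of all parameters
#' (normal priors on `beta` and `theta`, inverse-gamma on `sigma_sq`,
#' standard normal on every position coordinate), with all normalizing
#' constants included so values are comparable across draws.
#'
#' @inheritParams lsirm_log_likelihood
#' @param sigma_sq trait variance (> 0).
#' @param hyper an [lsirm_hyper()].
#' @return Scalar log posterior (unnormalized in the data).
#' @export
lsirm_log_posterior <- function(beta, theta, sigma_sq, W, Z, y,
                                hyper = lsirm_hyper(), imputed = NULL) {
  if (sigma_sq <= 0) stop("sigma_sq must be positive", call. = FALSE)
  W <- rbind(W); Z <- rbind(Z)
  ll <- lsirm_log_likelihood(beta, theta, W, Z, y, imputed)
  lp <- sum(stats::dnorm(beta, 0, sqrt(hyper$tau_beta_sq), log = TRUE)) +
    sum(stats::dnorm(theta, 0, sqrt(sigma_sq), log = TRUE)) +
    hyper$a_sigma * log(hyper$b_sigma) - lgamma(hyper$a_sigma) -
    (hyper$a_sigma + 1) * log(sigma_sq) - hyper$b_sigma / sigma_sq +
    sum(stats::dnorm(W, log = TRUE)) + sum(stats::dnorm(Z, log = TRUE))
  ll + lp
}

#' Fit the latent space item response model
#'
#' Bayesian fit of the two-parameter latent space item response model by
#' Metropolis-Hastings-within-Gibbs sampling: Gaussian random-walk updates
#' for the item intercepts, respondent traits and the item/respondent
#' positions (proposal scales adapted during burn-in), an exact conjugate
#' inverse-gamma Gibbs draw for the trait variance, and Bernoulli
#' re-imputation of missing responses at the current parameters in every
#' sweep (Bayesian data augmentation under missingness at random).
#'
#' Latent positions are only identified up to rotation, reflection and
#' translation; by default the retained draws are Procrustes-aligned to the
#' maximum-a-posteriori draw (see [procrustes_align()]) before posterior
#' means are formed, so position summaries are meaningful.
#'
#' @param data a [response_matrix()] or plain binary matrix (`NA` missing).
#'   Needs at least 2 respondents and 2 items; every row and column must
#'   contain at least one observed response (a fully missing matrix is also
#'   accepted and then explores the prior through the augmentation).
#' @param d latent space dimension (default 2).
#' @param hyper an [lsirm_hyper()].
#' @param control an [lsirm_control()].
#' @param seed integer seed; the fit is bit-reproducible given `seed`.
#' @param align Procrustes-align the chain to the MAP draw (recommended)?
#' @return An object of class `"lsirm"`; a list with, among others:
#'   \describe{
#'     \item{beta, theta, sigma_sq}{retained draws (S x P, S x N, length S).}
#'     \item{W, Z}{retained position draws (P x d x S, N x d x S arrays).}
#'     \item{log_posterior}{log posterior of each retained draw.}
#'     \item{beta_mean, theta_mean, W_mean, Z_mean, sigma_sq_mean}{posterior
#'       means (positions from aligned draws when `align = TRUE`).}
#'     \item{map_index}{index of the maximum-a-posteriori retained draw
#'       (ties broken by the earliest index).}
#'     \item{acceptance}{post-burn-in acceptance rate per proposal block.}
#'     \item{imputed, missing_index}{per-draw imputations of missing cells.}
#'   }
#' @examples
#' sim <- simulate_paired(sim_config(n_respondents = 60, n_items = 12,
#'                                   missing_rate = 0), seed = 1)
#' fit <- lsirm(sim$data$a, control = lsirm_control(600, 100, 5), seed = 1)
#' fit
#' head(coef(fit))
#' @export
lsirm <- function(data, d = 2, hyper = lsirm_hyper(),
                  control = lsirm_control(), seed = NULL, align = TRUE) {
  if (!inherits(data, "response_matrix")) data <- response_matrix(data)
  stopifnot(inherits(hyper, "lsirm_hyper"), inherits(control, "lsirm_control"),
            d >= 1)
  y <- data$values
  N <- nrow(y); P <- ncol(y)
  if (N < 2 || P < 2)
    stop("need at least 2 respondents and 2 items", call. = FALSE)
  all_missing <- all(is.na(y))
  if (!all_missing) {
    bad_r <- which(rowSums(!is.na(y)) == 0)
    bad_c <- which(colSums(!is.na(y)) == 0)
    if (length(bad_r) || length(bad_c))
      stop("degenerate data: no observed responses for ",
           paste(c(sprintf("respondent '%s'", data$respondent_ids[bad_r]),
                   sprintf("item '%s'", data$item_ids[bad_c])),
                 collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  # deterministic-given-seed initialization: item intercepts at the clipped
  # empirical logit, traits at zero, positions tightly around the origin
  rate <- colMeans(y, na.rm = TRUE)
  rate[is.nan(rate)] <- 0.5
  beta0 <- pmin(pmax(stats::qlogis(pmin(pmax(rate, 1e-3), 1 - 1e-3)), -3), 3)
  theta0 <- rep(0, N)
  W0 <- matrix(stats::rnorm(P * d, 0, sqrt(0.1)), P, d)
  Z0 <- matrix(stats::rnorm(N * d, 0, sqrt(0.1)), N, d)

  ym <- y
  storage.mode(ym) <- "integer"
  res <- .cpp_lsirm_mcmc(ym, as.integer(d), hyper$tau_beta_sq, hyper$a_sigma,
                         hyper$b_sigma, as.integer(control$n_iter),
                         as.integer(control$burnin), as.integer(control$thin),
                         c(control$jump_beta, control$jump_theta,
                           control$jump_w, control$jump_z),
                         isTRUE(control$adapt), beta0, theta0, 1.0, W0, Z0)

  colnames(res$beta) <- data$item_ids
  colnames(res$theta) <- data$respondent_ids
  lp <- res$log_posterior
  fit <- structure(list(
    beta = res$beta, theta = res$theta, sigma_sq = as.numeric(res$sigma_sq),
    W = res$W, Z = res$Z, log_posterior = lp,
    imputed = res$imputed, missing_index = res$missing_index,
    acceptance = res$acceptance, jumps = res$jumps,
    map_index = which.max(lp),  # which.max takes the earliest maximum
    aligned = FALSE, data = data, d = d, hyper = hyper, control = control,
    seed = seed, informant = data$informant), class = "lsirm")
  if (align) fit <- procrustes_align(fit)
  fit$beta_mean <- colMeans(fit$beta)
  fit$theta_mean <- colMeans(fit$theta)
  fit$sigma_sq_mean <- mean(fit$sigma_sq)
  fit$W_mean <- apply(fit$W, c(1, 2), mean)
  fit$Z_mean <- apply(fit$Z, c(1, 2), mean)
  rownames(fit$W_mean) <- data$item_ids
  rownames(fit$Z_mean) <- data$respondent_ids
  fit
}

#' Number of retained posterior draws
#' @param fit an [lsirm()] fit.
#' @return Integer draw count, `(n_iter - burnin) / thin`.
#' @export
n_draws <- function(fit) {
  stopifnot(inherits(fit, "lsirm"))
  nrow(fit$beta)
}

#' Posterior summary of a fitted model
#'
#' Per-parameter posterior means and the maximum-a-posteriori retained draw
#' (largest stored log posterior, earliest index on ties).
#'
#' @param fit an [lsirm()] fit.
#' @return A list with `beta_mean`, `theta_mean`, `sigma_sq_mean`, `W_mean`,
#'   `Z_mean`, `map_index`, and the MAP draw's parameters under `map`.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "lsirm"))
  if (n_draws(fit) < 1) stop("empty chain", call. = FALSE)
  s <- fit$map_index
  list(beta_mean = fit$beta_mean, theta_mean = fit$theta_mean,
       sigma_sq_mean = fit$sigma_sq_mean, W_mean = fit$W_mean,
       Z_mean = fit$Z_mean, map_index = s,
       map = list(beta = fit$beta[s, ], theta = fit$theta[s, ],
                  sigma_sq = fit$sigma_sq[s],
                  W = fit$W[, , s, drop = TRUE],
                  Z = fit$Z[, , s, drop = TRUE],
                  log_posterior = fit$log_posterior[s]))
}

#' Draws of the trait-variance full conditional
#'
#' Exposes the sampler's conjugate Gibbs update for the trait variance:
#' sigma_sq given theta is Inv-Gamma(a + N/2, b + sum(theta^2)/2).  The same
#' compiled routine the sampler uses generates the draws, so its moments can
#' be compared with the analytic full conditional.
#'
#' @param theta trait vector conditioned on.
#' @param hyper an [lsirm_hyper()].
#' @param n_draws number of draws.
#' @return Numeric vector of variance draws.
#' @export
sigma_sq_conditional <- function(theta, hyper = lsirm_hyper(),
                                 n_draws = 1000) {
  .cpp_sigma_sq_draws(as.numeric(theta), hyper$a_sigma, hyper$b_sigma,
                      as.integer(n_draws))
}
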