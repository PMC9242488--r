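# small simulation + short-chain fit used across unit tests
quick_config <- function(N = 50, P = 12, ...) {
  sim_config(n_respondents = N, n_items = P, n_shift = 2, n_displace = 1,
             ...)
}

quick_sim <- function(seed = 1, N = 50, P = 12, ...) {
  simulate_paired(quick_config(N, P, ...), seed = seed)
}

quick_fit <- function(data, seed = 1, n_iter = 1200, burnin = 400,
                      thin = 4, ...) {
  lsirm(data, control = lsirm_control(n_iter, burnin, thin), seed = seed,
        ...)
}

# hand-built fitted object (S identical draws at the given parameters),
# for tests that need exact control over the posterior summaries
fake_fit <- function(beta, theta, W, Z, y = NULL, informant = "parent",
                     S = 3, sigma_sq = 1) {
  P <- length(beta); N <- length(theta)
  W <- matrix(W, P); Z <- matrix(Z, N)
  d <- ncol(W)
  item_ids <- paste("Item", seq_len(P))
  resp_ids <- paste0("R", seq_len(N))
  if (is.null(y)) {
    p <- stats::plogis(outer(theta, beta, "+") -
                         as.matrix(stats::dist(rbind(Z, W)))[seq_len(N),
                                                             N + seq_len(P)])
    y <- (p >= 0.5) + 0L
  }
  data <- response_matrix(y, resp_ids, item_ids, informant)
  beta_m <- matrix(beta, S, P, byrow = TRUE, dimnames = list(NULL, item_ids))
  theta_m <- matrix(theta, S, N, byrow = TRUE, dimnames = list(NULL, resp_ids))
  Wd <- array(W, c(P, d, S)); Zd <- array(Z, c(N, d, S))
  Wm <- W; rownames(Wm) <- item_ids
  Zm <- Z; rownames(Zm) <- resp_ids
  structure(list(beta = beta_m, theta = theta_m,
                 sigma_sq = rep(sigma_sq, S),
                 W = Wd, Z = Zd, log_posterior = seq_len(S),
                 imputed = matrix(0L, 0, 0), missing_index = matrix(0L, 0, 2),
                 acceptance = c(beta = 0.3, theta = 0.3, w = 0.3, z = 0.3),
                 jumps = c(beta = 0.1, theta = 0.1, w = 0.1, z = 0.1),
                 map_index = S, aligned = TRUE, data = data, d = d,
                 hyper = lsirm_hyper(), control = lsirm_control(100, 10, 2),
                 seed = 1, informant = informant,
                 beta_mean = stats::setNames(beta, item_ids),
                 theta_mean = stats::setNames(theta, resp_ids),
                 sigma_sq_mean = sigma_sq, W_mean = Wm, Z_mean = Zm),
            class = "lsirm")
}

# scalar-loop log-likelihood oracle, deliberately naive
loop_log_likelihood <- function(beta, theta, W, Z, y) {
  ll <- 0
  for (k in seq_len(nrow(y))) {
    for (i in seq_len(ncol(y))) {
      if (is.na(y[k, i])) next
      p <- stats::plogis(beta[i] + theta[k] -
                           sqrt(sum((W[i, ] - Z[k, ])^2)))
      ll <- ll + y[k, i] * log(p) + (1 - y[k, i]) * log(1 - p)
    }
  }
  ll
}

# random rigid motion in R^2
random_rigid <- function(seed) {
  set.seed(seed)
  ang <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  if (stats::runif(1) < 0.5) R <- R %*% diag(c(1, -1))
  list(R = R, t = stats::rnorm(2, 0, 2))
}
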