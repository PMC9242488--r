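#' @export
print.lsirm <- function(x, ...) {
  cat(sprintf("Latent space item response model (%s report)\n", x$informant))
  cat(sprintf("  %d respondents x %d items, latent dimension %d\n",
              nrow(x$data$values), ncol(x$data$values), x$d))
  cat(sprintf("  %d retained draws (%d sweeps, burn-in %d, thin %d)%s\n",
              n_draws(x), x$control$n_iter, x$control$burnin, x$control$thin,
              if (x$aligned) ", Procrustes-aligned" else ""))
  cat(sprintf("  acceptance rates: beta %.2f, theta %.2f, w %.2f, z %.2f\n",
              x$acceptance["beta"], x$acceptance["theta"],
              x$acceptance["w"], x$acceptance["z"]))
  cat(sprintf("  posterior mean trait variance sigma^2 = %.3f\n",
              x$sigma_sq_mean))
  invisible(x)
}

#' Posterior summary method for fitted models
#'
#' @param object an [lsirm()] fit.
#' @param prob central credible-interval mass for the parameter tables.
#' @param ... unused.
#' @return A list of class `"summary.lsirm"` with item and respondent
#'   parameter tables (posterior mean, sd, interval) and fit metadata.
#' @export
summary.lsirm <- function(object, prob = 0.95, ...) {
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  tab <- function(draws) {
    cbind(mean = colMeans(draws), sd = apply(draws, 2, stats::sd),
          lower = apply(draws, 2, stats::quantile, qs[1]),
          upper = apply(draws, 2, stats::quantile, qs[2]))
  }
  out <- list(call_info = list(informant = object$informant, d = object$d,
                               draws = n_draws(object),
                               aligned = object$aligned),
              items = tab(object$beta), respondents = tab(object$theta),
              sigma_sq = c(mean = mean(object$sigma_sq),
                           sd = stats::sd(object$sigma_sq),
                           stats::quantile(object$sigma_sq, qs)),
              acceptance = object$acceptance,
              map_log_posterior = object$log_posterior[object$map_index],
              prob = prob)
  class(out) <- "summary.lsirm"
  out
}

#' @export
print.summary.lsirm <- function(x, ...) {
  ci <- x$call_info
  cat(sprintf("LSIRM posterior summary (%s report, d = %d, %d draws%s)\n",
              ci$informant, ci$d, ci$draws,
              if (ci$aligned) ", aligned" else ""))
  cat("\nItem easiness (beta), first items:\n")
  print(round(utils::head(x$items), 3))
  cat(sprintf("\nTrait variance sigma^2: mean %.3f (sd %.3f)\n",
              x$sigma_sq["mean"], x$sigma_sq["sd"]))
  cat(sprintf("MAP log posterior: %.2f\n", x$map_log_posterior))
  invisible(x)
}

#' Extract posterior-mean coefficients
#'
#' @param object an [lsirm()] fit.
#' @param type `"beta"` for item easiness intercepts, `"theta"` for
#'   respondent traits.
#' @param ... unused.
#' @return Named numeric vector of posterior means.
#' @export
coef.lsirm <- function(object, type = c("beta", "theta"), ...) {
  type <- match.arg(type)
  if (type == "beta") object$beta_mean else object$theta_mean
}

#' Predicted response probabilities
#'
#' Model-implied probability of a positive response for every
#' respondent-item cell, either by plugging posterior-mean parameters into
#' the success-probability formula (`method = "plugin"`) or by averaging the
#' per-draw probabilities over the chain (`method = "average"`).
#'
#' @param object an [lsirm()] fit.
#' @param method `"plugin"` or `"average"`.
#' @param type `"response"` for probabilities, `"class"` for thresholded 0/1
#'   predictions.
#' @param threshold classification threshold in (0, 1) for `type = "class"`.
#' @param ... unused.
#' @return N x P matrix of probabilities or 0/1 predictions.
#' @export
predict.lsirm <- function(object, method = c("plugin", "average"),
                          type = c("response", "class"), threshold = 0.5,
                          ...) {
  method <- match.arg(method)
  type <- match.arg(type)
  stopifnot(threshold > 0, threshold < 1)
  if (method == "plugin") {
    eta <- outer(object$theta_mean, object$beta_mean, "+") -
      latent_distances(object$W_mean, object$Z_mean)
    p <- stats::plogis(eta)
  } else {
    S <- n_draws(object)
    p <- 0
    for (s in seq_len(S)) {
      eta <- outer(object$theta[s, ], object$beta[s, ], "+") -
        latent_distances(object$W[, , s], object$Z[, , s])
      p <- p + stats::plogis(eta)
    }
    p <- p / S
  }
  dimnames(p) <- dimnames(object$data$values)
  if (type == "class") (p >= threshold) + 0L else p
}

#' @export
fitted.lsirm <- function(object, ...) predict(object, ...)

#' Response residuals of a fitted model
#'
#' @param object an [lsirm()] fit.
#' @param type `"response"` (y - p) or `"pearson"`
#'   ((y - p) / sqrt(p(1 - p))).
#' @param ... passed to [predict.lsirm()].
#' @return N x P matrix with `NA` at missing cells.
#' @export
residuals.lsirm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object, ...)
  r <- object$data$values - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  r
}

#' Observed-data log-likelihood at the posterior means
#' @param object an [lsirm()] fit.
#' @param ... unused.
#' @return A `"logLik"` object (plug-in value; df counts free parameters).
#' @export
logLik.lsirm <- function(object, ...) {
  ll <- lsirm_log_likelihood(object$beta_mean, object$theta_mean,
                             object$W_mean, object$Z_mean,
                             object$data$values)
  N <- nrow(object$data$values); P <- ncol(object$data$values)
  structure(ll, df = P + N + 1 + object$d * (P + N), class = "logLik")
}

#' Simulate response matrices from a fitted model
#'
#' Draws replicate binary response matrices at the posterior-mean
#' parameters (posterior predictive at the plug-in estimate).
#'
#' @param object an [lsirm()] fit.
#' @param nsim number of replicate matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` [response_matrix()] objects.
#' @export
simulate.lsirm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  lapply(seq_len(nsim), function(s) {
    response_matrix(matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p),
                           dimnames = dimnames(p)),
                    informant = object$informant)
  })
}

#' Plot the interaction map of a fitted model
#'
#' Displays posterior-mean respondent positions (points) and item positions
#' (labels) in the first two latent dimensions; optionally overlays
#' syndrome centroids.
#'
#' @param x an [lsirm()] fit.
#' @param syndromes optional [syndrome_map()] whose centroids are overlaid.
#' @param items show item labels?
#' @param respondents show respondent points?
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lsirm <- function(x, syndromes = NULL, items = TRUE,
                       respondents = TRUE, ...) {
  W <- x$W_mean; Z <- x$Z_mean
  rng <- apply(rbind(W, Z), 2, range)
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2],
                 xlab = "latent dimension 1", ylab = "latent dimension 2",
                 main = sprintf("Interaction map (%s report)", x$informant),
                 asp = 1, ...)
  if (respondents)
    graphics::points(Z[, 1], Z[, 2], pch = 16, cex = 0.5,
                     col = grDevices::adjustcolor("grey40", 0.5))
  if (items)
    graphics::text(W[, 1], W[, 2], labels = seq_len(nrow(W)), cex = 0.7,
                   col = "firebrick")
  if (!is.null(syndromes)) {
    cen <- syndrome_centroids(x, syndromes)
    graphics::points(cen$centroids[, 1], cen$centroids[, 2], pch = 21,
                     bg = "gold", cex = 1.6)
    graphics::text(cen$centroids[, 1], cen$centroids[, 2],
                   labels = rownames(cen$centroids), pos = 3, font = 2)
  }
  invisible(x)
}

#' Convergence diagnostics for a fitted model
#'
#' Trace-style diagnostics, provided as aids rather than gates: the
#' log-posterior trace, per-block acceptance rates, and a crude effective
#' sample size (from the lag-autocorrelation sum, capped at the draw count)
#' for the trait variance and a few item intercepts.
#'
#' @param fit an [lsirm()] fit.
#' @param max_lag largest autocorrelation lag used for the ESS estimate.
#' @return A list with `acceptance`, `log_posterior_trace`, and `ess`.
#' @export
lsirm_diagnostics <- function(fit, max_lag = 50) {
  stopifnot(inherits(fit, "lsirm"))
  ess1 <- function(v) {
    S <- length(v)
    if (stats::sd(v) == 0) return(S)
    ac <- stats::acf(v, lag.max = min(max_lag, S - 1), plot = FALSE)$acf[-1]
    pos <- ac[seq_len(max(which(ac > 0), 1))]
    min(S, S / (1 + 2 * sum(pos)))
  }
  idx <- unique(round(seq(1, ncol(fit$beta), length.out = min(5, ncol(fit$beta)))))
  list(acceptance = fit$acceptance,
       log_posterior_trace = fit$log_posterior,
       ess = c(sigma_sq = ess1(fit$sigma_sq),
               stats::setNames(vapply(idx, function(i) ess1(fit$beta[, i]),
                                      0), paste0("beta_", idx))))
}
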