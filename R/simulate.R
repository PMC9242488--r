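#' Configuration for a synthetic paired-informant simulation
#'
#' Describes the generative conditions for a pair of instruments answered
#' about the same children by two informants.  Instrument a (parent report)
#' defines the base truth: items are placed around eight syndrome poles in
#' the latent plane — the externalizing pair (RBB, AB) and internalizing
#' trio (AD, WD, SC) in opposite half-planes, the non-extreme syndromes
#' (AP, SP, TP) in between — with unassigned items scattered centrally;
#' respondents form clusters around a few pole directions.  Instrument b
#' (self report) derives from the same truth with three controllable
#' cross-informant discrepancies: an easiness shift `delta_beta` on
#' `n_shift` unassigned items (behaviors children endorse more readily than
#' parents report), a common displacement of an `n_displace`-item cluster
#' (a dependency structure present for one informant only), and Gaussian
#' jitter on respondent positions.  A global intercept offset per
#' instrument is calibrated by bisection so the expected positive-response
#' rates hit `target_rate_a` / `target_rate_b` (0.27 parent, 0.43 self by
#' default, matching typical dichotomized checklist data).  Missingness is
#' completely at random at `missing_rate` (a strict subcase of missing at
#' random).
#'
#' @param n_respondents,n_items,d problem dimensions.
#' @param syndrome_sizes named integer vector of member-item counts per
#'   syndrome; the remaining items are unassigned (`"none"`).  Default:
#'   proportional allocation of 80% of the items over the eight standard
#'   syndromes.
#' @param pole_radius radius of the syndrome pole centers.
#' @param item_spread within-syndrome item position standard deviation.
#' @param scatter_sd standard deviation of unassigned item positions.
#' @param n_clusters,cluster_radius,cluster_spread respondent cluster
#'   count, center radius and within-cluster standard deviation.  With the
#'   default four clusters the centers sit at the three higher-order
#'   syndrome poles — externalizing (0 degrees), the non-extreme AP/SP/TP
#'   direction (90 degrees) and internalizing (180 degrees) — plus the
#'   neutral center of the map (respondents aligned with no syndrome);
#'   other counts place centers at evenly spaced angles.
#' @param cluster_centers optional explicit n_clusters x d matrix of
#'   cluster centers overriding the default layout.
#' @param beta_sd,theta_sd standard deviations of the item intercepts and
#'   respondent traits.  The `beta_sd` default (1.4) is calibrated so the
#'   across-item dispersion of positive-response rates at the default
#'   targets reproduces the 0.17 (parent) / 0.24 (self) standard
#'   deviations typical of dichotomized checklist data.
#' @param target_rate_a,target_rate_b expected positive-response rates.
#' @param n_shift,delta_beta easiness-shifted item count and shift size.
#' @param n_displace,displacement displaced-cluster size and displacement
#'   vector (length d).
#' @param jitter_sd respondent-position jitter for instrument b.
#' @param missing_rate per-cell missingness probability, in \[0, 0.05\].
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_paired()]
#' @export
sim_config <- function(n_respondents = 662, n_items = 118, d = 2,
                       syndrome_sizes = NULL, pole_radius = 2,
                       item_spread = 0.4, scatter_sd = 1,
                       n_clusters = 4, cluster_radius = 1.8,
                       cluster_spread = 0.35, cluster_centers = NULL,
                       beta_sd = 1.4, theta_sd = 1,
                       target_rate_a = 0.27, target_rate_b = 0.43,
                       n_shift = 12, delta_beta = 1.5, n_displace = 6,
                       displacement = c(2, 2), jitter_sd = 0.3,
                       missing_rate = 0.002) {
  stopifnot(n_respondents >= 2, n_items >= 2, d >= 1,
            missing_rate >= 0, missing_rate <= 0.05,
            length(displacement) == d,
            n_shift >= 0, n_displace >= 0, n_clusters >= 1)
  labs <- c("AB", "AD", "AP", "RBB", "SC", "SP", "TP", "WD")
  if (is.null(syndrome_sizes)) {
    # canonical relative subscale sizes, scaled to assign ~80% of the items
    weights <- c(AB = 18, AD = 13, AP = 10, RBB = 17, SC = 11, SP = 11,
                 TP = 15, WD = 8)
    n_assigned <- round(0.8 * n_items)
    syndrome_sizes <- floor(weights / sum(weights) * n_assigned)
    rem <- n_assigned - sum(syndrome_sizes)
    if (rem > 0) {
      top <- names(sort(weights, decreasing = TRUE))[seq_len(rem)]
      syndrome_sizes[top] <- syndrome_sizes[top] + 1L
    }
  }
  stopifnot(all(names(syndrome_sizes) %in% labs),
            sum(syndrome_sizes) <= n_items)
  n_none <- n_items - sum(syndrome_sizes)
  if (n_shift + n_displace > n_none + sum(syndrome_sizes))
    stop("discrepancy sets larger than the item set", call. = FALSE)
  if (!is.null(cluster_centers)) {
    cluster_centers <- as.matrix(cluster_centers)
    stopifnot(nrow(cluster_centers) == n_clusters,
              ncol(cluster_centers) == d)
  }
  structure(list(n_respondents = n_respondents, n_items = n_items, d = d,
                 syndrome_sizes = syndrome_sizes, pole_radius = pole_radius,
                 item_spread = item_spread, scatter_sd = scatter_sd,
                 n_clusters = n_clusters, cluster_radius = cluster_radius,
                 cluster_spread = cluster_spread,
                 cluster_centers = cluster_centers, beta_sd = beta_sd,
                 theta_sd = theta_sd, target_rate_a = target_rate_a,
                 target_rate_b = target_rate_b, n_shift = n_shift,
                 delta_beta = delta_beta, n_displace = n_displace,
                 displacement = displacement, jitter_sd = jitter_sd,
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Zero-discrepancy variant of a simulation configuration
#'
#' Removes every cross-informant perturbation (no easiness shifts, no
#' displaced cluster, no respondent jitter) and equalizes the target
#' positive rates, so the two instruments share an identical ground truth
#' and differ only by independent Bernoulli sampling — the null condition
#' for discrepancy analyses.
#'
#' @param config a [sim_config()].
#' @param target_rate shared positive-rate target (default: mean of the
#'   two configured targets).
#' @return A modified `"sim_config"`.
#' @export
sim_config_null <- function(config = sim_config(), target_rate = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(target_rate))
    target_rate <- mean(c(config$target_rate_a, config$target_rate_b))
  config$n_shift <- 0L
  config$n_displace <- 0L
  config$jitter_sd <- 0
  config$target_rate_a <- config$target_rate_b <- target_rate
  config
}

# syndrome pole angles in degrees: externalizing (RBB, AB) in the right
# half-plane, internalizing (AD, WD, SC) opposite, AP/SP/TP between;
# within-pole angles are kept within 30 degrees so that within-pole
# centroid cosine similarity stays above 0.7 under the default item spread
pole_angles <- c(RBB = -15, AB = 15, AP = 70, SP = 90, TP = 110,
                 AD = 165, WD = 180, SC = 195)

# solve mean(plogis(eta + c)) = target for the global intercept offset c
calibrate_offset <- function(eta, target, lower = -15, upper = 15) {
  stats::uniroot(function(c) mean(stats::plogis(eta + c)) - target,
                 c(lower, upper), tol = 1e-10)$root
}

#' Simulate a paired-informant dataset with known ground truth
#'
#' Draws a full ground truth for instrument a per the geometry and
#' distribution plan in `config`, derives instrument b's truth by the
#' configured perturbations, calibrates each instrument's global intercept
#' offset to its target positive rate, simulates both binary response
#' matrices by independent Bernoulli draws from the latent-space response
#' model, and applies the missing-completely-at-random mask.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory; the result is bit-reproducible).
#' @return A list with `data` (a [paired_dataset()]) and `truth`, a list of
#'   class `"sim_truth"` holding the true parameters per instrument
#'   (`beta_a`, `theta`, `W_a`, `Z_a`, `beta_b`, `W_b`, `Z_b`), the
#'   discrepancy-set memberships (`shifted_items`, `displaced_items`),
#'   respondent `cluster_labels`, the syndrome map, and the calibrated
#'   intercept offsets.
#' @examples
#' sim <- simulate_paired(sim_config(n_respondents = 50, n_items = 20),
#'                        seed = 42)
#' sim$data
#' sim$truth$shifted_items
#' @export
simulate_paired <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for simulation", call. = FALSE)
  set.seed(seed)
  N <- config$n_respondents; P <- config$n_items; d <- config$d
  item_ids <- paste("Item", seq_len(P))
  resp_ids <- paste0("R", seq_len(N))

  # --- syndrome assignment and item geometry -------------------------
  sizes <- config$syndrome_sizes
  assignment <- rep("none", P)
  pos <- 1L
  for (s in names(sizes)) {
    if (sizes[[s]] == 0) next
    assignment[pos:(pos + sizes[[s]] - 1L)] <- s
    pos <- pos + sizes[[s]]
  }
  names(assignment) <- item_ids
  syndromes <- syndrome_map(assignment)

  W <- matrix(0, P, d)
  for (s in names(sizes)) {
    idx <- which(assignment == s)
    if (!length(idx)) next
    ang <- pole_angles[[s]] * pi / 180
    center <- config$pole_radius * c(cos(ang), sin(ang), rep(0, d - 2))[1:d]
    W[idx, ] <- matrix(rep(center, each = length(idx)), length(idx), d) +
      matrix(stats::rnorm(length(idx) * d, 0, config$item_spread),
             length(idx), d)
  }
  none_idx <- which(assignment == "none")
  if (length(none_idx))
    W[none_idx, ] <- matrix(stats::rnorm(length(none_idx) * d, 0,
                                         config$scatter_sd),
                            length(none_idx), d)

  # --- respondent clusters -------------------------------------------
  n_cl <- config$n_clusters
  if (!is.null(config$cluster_centers)) {
    centers <- config$cluster_centers
  } else {
    if (n_cl == 4) {
      # higher-order syndrome poles (EXT, non-extreme, INT) plus the
      # neutral center of the map
      cl_angles <- c(0, 90, 180) * pi / 180
    } else {
      cl_angles <- seq(0, 2 * pi, length.out = n_cl + 1)[seq_len(n_cl)]
    }
    centers <- cbind(config$cluster_radius * cos(cl_angles),
                     config$cluster_radius * sin(cl_angles))
    if (n_cl == 4) centers <- rbind(centers, 0)
    if (d > 2) centers <- cbind(centers, matrix(0, nrow(centers), d - 2))
    if (d == 1) centers <- centers[, 1, drop = FALSE]
  }
  cluster_labels <- sample(rep_len(seq_len(n_cl), N))
  Z <- centers[cluster_labels, , drop = FALSE] +
    matrix(stats::rnorm(N * d, 0, config$cluster_spread), N, d)

  # --- intercepts and traits -----------------------------------------
  beta_raw <- stats::rnorm(P, 0, config$beta_sd)
  theta <- stats::rnorm(N, 0, config$theta_sd)

  # --- instrument-b perturbations ------------------------------------
  pool <- if (length(none_idx) >= config$n_shift + config$n_displace)
    none_idx else seq_len(P)
  picked <- if (config$n_shift + config$n_displace > 0)
    sample(pool, config$n_shift + config$n_displace) else integer()
  shifted <- sort(utils::head(picked, config$n_shift))
  displaced <- sort(utils::tail(picked, config$n_displace))
  if (length(intersect(shifted, displaced)))
    message("shifted and displaced item sets overlap")

  beta_raw_b <- beta_raw
  beta_raw_b[shifted] <- beta_raw_b[shifted] + config$delta_beta
  W_b <- W
  if (length(displaced))
    W_b[displaced, ] <- W_b[displaced, ] +
      matrix(rep(config$displacement, each = length(displaced)),
             length(displaced), d)
  Z_b <- Z + matrix(stats::rnorm(N * d, 0, config$jitter_sd), N, d)

  # --- positive-rate calibration (deterministic given the truth) -----
  eta_a <- outer(theta, beta_raw, "+") - latent_distances(W, Z)
  off_a <- calibrate_offset(eta_a, config$target_rate_a)
  eta_b <- outer(theta, beta_raw_b, "+") - latent_distances(W_b, Z_b)
  off_b <- calibrate_offset(eta_b, config$target_rate_b)
  beta_a <- beta_raw + off_a
  beta_b <- beta_raw_b + off_b

  truth <- structure(list(
    beta_a = stats::setNames(beta_a, item_ids),
    beta_b = stats::setNames(beta_b, item_ids),
    theta = stats::setNames(theta, resp_ids),
    W_a = W, Z_a = Z, W_b = W_b, Z_b = Z_b,
    shifted_items = item_ids[shifted], displaced_items = item_ids[displaced],
    cluster_labels = stats::setNames(cluster_labels, resp_ids),
    syndromes = syndromes, intercept_offsets = c(a = off_a, b = off_b),
    config = config), class = "sim_truth")

  a <- simulate_instrument(list(beta = beta_a, theta = theta, W = W, Z = Z),
                           informant = "parent",
                           item_ids = item_ids, respondent_ids = resp_ids)
  b <- simulate_instrument(list(beta = beta_b, theta = theta, W = W_b,
                                Z = Z_b), informant = "self",
                           item_ids = item_ids, respondent_ids = resp_ids)
  if (config$missing_rate > 0) {
    a <- apply_mar_mask(a, config$missing_rate)
    b <- apply_mar_mask(b, config$missing_rate)
  }
  list(data = paired_dataset(a, b, syndromes), truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Synthetic paired-informant truth: %d respondents x %d items\n",
              length(x$theta), length(x$beta_a)))
  cat(sprintf("  %d easiness-shifted items, %d displaced items, %d respondent clusters\n",
              length(x$shifted_items), length(x$displaced_items),
              max(x$cluster_labels)))
  invisible(x)
}

#' Simulate one instrument's response matrix from a ground truth
#'
#' Independent Bernoulli draws, cell by cell, at the latent-space response
#' probability `plogis(beta_i + theta_k - ||w_i - z_k||)`.
#'
#' @param truth list with `beta` (length P), `theta` (length N), `W`
#'   (P x d), `Z` (N x d).
#' @param seed optional integer seed (set it when calling outside
#'   [simulate_paired()], which manages the RNG itself).
#' @param informant informant tag.
#' @param item_ids,respondent_ids optional labels.
#' @return A [response_matrix()].
#' @export
simulate_instrument <- function(truth, seed = NULL, informant = "other",
                                item_ids = NULL, respondent_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::plogis(outer(truth$theta, truth$beta, "+") -
                       latent_distances(truth$W, truth$Z))
  y <- matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p))
  response_matrix(y, respondent_ids = respondent_ids, item_ids = item_ids,
                  informant = informant)
}

#' Mask responses completely at random
#'
#' Masks each cell independently with the given probability, irrespective
#' of the (observed or unobserved) values — missingness completely at
#' random, a strict subcase of missing at random.
#'
#' @param m a [response_matrix()].
#' @param rate per-cell masking probability in \[0, 1).
#' @param seed optional integer seed.
#' @return The masked [response_matrix()].
#' @export
apply_mar_mask <- function(m, rate, seed = NULL) {
  stopifnot(inherits(m, "response_matrix"), rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(m)
  v <- m$values
  v[stats::runif(length(v)) < rate] <- NA_integer_
  response_matrix(v, m$respondent_ids, m$item_ids, m$informant)
}
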