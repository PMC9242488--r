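#' Compare item easiness between two informants
#'
#' Pearson correlation of the posterior-mean item intercepts of two fits on
#' the same items, a resistant regression line of the second on the first,
#' and outlier flags for items that deviate from the common linear trend.
#' The line is a Huber M-estimate (robust regression), so that genuinely
#' discrepant items — which can be numerous and large — do not drag the
#' line or inflate the residual scale and thereby mask one another; an item
#' is flagged when its absolute residual exceeds `threshold` times the
#' robust residual scale.  Flagged items are those endorsed systematically
#' more (or less) easily by one informant than the overall relationship
#' predicts.
#'
#' @param fit_a,fit_b [lsirm()] fits on the same item set.
#' @param threshold scaled-residual cutoff for flagging (default 2.5).
#' @return A list of class `"beta_comparison"`: `r` (Pearson correlation),
#'   `fit` (the robust `rlm` of beta_b on beta_a), `table` (per-item data
#'   frame with both intercepts, scaled residual and flag), `flagged` (ids
#'   of flagged items).
#' @export
beta_compare <- function(fit_a, fit_b, threshold = 2.5) {
  stopifnot(inherits(fit_a, "lsirm"), inherits(fit_b, "lsirm"))
  if (!identical(fit_a$data$item_ids, fit_b$data$item_ids))
    stop("fits must share identical item ids", call. = FALSE)
  ba <- fit_a$beta_mean; bb <- fit_b$beta_mean
  if (length(ba) < 3) stop("need at least 3 items", call. = FALSE)
  r <- stats::cor(ba, bb)
  rfit <- suppressWarnings(MASS::rlm(bb ~ ba, maxit = 100))
  res <- stats::residuals(rfit)
  scale <- rfit$s
  scaled <- if (is.na(scale) || scale < 1e-8) rep(0, length(res))
            else res / scale
  flag <- abs(scaled) > threshold
  tab <- data.frame(item_id = fit_a$data$item_ids, beta_a = unname(ba),
                    beta_b = unname(bb), scaled_residual = unname(scaled),
                    flagged = unname(flag), row.names = NULL)
  structure(list(r = r, fit = rfit, table = tab,
                 flagged = tab$item_id[flag], threshold = threshold),
            class = "beta_comparison")
}

#' @export
print.beta_comparison <- function(x, ...) {
  cat(sprintf("Item easiness comparison: r = %.3f, slope = %.3f\n",
              x$r, stats::coef(x$fit)[2]))
  cat(sprintf("%d item(s) flagged (|residual| > %.1f robust scales)",
              length(x$flagged), x$threshold))
  if (length(x$flagged))
    cat(":", paste(utils::head(x$flagged, 15), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Posterior samples of an item-pair distance
#'
#' The per-draw Euclidean distance between the latent positions of two
#' items, i.e. the posterior distribution of `||w_i - w_j||` implied by the
#' (aligned) chain.  This distribution quantifies the estimated dependency
#' between the two items in one instrument.
#'
#' @param fit an aligned [lsirm()] fit.
#' @param i,j item ids or indices.
#' @return Object of class `"distance_distribution"`: a list with `samples`
#'   (length = number of retained draws), `item_pair`, `informant`.
#' @export
distance_samples <- function(fit, i, j) {
  stopifnot(inherits(fit, "lsirm"))
  ii <- if (is.character(i)) match(i, fit$data$item_ids) else as.integer(i)
  jj <- if (is.character(j)) match(j, fit$data$item_ids) else as.integer(j)
  if (is.na(ii) || is.na(jj)) stop("unknown item", call. = FALSE)
  if (ii == jj)
    warning("i and j name the same item; the distance is degenerately zero")
  dif <- fit$W[ii, , ] - fit$W[jj, , ]  # d x S
  structure(list(samples = sqrt(colSums(dif^2)),
                 item_pair = fit$data$item_ids[c(ii, jj)],
                 informant = fit$informant),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("Posterior distance ||w_i - w_j|| for '%s' vs '%s' (%s): mean %.3f, sd %.3f, %d draws\n",
              x$item_pair[1], x$item_pair[2], x$informant,
              mean(x$samples), stats::sd(x$samples), length(x$samples)))
  invisible(x)
}

# Kernel density estimates of two sample vectors on one shared grid:
# Gaussian kernel, Silverman's rule per sample, 512 grid points over the
# union support padded by 3 bandwidths.
kde_pair <- function(a, b, n_grid = 512) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1] && a[1] == 0)
    stop("both sample sets are constant at zero; density undefined",
         call. = FALSE)
  bw_a <- if (stats::sd(a) > 0) stats::bw.nrd0(a) else 1e-3
  bw_b <- if (stats::sd(b) > 0) stats::bw.nrd0(b) else 1e-3
  pad <- 3 * max(bw_a, bw_b)
  lo <- min(a, b) - pad
  hi <- max(a, b) + pad
  list(x = seq(lo, hi, length.out = n_grid),
       fa = stats::density(a, bw = bw_a, from = lo, to = hi, n = n_grid)$y,
       fb = stats::density(b, bw = bw_b, from = lo, to = hi, n = n_grid)$y)
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Overlap of two posterior distance distributions
#'
#' The overlap statistic `R` is the integral of the pointwise minimum of
#' the two estimated densities, a number in \[0, 1\]: 1 for identical
#' distributions, 0 for disjoint supports.  `R <= 0.05` flags an item pair
#' whose dependency differs materially between the two instruments.
#' Densities are Gaussian kernel estimates with Silverman bandwidths,
#' integrated by the trapezoid rule on a 512-point grid over the padded
#' union support.
#'
#' @param da,db `"distance_distribution"` objects (or bare sample vectors).
#' @param flag_at threshold below which the pair is flagged as different.
#' @return A list of class `"overlap_result"`: `R`, `flag_different`,
#'   `item_pair` (when available).
#' @export
overlap_R <- function(da, db, flag_at = 0.05) {
  a <- if (inherits(da, "distance_distribution")) da$samples else as.numeric(da)
  b <- if (inherits(db, "distance_distribution")) db$samples else as.numeric(db)
  if (!length(a) || !length(b)) stop("empty sample vector", call. = FALSE)
  g <- kde_pair(a, b)
  R <- min(max(trapezoid(g$x, pmin(g$fa, g$fb)), 0), 1)
  structure(list(R = R, flag_different = R <= flag_at,
                 item_pair = if (inherits(da, "distance_distribution"))
                   da$item_pair else NULL),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Distance-distribution overlap R = %.3f%s\n", x$R,
              if (x$flag_different) " (flagged as different)" else ""))
  invisible(x)
}

#' Kullback-Leibler divergence between two distance distributions
#'
#' KL(f_a || f_b) on the shared kernel-density grid of [overlap_R()], with
#' both densities floored at `eps` before the log ratio; the symmetrized
#' divergence (average of the two directions) is reported alongside.
#' Non-negative, and near zero for matching samples.
#'
#' @param da,db `"distance_distribution"` objects or sample vectors.
#' @param eps density floor guarding the log ratio.
#' @return A list with `kl` (KL(a||b)), `kl_reverse`, `symmetrized`.
#' @export
kl_divergence <- function(da, db, eps = 1e-12) {
  a <- if (inherits(da, "distance_distribution")) da$samples else as.numeric(da)
  b <- if (inherits(db, "distance_distribution")) db$samples else as.numeric(db)
  if (!length(a) || !length(b)) stop("empty sample vector", call. = FALSE)
  g <- kde_pair(a, b)
  fa <- pmax(g$fa, eps); fb <- pmax(g$fb, eps)
  kl_ab <- max(trapezoid(g$x, fa * (log(fa) - log(fb))), 0)
  kl_ba <- max(trapezoid(g$x, fb * (log(fb) - log(fa))), 0)
  list(kl = kl_ab, kl_reverse = kl_ba, symmetrized = (kl_ab + kl_ba) / 2)
}

#' Kolmogorov-Smirnov comparison of two distance distributions
#'
#' Two-sample KS statistic and asymptotic p-value on the raw posterior
#' samples.  Note the caveat: MCMC draws are autocorrelated, so the nominal
#' p-value treats dependent samples as independent and is anti-conservative;
#' it is reported for descriptive screening, as is conventional.
#'
#' @param da,db `"distance_distribution"` objects or sample vectors.
#' @return A list with `statistic` and `p_value`.
#' @export
ks_compare <- function(da, db) {
  a <- if (inherits(da, "distance_distribution")) da$samples else as.numeric(da)
  b <- if (inherits(db, "distance_distribution")) db$samples else as.numeric(db)
  if (!length(a) || !length(b)) stop("empty sample vector", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

# S x P(P-1)/2-free representation: all pairwise item distances per draw,
# returned as a P x P x S array
pairwise_item_distances <- function(fit) {
  P <- dim(fit$W)[1]; S <- dim(fit$W)[3]
  out <- array(0, c(P, P, S))
  for (s in seq_len(S))
    out[, , s] <- as.matrix(stats::dist(fit$W[, , s]))
  out
}

#' Overlap matrix over all item pairs
#'
#' Computes the overlap statistic of [overlap_R()] for every item pair in
#' two matched fits, returning the symmetric P x P matrix of `R` values, a
#' logical flag mask (`R <= flag_at`), and the proportion of flagged pairs.
#'
#' @param fit_a,fit_b matched, aligned [lsirm()] fits on the same items.
#' @param flag_at flagging threshold on `R`.
#' @return A list of class `"overlap_matrix"`: `R` (P x P, diagonal `NA`),
#'   `flagged` (logical matrix), `flagged_proportion` (share of the
#'   P(P-1)/2 unordered pairs flagged).
#' @export
overlap_matrix <- function(fit_a, fit_b, flag_at = 0.05) {
  stopifnot(inherits(fit_a, "lsirm"), inherits(fit_b, "lsirm"))
  if (!identical(fit_a$data$item_ids, fit_b$data$item_ids))
    stop("fits must share identical item ids", call. = FALSE)
  P <- length(fit_a$data$item_ids)
  da <- pairwise_item_distances(fit_a)
  db <- pairwise_item_distances(fit_b)
  R <- matrix(NA_real_, P, P,
              dimnames = list(fit_a$data$item_ids, fit_a$data$item_ids))
  for (i in seq_len(P - 1)) {
    for (j in seq.int(i + 1, P)) {
      R[i, j] <- R[j, i] <- overlap_R(da[i, j, ], db[i, j, ], flag_at)$R
    }
  }
  flagged <- !is.na(R) & R <= flag_at
  structure(list(R = R, flagged = flagged,
                 flagged_proportion = mean(R[upper.tri(R)] <= flag_at),
                 flag_at = flag_at),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  P <- nrow(x$R)
  cat(sprintf("Item-pair overlap matrix: %d items, %d pairs\n",
              P, P * (P - 1) / 2))
  cat(sprintf("  %.1f%% of pairs flagged as different (R <= %.2f)\n",
              100 * x$flagged_proportion, x$flag_at))
  invisible(x)
}

#' Item-pair distance difference table
#'
#' Ranks item pairs by how much their latent distance differs between two
#' matched fits.  Two rankings are reported: by the absolute difference of
#' posterior-mean distances, and (when an [overlap_matrix()] is supplied)
#' by ascending overlap `R`.  Distances at the maximum-a-posteriori draw
#' are listed alongside the posterior means for each instrument.
#'
#' @param fit_a,fit_b matched, aligned [lsirm()] fits on the same items.
#' @param top_k number of pairs reported (default 12).
#' @param overlap optional [overlap_matrix()] for the overlap-based ranking.
#' @return A list with data frames `by_mean_difference` and (if `overlap`
#'   given) `by_overlap`, each with per-instrument posterior-mean and MAP
#'   distances.
#' @export
distance_difference_table <- function(fit_a, fit_b, top_k = 12,
                                      overlap = NULL) {
  stopifnot(inherits(fit_a, "lsirm"), inherits(fit_b, "lsirm"))
  ids <- fit_a$data$item_ids
  P <- length(ids)
  da <- pairwise_item_distances(fit_a)
  db <- pairwise_item_distances(fit_b)
  mean_a <- apply(da, c(1, 2), mean); mean_b <- apply(db, c(1, 2), mean)
  map_a <- da[, , fit_a$map_index]; map_b <- db[, , fit_b$map_index]
  ut <- which(upper.tri(mean_a), arr.ind = TRUE)
  tab <- data.frame(item_i = ids[ut[, 1]], item_j = ids[ut[, 2]],
                    mean_dist_a = mean_a[ut], mean_dist_b = mean_b[ut],
                    map_dist_a = map_a[ut], map_dist_b = map_b[ut])
  tab$abs_mean_difference <- abs(tab$mean_dist_a - tab$mean_dist_b)
  out <- list(by_mean_difference =
                utils::head(tab[order(-tab$abs_mean_difference), ], top_k))
  if (!is.null(overlap)) {
    tab$R <- overlap$R[ut]
    out$by_overlap <- utils::head(tab[order(tab$R), ], top_k)
  }
  rownames(out$by_mean_difference) <- NULL
  if (!is.null(out$by_overlap)) rownames(out$by_overlap) <- NULL
  out
}

#' Syndrome centroids in the interaction map
#'
#' The latent position of a syndrome is the arithmetic mean of the
#' posterior-mean positions of its member items; unassigned items
#' (`"none"`) are excluded, and empty syndromes are skipped with a warning.
#'
#' @param fit an aligned [lsirm()] fit.
#' @param syndromes a [syndrome_map()].
#' @return A list of class `"syndrome_centroids"` with `centroids` (K x d
#'   matrix, rownames = syndrome labels) and `informant`.
#' @export
syndrome_centroids <- function(fit, syndromes) {
  stopifnot(inherits(fit, "lsirm"), inherits(syndromes, "syndrome_map"))
  labs <- syndromes$syndrome_order
  cen <- matrix(NA_real_, 0, fit$d)
  kept <- character()
  for (s in labs) {
    members <- intersect(syndrome_items(syndromes, s), fit$data$item_ids)
    if (!length(members)) {
      warning("syndrome '", s, "' has no member items; skipped")
      next
    }
    cen <- rbind(cen, colMeans(fit$W_mean[members, , drop = FALSE]))
    kept <- c(kept, s)
  }
  rownames(cen) <- kept
  structure(list(centroids = cen, informant = fit$informant),
            class = "syndrome_centroids")
}

#' Cosine similarity of two vectors
#'
#' `cos(phi) = a.b / (||a|| ||b||)`, in \[-1, 1\]: 1 for parallel, -1 for
#' opposite, 0 for orthogonal directions.  Both vectors must be nonzero.
#'
#' @param a,b numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  min(max(sum(a * b) / (na * nb), -1), 1)
}

#' Cosine-similarity matrix of syndrome positions
#'
#' Pairwise cosine similarity between syndrome centroid position vectors in
#' one instrument, in canonical syndrome order.  Computed per instrument,
#' these matrices show which syndrome directions align (e.g. the
#' externalizing pair RBB/AB, the internalizing trio AD/WD/SC) and how the
#' alignment pattern differs between informants.
#'
#' @param centroids a [syndrome_centroids()] object, or an [lsirm()] fit
#'   (in which case `syndromes` must be given).
#' @param syndromes a [syndrome_map()], required when `centroids` is a fit.
#' @return Symmetric K x K matrix with unit diagonal.
#' @export
syndrome_similarity <- function(centroids, syndromes = NULL) {
  if (inherits(centroids, "lsirm")) {
    stopifnot(!is.null(syndromes))
    centroids <- syndrome_centroids(centroids, syndromes)
  }
  cen <- centroids$centroids
  K <- nrow(cen)
  out <- matrix(1, K, K, dimnames = list(rownames(cen), rownames(cen)))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i != j) out[i, j] <- cosine_similarity(cen[i, ], cen[j, ])
    }
  }
  out
}

#' Respondent-to-syndrome distances
#'
#' Euclidean distance from each respondent's posterior-mean position to
#' each syndrome centroid.  Small distances mark the syndromes a respondent
#' is most aligned with (their likely problem domains), so these rows are
#' the natural feature vectors for respondent profiling and clustering.
#'
#' @param fit an aligned [lsirm()] fit.
#' @param centroids a [syndrome_centroids()]; computed from `syndromes`
#'   when omitted (ignored for `method = "average"`, which recomputes
#'   centroids per draw).
#' @param syndromes a [syndrome_map()], used when `centroids` is missing
#'   and required for `method = "average"`.
#' @param method `"plugin"` (distance between posterior-mean positions) or
#'   `"average"` (posterior mean of the per-draw distances, which folds
#'   posterior uncertainty into the feature).
#' @return N x K matrix of non-negative distances.
#' @export
respondent_syndrome_distances <- function(fit, centroids = NULL,
                                          syndromes = NULL,
                                          method = c("plugin", "average")) {
  stopifnot(inherits(fit, "lsirm"))
  method <- match.arg(method)
  if (method == "average") {
    stopifnot(!is.null(syndromes))
    labs <- syndromes$syndrome_order
    members <- lapply(labs, function(s)
      match(intersect(syndrome_items(syndromes, s), fit$data$item_ids),
            fit$data$item_ids))
    names(members) <- labs
    members <- members[lengths(members) > 0]
    N <- dim(fit$Z)[1]; S <- dim(fit$Z)[3]
    out <- matrix(0, N, length(members),
                  dimnames = list(fit$data$respondent_ids, names(members)))
    for (s in seq_len(S)) {
      Zs <- fit$Z[, , s]
      for (j in seq_along(members)) {
        cen <- colMeans(matrix(fit$W[members[[j]], , s],
                               ncol = dim(fit$W)[2]))
        out[, j] <- out[, j] + sqrt(rowSums(sweep(Zs, 2, cen)^2))
      }
    }
    return(out / S)
  }
  if (is.null(centroids)) {
    stopifnot(!is.null(syndromes))
    centroids <- syndrome_centroids(fit, syndromes)
  }
  cen <- centroids$centroids
  Z <- fit$Z_mean
  out <- matrix(0, nrow(Z), nrow(cen),
                dimnames = list(rownames(Z), rownames(cen)))
  for (k in seq_len(nrow(cen)))
    out[, k] <- sqrt(rowSums(sweep(Z, 2, cen[k, ])^2))
  out
}

#' Cluster respondents on their syndrome-distance profiles
#'
#' K-means (25 restarts) on the rows of a respondent-by-syndrome distance
#' matrix.  Respondents whose positions sit near the same syndromes share a
#' profile and land in the same cluster; the per-cluster mean distance to
#' each syndrome characterizes what each cluster is close to.
#'
#' @param dist_matrix N x K matrix from [respondent_syndrome_distances()].
#' @param k number of clusters (default 4).
#' @param seed integer seed for the restarts.
#' @param nstart number of random restarts.
#' @return A list of class `"respondent_clusters"`: `labels` (length-N
#'   integer vector), `profile` (k x K matrix of mean distances), `sizes`,
#'   and the underlying `kmeans` object.
#' @export
cluster_respondents <- function(dist_matrix, k = 4, seed = NULL,
                                nstart = 25) {
  dist_matrix <- as.matrix(dist_matrix)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > nrow(dist_matrix))
    stop("k exceeds the number of respondents", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(dist_matrix, centers = k, nstart = nstart,
                      iter.max = 100)
  profile <- apply(dist_matrix, 2, function(col) tapply(col, km$cluster, mean))
  structure(list(labels = km$cluster, profile = profile,
                 sizes = km$size, kmeans = km),
            class = "respondent_clusters")
}

#' @export
print.respondent_clusters <- function(x, ...) {
  cat(sprintf("Respondent clustering: %d clusters, sizes %s\n",
              length(x$sizes), paste(x$sizes, collapse = "/")))
  cat("Mean distance to each syndrome by cluster:\n")
  print(round(x$profile, 3))
  invisible(x)
}
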