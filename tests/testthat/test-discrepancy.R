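test_that("distance samples match a per-draw loop oracle", {
  sim <- quick_sim(seed = 51, N = 15, P = 6)
  f <- quick_fit(sim$data$a, seed = 2, n_iter = 400, burnin = 100, thin = 3)
  ds <- distance_samples(f, 2, 5)
  oracle <- vapply(seq_len(n_draws(f)), function(s)
    sqrt(sum((f$W[2, , s] - f$W[5, , s])^2)), 0)
  expect_equal(ds$samples, oracle, tolerance = 1e-12)
  expect_identical(length(ds$samples), n_draws(f))
  expect_true(all(ds$samples >= 0))
  # by id as well as by index
  expect_equal(distance_samples(f, "Item 2", "Item 5")$samples, ds$samples)
  expect_warning(dd <- distance_samples(f, 3, 3), "same item")
  expect_true(all(dd$samples == 0))
})

test_that("overlap statistic behaves like a bounded density overlap", {
  set.seed(52)
  a <- rnorm(4000)
  same <- overlap_R(a, a)
  expect_gt(same$R, 0.98)
  expect_false(same$flag_different)
  far <- overlap_R(a, a + 100)
  expect_lt(far$R, 0.01)
  expect_true(far$flag_different)
  # symmetry
  b <- rnorm(4000, 1)
  expect_equal(overlap_R(a, b)$R, overlap_R(b, a)$R, tolerance = 1e-10)
  expect_error(overlap_R(numeric(0), a), "empty")
})

test_that("overlap matches numeric integration of the true densities", {
  # two unit-variance Gaussians a shift apart overlap by 2*pnorm(-shift/2)
  grid <- seq(-10, 12, length.out = 20001)
  set.seed(53)
  prev <- Inf
  for (shift in c(0, 0.5, 1, 2)) {
    oracle <- sum(pmin(dnorm(grid), dnorm(grid, shift))) * diff(grid[1:2])
    expect_equal(oracle, 2 * pnorm(-shift / 2), tolerance = 1e-6)
    r <- overlap_R(rnorm(5000), rnorm(5000, shift))$R
    expect_lt(abs(r - oracle), 0.03)
    expect_lt(r, prev + 1e-12)  # monotone decreasing in the shift
    prev <- r
  }
})

test_that("KL divergence is non-negative and matches the Gaussian closed form", {
  set.seed(54)
  a <- rnorm(5000)
  expect_lt(kl_divergence(a, a)$kl, 0.02)
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(500, runif(1, -1, 1), runif(1, 0.5, 2))
    y <- rnorm(500, runif(1, -1, 1), runif(1, 0.5, 2))
    kl <- kl_divergence(x, y)
    expect_gte(kl$kl, 0)
    expect_gte(kl$kl_reverse, 0)
    expect_equal(kl$symmetrized, (kl$kl + kl$kl_reverse) / 2)
  }
  # KL(N(0,1) || N(1,1)) = 1/2
  expect_lt(abs(kl_divergence(rnorm(5000), rnorm(5000, 1))$kl - 0.5), 0.1)
})

test_that("KS comparison gives the textbook edge cases", {
  x <- c(1, 2, 3)
  expect_equal(ks_compare(x, x)$statistic, 0)
  expect_equal(ks_compare(x, c(4, 5, 6))$statistic, 1)
  set.seed(55)
  ks <- ks_compare(rnorm(200), rnorm(200, 2))
  expect_true(ks$statistic >= 0 && ks$statistic <= 1)
  expect_lt(ks$p_value, 0.01)
})

test_that("cosine similarity covers the closed-form cases", {
  expect_equal(cosine_similarity(c(1, 2), c(1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 2), -c(1, 2)), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 3)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("syndrome centroids average the member item positions", {
  set.seed(56)
  W <- matrix(rnorm(12), 6, 2)
  f <- fake_fit(rnorm(6), rnorm(4), W, matrix(rnorm(8), 4, 2))
  sm <- syndrome_map(stats::setNames(c("AB", "AB", "AD", "none", "SC", "AB"),
                                     f$data$item_ids))
  expect_warning(cen <- syndrome_centroids(f, sm), "no member items")
  expect_equal(cen$centroids["AB", ], colMeans(W[c(1, 2, 6), ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # single-member syndrome sits on its item
  expect_equal(cen$centroids["AD", ], W[3, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # two items at +/-v have their centroid at the origin
  f2 <- fake_fit(c(0, 0), c(0, 0), rbind(c(1, 2), c(-1, -2)),
                 matrix(0, 2, 2))
  sm2 <- syndrome_map(stats::setNames(c("TP", "TP"), f2$data$item_ids))
  expect_warning(cen2 <- syndrome_centroids(f2, sm2))
  expect_equal(unname(cen2$centroids["TP", ]), c(0, 0), tolerance = 1e-12)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(57)
  f <- fake_fit(rnorm(8), rnorm(5), matrix(rnorm(16), 8, 2),
                matrix(rnorm(10), 5, 2))
  sm <- syndrome_map(stats::setNames(rep(c("AB", "AD", "SC", "TP"), 2),
                                     f$data$item_ids))
  suppressWarnings(S <- syndrome_similarity(f, sm))
  expect_equal(diag(S), rep(1, 4), ignore_attr = TRUE)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))
})

test_that("respondent-syndrome distances match a loop oracle", {
  set.seed(58)
  f <- fake_fit(rnorm(6), rnorm(5), matrix(rnorm(12), 6, 2),
                matrix(rnorm(10), 5, 2))
  sm <- syndrome_map(stats::setNames(c("AB", "AB", "AD", "AD", "SC", "SC"),
                                     f$data$item_ids))
  suppressWarnings({
    cen <- syndrome_centroids(f, sm)
    dm <- respondent_syndrome_distances(f, cen)
  })
  for (k in 1:5) {
    for (s in seq_len(nrow(cen$centroids))) {
      expect_equal(dm[k, s],
                   sqrt(sum((f$Z_mean[k, ] - cen$centroids[s, ])^2)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  expect_true(all(dm >= 0))
  # triangle inequality between any respondent and two centroids
  cc <- sqrt(sum((cen$centroids[1, ] - cen$centroids[2, ])^2))
  expect_true(all(dm[, 1] + dm[, 2] >= cc - 1e-12))
  # the averaged variant agrees for a chain of identical draws
  dm_avg <- respondent_syndrome_distances(f, syndromes = sm,
                                          method = "average")
  expect_equal(dm_avg, dm[, colnames(dm_avg)], tolerance = 1e-12)
})

test_that("k-means separates well-separated profiles and is reproducible", {
  set.seed(59)
  blob1 <- matrix(rnorm(40, 0, 0.1), 20, 2)
  blob2 <- matrix(rnorm(40, 5, 0.1), 20, 2)
  dm <- rbind(blob1, blob2)
  cl <- cluster_respondents(dm, k = 2, seed = 60)
  expect_identical(length(unique(cl$labels[1:20])), 1L)
  expect_identical(length(unique(cl$labels[21:40])), 1L)
  expect_false(cl$labels[1] == cl$labels[21])
  cl2 <- cluster_respondents(dm, k = 2, seed = 60)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_respondents(dm, k = 50), "exceeds")
  expect_error(cluster_respondents(dm, k = 1), "at least 2")
  expect_identical(dim(cl$profile), c(2L, 2L))
})

test_that("easiness comparison reports correlation, line and flags", {
  set.seed(61)
  beta <- rnorm(10)
  f1 <- fake_fit(beta, rnorm(5), matrix(rnorm(20), 10, 2),
                 matrix(rnorm(10), 5, 2))
  same <- beta_compare(f1, f1)
  expect_equal(same$r, 1)
  expect_length(same$flagged, 0)

  f2 <- f1
  f2$beta_mean <- 2 * f1$beta_mean
  doubled <- beta_compare(f1, f2)
  expect_equal(doubled$r, 1)
  expect_equal(unname(coef(doubled$fit)[2]), 2, tolerance = 1e-8)
  expect_length(doubled$flagged, 0)

  # one grossly shifted item is flagged
  f3 <- f1
  f3$beta_mean <- f1$beta_mean + c(rep(0, 9), 5) +
    rnorm(10, 0, 0.05)
  shifted <- beta_compare(f1, f3)
  expect_identical(shifted$flagged, "Item 10")
})

test_that("overlap matrix of a fit with itself flags nothing", {
  sim <- quick_sim(seed = 62, N = 20, P = 6)
  f <- quick_fit(sim$data$a, seed = 3, n_iter = 400, burnin = 100, thin = 3)
  ov <- overlap_matrix(f, f)
  expect_true(all(is.na(diag(ov$R))))
  expect_equal(ov$R, t(ov$R), tolerance = 1e-12)
  expect_true(all(ov$R[upper.tri(ov$R)] > 0.9))
  expect_identical(ov$flagged_proportion, 0)
  tabs <- distance_difference_table(f, f, top_k = 5, overlap = ov)
  expect_identical(nrow(tabs$by_mean_difference), 5L)
  expect_true(all(tabs$by_mean_difference$abs_mean_difference < 1e-12))
  expect_identical(nrow(tabs$by_overlap), 5L)
})
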