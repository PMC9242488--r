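test_that("simulation is reproducible and validates its configuration", {
  cfg <- quick_config()
  s1 <- simulate_paired(cfg, seed = 5)
  s2 <- simulate_paired(cfg, seed = 5)
  expect_identical(s1$data$a$values, s2$data$a$values)
  expect_identical(s1$truth$beta_b, s2$truth$beta_b)
  s3 <- simulate_paired(cfg, seed = 6)
  expect_false(identical(s1$data$a$values, s3$data$a$values))
  expect_error(simulate_paired(cfg), "seed is mandatory")
  expect_error(sim_config(missing_rate = 0.2), "missing_rate")
  expect_error(sim_config(n_items = 10, n_shift = 8, n_displace = 6),
               "larger than the item set")
})

test_that("instrument simulation follows the response model cell-wise", {
  # impossibly hard items produce an all-zero matrix
  truth <- list(beta = rep(-30, 3), theta = rep(0, 4),
                W = matrix(0, 3, 2), Z = matrix(0, 4, 2))
  m <- simulate_instrument(truth, seed = 7)
  expect_true(all(m$values == 0))
  expect_identical(simulate_instrument(truth, seed = 8)$values,
                   simulate_instrument(truth, seed = 8)$values)
  # empirical cell frequency over many replicate respondents with an
  # identical parameter row approaches the model probability
  n_rep <- 10000
  truth2 <- list(beta = c(0.4, -1), theta = rep(0.3, n_rep),
                 W = rbind(c(0, 0), c(1, 0)),
                 Z = matrix(rep(c(0.5, 0), each = n_rep), n_rep, 2))
  m2 <- simulate_instrument(truth2, seed = 9)
  for (i in 1:2) {
    p_true <- success_probability(truth2$beta[i], 0.3, truth2$W[i, ],
                                  c(0.5, 0))
    se <- sqrt(p_true * (1 - p_true) / n_rep)
    expect_lt(abs(mean(m2$values[, i]) - p_true), 3 * se)
  }
})

test_that("positive-response rates are calibrated to their targets", {
  sim <- simulate_paired(sim_config(), seed = 10)  # full-size defaults
  expect_lt(abs(positive_rate(sim$data$a) - 0.27), 0.03)
  expect_lt(abs(positive_rate(sim$data$b) - 0.43), 0.03)
  # across-item dispersion of rates resembles dichotomized checklist data
  expect_lt(abs(sd(positive_rate(sim$data$a, by = "item")) - 0.17), 0.05)
  expect_lt(abs(sd(positive_rate(sim$data$b, by = "item")) - 0.24), 0.05)
})

test_that("random masking hits its expected cell count and is seed-stable", {
  m <- response_matrix(matrix(1L, 662, 118))
  expect_identical(apply_mar_mask(m, 0)$values, m$values)
  masked <- apply_mar_mask(m, 0.002, seed = 11)
  n_masked <- sum(is.na(masked$values))
  expected <- 662 * 118 * 0.002
  se <- sqrt(662 * 118 * 0.002 * 0.998)
  expect_lt(abs(n_masked - expected), 3 * se)
  expect_identical(apply_mar_mask(m, 0.002, seed = 11)$values,
                   masked$values)
})

test_that("zero-discrepancy configurations give identical truths", {
  cfg <- sim_config_null(quick_config())
  sim <- simulate_paired(cfg, seed = 12)
  expect_identical(sim$truth$beta_a, sim$truth$beta_b)
  expect_identical(sim$truth$W_a, sim$truth$W_b)
  expect_identical(sim$truth$Z_a, sim$truth$Z_b)
  expect_lt(abs(positive_rate(sim$data$a) - positive_rate(sim$data$b)),
            0.05)
})

test_that("easiness shifts raise the shifted items' rates in instrument b", {
  cfg <- sim_config(n_respondents = 300, n_items = 40, n_shift = 12,
                    n_displace = 0, jitter_sd = 0, target_rate_a = 0.3,
                    target_rate_b = 0.3, delta_beta = 1.5)
  sim <- simulate_paired(cfg, seed = 13)
  sh <- sim$truth$shifted_items
  expect_length(sh, 12)
  rate_a <- positive_rate(sim$data$a, by = "item")
  rate_b <- positive_rate(sim$data$b, by = "item")
  expect_true(all(rate_b[sh] > rate_a[sh]))
  # with equal rate targets the non-shifted items move the other way or
  # stay put on average (the global offset re-balances the total rate)
  other <- setdiff(names(rate_a), sh)
  expect_lt(mean(rate_b[other] - rate_a[other]), 0.02)
  # truth bookkeeping: instrument-b intercepts differ from a by the shift
  # plus a common offset
  diff_b <- sim$truth$beta_b - sim$truth$beta_a
  expect_equal(unname(diff_b[sh] - mean(diff_b[sh])), rep(0, 12),
               tolerance = 1e-12)
  expect_equal(unname(diff_b[sh][1] - diff_b[other][1]), 1.5,
               tolerance = 1e-12)
})

test_that("displaced items move rigidly and jitter perturbs respondents", {
  cfg <- sim_config(n_respondents = 100, n_items = 30, n_shift = 0,
                    n_displace = 5, displacement = c(2, -1),
                    jitter_sd = 0.3)
  sim <- simulate_paired(cfg, seed = 14)
  dp <- match(sim$truth$displaced_items, colnames(sim$data$a$values))
  expect_length(dp, 5)
  expect_equal(sim$truth$W_b[dp, ] - sim$truth$W_a[dp, ],
               matrix(rep(c(2, -1), each = 5), 5, 2), tolerance = 1e-12)
  expect_identical(sim$truth$W_b[-dp, ], sim$truth$W_a[-dp, ])
  expect_gt(sd(sim$truth$Z_b - sim$truth$Z_a), 0.2)
})

test_that("syndrome geometry opposes the two higher-order poles", {
  sim <- simulate_paired(sim_config(n_shift = 0, n_displace = 0), seed = 15)
  sm <- sim$truth$syndromes
  W <- sim$truth$W_a
  ids <- names(sm$assignments)
  centroid <- function(s)
    colMeans(W[match(syndrome_items(sm, s), ids), , drop = FALSE])
  ext <- sapply(sm$externalizing, centroid)
  int <- sapply(sm$internalizing, centroid)
  # within-pole directions agree, between-pole directions oppose
  expect_gt(cosine_similarity(ext[, 1], ext[, 2]), 0.7)
  for (i in seq_len(ncol(int)))
    for (j in seq_len(ncol(int)))
      if (i < j) expect_gt(cosine_similarity(int[, i], int[, j]), 0.7)
  expect_lt(cosine_similarity(rowMeans(ext), rowMeans(int)), -0.9)
})
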