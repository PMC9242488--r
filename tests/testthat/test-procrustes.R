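test_that("identity and exact rigid motions are recovered", {
  set.seed(41)
  Z0 <- matrix(rnorm(12), 6, 2)
  tr <- procrustes_fit(Z0, Z0)
  expect_equal(tr$rotation, diag(2), tolerance = 1e-10)
  expect_equal(tr$residual, 0, tolerance = 1e-12)

  for (seed in 1:4) {
    rig <- random_rigid(seed)
    Z <- Z0 %*% rig$R + rep(rig$t, each = 6)
    tr <- procrustes_fit(Z, Z0)
    expect_lt(tr$residual, 1e-8)
    expect_equal(apply_transform(tr, Z), Z0, tolerance = 1e-8)
    expect_equal(crossprod(tr$rotation), diag(2), tolerance = 1e-8)
    expect_equal(abs(det(tr$rotation)), 1, tolerance = 1e-8)
  }
})

test_that("the fitted transform beats a 1-degree grid search", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(12), 6, 2)
    X0 <- matrix(rnorm(12), 6, 2)
    fit_res <- procrustes_fit(X, X0)$residual
    best <- Inf
    for (flip in list(diag(2), diag(c(1, -1)))) {
      for (ang in seq(0, 359) * pi / 180) {
        R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2) %*% flip
        XR <- X %*% R
        tt <- colMeans(X0) - colMeans(XR)
        best <- min(best, sum((X0 - sweep(XR, 2, tt, "+"))^2))
      }
    }
    expect_lte(fit_res, best + 1e-10)
  }
})

test_that("procrustes residual is symmetric in its arguments", {
  set.seed(43)
  A <- matrix(rnorm(10), 5, 2); B <- matrix(rnorm(10), 5, 2)
  expect_equal(procrustes_fit(A, B)$residual, procrustes_fit(B, A)$residual,
               tolerance = 1e-8)
})

test_that("procrustes solution agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(44)
  X <- matrix(rnorm(16), 8, 2); X0 <- matrix(rnorm(16), 8, 2)
  ours <- procrustes_fit(X, X0)
  ref <- vegan::procrustes(X0, X, scale = FALSE, symmetric = FALSE)
  expect_equal(ours$residual, sum(stats::residuals(ref)^2), tolerance = 1e-8)
  expect_equal(ours$rotation, unclass(ref$rotation), tolerance = 1e-8,
               ignore_attr = TRUE)
  # vegan reports the rotated configuration about the target's centroid
  expect_equal(apply_transform(ours, X),
               sweep(unclass(ref$Yrot), 2, as.numeric(ref$xmean), "+"),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("chain alignment collapses rigid-motion-equivalent draws", {
  set.seed(45)
  base_W <- matrix(rnorm(8), 4, 2); base_Z <- matrix(rnorm(6), 3, 2)
  ff <- fake_fit(rnorm(4), rnorm(3), base_W, base_Z, S = 5)
  for (s in 1:4) {  # draws 1..4 are rigid motions of draw 5's configuration
    rig <- random_rigid(100 + s)
    st <- rbind(base_W, base_Z) %*% rig$R + rep(rig$t, each = 7)
    ff$W[, , s] <- st[1:4, ]; ff$Z[, , s] <- st[5:7, ]
  }
  ff$aligned <- FALSE
  al <- procrustes_align(ff)
  for (s in 1:4) {
    expect_equal(al$W[, , s], al$W[, , 5], tolerance = 1e-8)
    expect_equal(al$Z[, , s], al$Z[, , 5], tolerance = 1e-8)
  }
})

test_that("alignment preserves every within-draw distance and likelihood", {
  sim <- quick_sim(seed = 46, N = 15, P = 6, missing_rate = 0)
  f <- lsirm(sim$data$a, control = lsirm_control(400, 100, 3), seed = 3,
             align = FALSE)
  dist_pre <- lapply(1:5, function(s)
    as.matrix(dist(rbind(f$W[, , s], f$Z[, , s]))))
  ll_pre <- vapply(1:5, function(s)
    lsirm_log_likelihood(f$beta[s, ], f$theta[s, ], f$W[, , s], f$Z[, , s],
                         sim$data$a$values), 0)
  al <- procrustes_align(f)
  for (s in 1:5) {
    expect_equal(as.matrix(dist(rbind(al$W[, , s], al$Z[, , s]))),
                 dist_pre[[s]], tolerance = 1e-10)
  }
  ll_post <- vapply(1:5, function(s)
    lsirm_log_likelihood(al$beta[s, ], al$theta[s, ], al$W[, , s],
                         al$Z[, , s], sim$data$a$values), 0)
  expect_equal(ll_post, ll_pre, tolerance = 1e-10)
  # intercepts, traits and the variance are untouched
  expect_identical(al$beta, f$beta)
  expect_identical(al$sigma_sq, f$sigma_sq)
})

test_that("matching maps onto a reference recovers rigid motions exactly", {
  set.seed(47)
  ref <- fake_fit(rnorm(5), rnorm(4), matrix(rnorm(10), 5, 2),
                  matrix(rnorm(8), 4, 2))
  self_match <- match_maps(ref, ref)
  expect_equal(attr(self_match, "match_transform")$rotation, diag(2),
               tolerance = 1e-8)
  expect_equal(self_match$W_mean, ref$W_mean, tolerance = 1e-10)

  rig <- random_rigid(48)
  other <- ref
  move <- function(M) M %*% rig$R + rep(rig$t, each = nrow(M))
  other$W_mean <- move(ref$W_mean); other$Z_mean <- move(ref$Z_mean)
  for (s in seq_len(dim(other$W)[3])) {
    other$W[, , s] <- move(ref$W[, , s]); other$Z[, , s] <- move(ref$Z[, , s])
  }
  dist_before <- as.matrix(dist(other$W_mean))
  matched <- match_maps(ref, other)
  expect_equal(matched$W_mean, ref$W_mean, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(matched$Z_mean, ref$Z_mean, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(as.matrix(dist(matched$W_mean)), dist_before,
               tolerance = 1e-10, ignore_attr = TRUE)
  wrong <- ref
  wrong$data$item_ids[1] <- "other item"
  expect_error(match_maps(ref, wrong), "identical item ids")
})
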