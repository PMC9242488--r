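make_paired <- function(va, vb, syn) {
  ids <- colnames(va)
  a <- response_matrix(va, informant = "parent")
  b <- response_matrix(vb, informant = "self")
  paired_dataset(a, b, syndrome_map(stats::setNames(syn, ids)))
}

test_that("syndrome sum scores add non-missing member items", {
  v <- matrix(c(1, 0, 1,
                0, 1, NA,
                1, 1, 0), 3, 3, byrow = TRUE,
              dimnames = list(paste0("r", 1:3), paste0("i", 1:3)))
  m <- response_matrix(v)
  sm <- syndrome_map(c(i1 = "AB", i2 = "AB", i3 = "AD"))
  sc <- syndrome_sum_scores(m, sm)
  expect_equal(unname(sc$scores[, "AB"]), c(1L, 1L, 2L))
  expect_equal(unname(sc$scores[, "AD"]), c(1L, 0L, 0L))
  expect_equal(unname(sc$n_available[2, ]), c(2L, 0L))
  expect_identical(unname(sc$n_items), c(2L, 1L))
  # zero matrix gives zero scores
  z <- syndrome_sum_scores(response_matrix(matrix(0, 2, 3,
         dimnames = list(NULL, paste0("i", 1:3)))), sm)
  expect_true(all(z$scores == 0))
  # loop oracle on a random fixture
  set.seed(71)
  vr <- matrix(sample(c(0L, 1L, NA), 80, TRUE, c(.45, .45, .1)), 8, 10,
               dimnames = list(NULL, paste0("q", 1:10)))
  syn <- sample(c("AB", "AD", "SC", "none"), 10, TRUE)
  mr <- response_matrix(vr)
  smr <- syndrome_map(stats::setNames(syn, colnames(vr)))
  scr <- syndrome_sum_scores(mr, smr)
  for (s in colnames(scr$scores)) {
    members <- names(which(smr$assignments == s))
    for (k in 1:8)
      expect_identical(scr$scores[k, s],
                       as.integer(sum(vr[k, members], na.rm = TRUE)))
  }
})

test_that("syndrome correlations follow the textbook formula", {
  sa <- structure(list(scores = cbind(AB = c(1, 2, 3, 4), AD = c(0, 1, 1, 2)),
                       n_available = NULL, n_items = NULL),
                  class = "syndrome_scores")
  sb <- structure(list(scores = cbind(AB = c(2, 1, 4, 5), AD = c(2, 2, 2, 2)),
                       n_available = NULL, n_items = NULL),
                  class = "syndrome_scores")
  expect_warning(rr <- syndrome_correlations(sa, sb), "zero-variance")
  x <- sa$scores[, "AB"]; y <- sb$scores[, "AB"]
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(rr["AB"]), hand)
  expect_true(is.na(rr["AD"]))
  # perfect and inverted agreement
  expect_equal(unname(suppressWarnings(
    syndrome_correlations(sa, sa))["AB"]), 1)
  sneg <- sa; sneg$scores <- -sa$scores + 10
  expect_equal(unname(suppressWarnings(
    syndrome_correlations(sa, sneg))["AB"]), -1)
})

test_that("item kappa matches hand computation and the chance-level case", {
  va <- cbind(i1 = c(1L, 1L, 0L, 0L), i2 = c(1L, 0L, 1L, 0L))
  vb <- cbind(i1 = c(1L, 0L, 1L, 0L), i2 = c(1L, 0L, 1L, 0L))
  pd <- make_paired(va, vb, c("AB", "AB"))
  kap <- item_kappa(pd$a, pd$b, pd$syndromes)
  expect_equal(unname(kap$kappa["i1"]), 0)   # agreement exactly at chance
  expect_equal(unname(kap$kappa["i2"]), 1)   # identical columns
  expect_equal(unname(kap$syndrome_mean["AB"]), 0.5)
  # identical instruments give kappa 1 everywhere
  self_k <- item_kappa(pd$a, pd$a)
  expect_true(all(self_k$kappa == 1))
  # degenerate marginals are flagged, not computed
  vc <- cbind(i1 = c(0L, 0L, 0L, 0L), i2 = c(1L, 1L, 1L, 1L))
  pdc <- make_paired(vc, vc, c("AB", "AB"))
  expect_true(all(is.na(item_kappa(pdc$a, pdc$b)$kappa)))
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(72)
  x <- rbinom(300, 1, 0.4)
  y <- ifelse(runif(300) < 0.7, x, rbinom(300, 1, 0.4))
  a <- response_matrix(cbind(i1 = x, i2 = rbinom(300, 1, .5)))
  b <- response_matrix(cbind(i1 = y, i2 = rbinom(300, 1, .5)))
  ours <- item_kappa(a, b)$kappa["i1"]
  ref <- e1071::classAgreement(table(x, y))$kappa
  expect_equal(unname(ours), ref, tolerance = 1e-12)
})

test_that("kappa is near zero for independent informants", {
  set.seed(73)
  n <- 10000
  a <- response_matrix(cbind(i1 = rbinom(n, 1, 0.4), i2 = rbinom(n, 1, 0.6)))
  b <- response_matrix(cbind(i1 = rbinom(n, 1, 0.4), i2 = rbinom(n, 1, 0.6)))
  kap <- item_kappa(a, b)$kappa
  expect_true(all(abs(kap) < 0.03))
  expect_true(all(kap >= -1 & kap <= 1))
})

test_that("jaccard similarity counts shared positives over the union", {
  v <- cbind(A = c(1L, 1L, 0L), B = c(1L, 0L, 1L), C = c(1L, 1L, 0L),
             D = c(0L, 0L, 0L))
  J <- jaccard_similarity(response_matrix(v))$J
  expect_equal(J["A", "B"], 1 / 3, ignore_attr = TRUE)
  expect_equal(J["A", "C"], 1, ignore_attr = TRUE)
  expect_true(is.na(J["D", "D"]))      # empty union is undefined
  expect_equal(J["A", "A"], 1, ignore_attr = TRUE)
  # disjoint supports
  v2 <- cbind(A = c(1L, 0L), B = c(0L, 1L))
  expect_equal(jaccard_similarity(response_matrix(v2))$J["A", "B"], 0,
               ignore_attr = TRUE)
})

test_that("jaccard difference ranks pairs and excludes undefined ones", {
  va <- cbind(i1 = c(1L, 1L, 0L, 0L), i2 = c(1L, 1L, 0L, 0L),
              i3 = c(0L, 0L, 1L, 1L), i4 = c(0L, 0L, 0L, 0L),
              i5 = c(0L, 0L, 0L, 0L))
  vb <- cbind(i1 = c(1L, 1L, 0L, 0L), i2 = c(0L, 0L, 1L, 1L),
              i3 = c(0L, 0L, 1L, 1L), i4 = c(0L, 0L, 0L, 0L),
              i5 = c(0L, 0L, 0L, 0L))
  jd <- jaccard_difference(response_matrix(va), response_matrix(vb),
                           top_k = 3)
  expect_equal(jd$difference["i1", "i2"], -1, ignore_attr = TRUE)
  expect_identical(jd$top_pairs$item_i[1], "i1")
  expect_identical(jd$undefined_pairs, 1L)  # i4-i5 has an empty union twice
  expect_true(all(jd$J_a >= 0 | is.na(jd$J_a)))
})

test_that("baseline statistics are equivariant to respondent permutation", {
  set.seed(74)
  va <- matrix(rbinom(60, 1, 0.4), 10, 6,
               dimnames = list(NULL, paste0("i", 1:6)))
  vb <- matrix(rbinom(60, 1, 0.5), 10, 6,
               dimnames = list(NULL, paste0("i", 1:6)))
  syn <- rep(c("AB", "AD"), 3)
  pd <- make_paired(va, vb, syn)
  perm <- sample(10)
  pd2 <- make_paired(va[perm, ], vb[perm, ], syn)
  expect_equal(item_kappa(pd$a, pd$b)$kappa, item_kappa(pd2$a, pd2$b)$kappa)
  expect_equal(jaccard_difference(pd$a, pd$b)$difference,
               jaccard_difference(pd2$a, pd2$b)$difference)
  expect_equal(
    syndrome_correlations(syndrome_sum_scores(pd$a, pd$syndromes),
                          syndrome_sum_scores(pd$b, pd$syndromes)),
    syndrome_correlations(syndrome_sum_scores(pd2$a, pd2$syndromes),
                          syndrome_sum_scores(pd2$b, pd2$syndromes)))
})
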