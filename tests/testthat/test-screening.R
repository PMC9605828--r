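test_that("Mahalanobis distance flags a perturbed duplicate and reduces to
           the Euclidean norm under identity score covariance", {
  g <- make_grid(9000, 5000, 20)
  base <- sin(seq_len(20))
  mat <- matrix(rep(base, each = 12), 12, byrow = FALSE)
  set.seed(4)
  mat <- mat + matrix(rnorm(12 * 20, sd = 0.01), 12)
  mat[7, ] <- mat[7, ] + 0.5
  s <- spectrum_set(sprintf("s%d", 1:12), g, mat)
  d <- mahalanobis_distances(s, n_components = 3)
  expect_true(all(d >= 0))
  expect_equal(which.max(d), 7L)

  # data confined to a 2-D subspace with whitened (identity) covariance:
  # the PCA-space Mahalanobis distance is the Euclidean norm of the
  # centred rows
  set.seed(5)
  Z <- matrix(rnorm(40), 20, 2)
  Z <- scale(Z, scale = FALSE)
  W <- Z %*% solve(chol(cov(Z)))          # unit covariance scores
  X <- cbind(W, matrix(0, 20, 6))
  s2 <- spectrum_set(sprintf("s%d", 1:20), make_grid(9000, 5000, 8), X)
  d2 <- mahalanobis_distances(s2, n_components = 2)
  expect_equal(d2, sqrt(rowSums(scale(W, scale = FALSE)^2)), tolerance = 1e-8)
})

test_that("Mahalanobis distances are invariant to a common affine map", {
  sim <- tiny_sim(n = 15, p = 30, seed = 6)
  s <- sim$spectra
  set.seed(8)
  A <- diag(30) + matrix(rnorm(900, sd = 0.05), 30)
  b <- rnorm(30)
  s2 <- spectrum_set(s$sample_ids, s$grid,
                     sweep(s$absorbance %*% A, 2L, b, "+"))
  # invariance requires the score space to span the full data rank (n - 1)
  d1 <- mahalanobis_distances(s, n_components = 14)
  d2 <- mahalanobis_distances(s2, n_components = 14)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("Dixon's Q test matches the gap/range arithmetic", {
  res <- dixon_test(c(0.10, 0.15, 0.16, 0.17, 0.95), alpha = 0.05)
  expect_equal(res$Q, (0.95 - 0.17) / (0.95 - 0.10))
  expect_true(res$flag)
  expect_equal(res$suspect, 5L)

  same <- dixon_test(rep(2, 5))
  expect_false(same$flag)
  expect_equal(same$Q, 0)

  sym <- dixon_test(1:5, alpha = 0.05)
  expect_false(sym$flag)   # Q = 0.25 against critical 0.710

  expect_error(dixon_test(1:2), "3 <= n <= 30")
  expect_error(dixon_test(1:31), "3 <= n <= 30")
  expect_error(dixon_test(1:5, alpha = 0.2), "tabulated")
})

test_that("Chauvenet's criterion applies the normal-tail expected count", {
  # n = 10 with one point about 4 SD out: expected count well below 0.5
  v <- c(0.97, 1.03, 0.99, 1.01, 0.98, 1.02, 0.96, 1.04, 1.00, 1.60)
  res <- chauvenet(v)
  z <- abs(v - mean(v)) / sd(v)
  oracle <- 10 * 2 * pnorm(z, lower.tail = FALSE) < 0.5
  expect_identical(res$flag, oracle)
  expect_true(res$flag[10])
  expect_false(any(res$flag[1:9]))

  expect_message(res0 <- chauvenet(rep(3, 6)), "zero spread")
  expect_false(any(res0$flag))

  # n = 4 at one SD: 4 * 0.317 > 0.5, not flagged
  v4 <- c(-1, 1, -1, 1)
  expect_false(any(chauvenet(v4)$flag))

  expect_error(chauvenet(1:3), "n >= 4")
})

test_that("screening excludes a grossly outlying spectrum and nothing else
           in clean data", {
  sim <- tiny_sim(n = 40, p = 60, seed = 12)
  s <- sim$spectra
  rep_clean <- screen_outliers(s)
  expect_true(all(rep_clean$excluded %in% s$sample_ids))

  bad <- s
  bad$absorbance[13, ] <- bad$absorbance[13, ] + 5
  bad <- spectrum_set(s$sample_ids, s$grid, bad$absorbance)
  rep_bad <- screen_outliers(bad)
  expect_true("s013" %in% rep_bad$excluded)
  expect_equal(rep_bad$ranked_ids[1], "s013")
  expect_true(all(rep_bad$distance >= 0))
})
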