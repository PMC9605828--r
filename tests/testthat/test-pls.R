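test_that("PLS nails exact low-rank data with one component", {
  set.seed(1)
  t <- rnorm(25)
  p <- rnorm(8)
  X <- outer(t, p)
  fit <- fit_pls(X, t, 1)
  expect_lt(max(abs(fit$fitted - t)), 1e-10)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  fit <- fit_pls(X, y, 5)
  ols <- lm.fit(cbind(1, X), y)
  pred_ols <- cbind(1, X) %*% ols$coefficients
  expect_lt(max(abs(predict(fit, X) - pred_ols)), 1e-8)
})

test_that("PLS input contracts are enforced", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_pls(X, rep(1, 10), 2), "zero variance")
  expect_error(fit_pls(X, rnorm(10), 10), "n_lv")
  expect_error(fit_pls(X, rnorm(9), 2), "length")
})

test_that("the affine prediction contract holds", {
  set.seed(3)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  fit <- fit_pls(X, y, 3)
  expect_lt(max(abs(predict(fit, X) - fit$fitted)), 1e-10)
  expect_equal(predict(fit, matrix(fit$x_mean, 1)), fit$y_mean,
               tolerance = 1e-10)
  expect_error(predict(fit, X[, 1:3]), "columns")
})

test_that("scores are orthogonal and training error is monotone in LVs", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 12), 30)
    y <- X %*% rnorm(12) + rnorm(30, sd = 0.3)
    fit <- fit_pls(X, y, 6)
    G <- crossprod(fit$scores)
    off <- G - diag(diag(G))
    expect_lt(max(abs(off)) / max(diag(G)), 1e-8)

    rmsec <- vapply(1:6, function(a) {
      rmse(fit_pls(X, y, a)$fitted, y)
    }, numeric(1))
    expect_true(all(diff(rmsec) <= 1e-12))
  }
})

test_that("NIPALS agrees with an independent SIMPLS implementation", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 18; p <- 10; a <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n)
    y <- X %*% rnorm(p) + rnorm(n, sd = 0.5)
    Xnew <- matrix(rnorm(5 * p), 5)
    fit <- fit_pls(X, y, a)
    oracle <- simpls_oracle(X, y, a)
    expect_lt(max(abs(predict(fit, Xnew) - oracle$predict(Xnew))), 1e-6)
  }
})

test_that("constant variables do not change the fit", {
  set.seed(4)
  X <- matrix(rnorm(80), 20, 4)
  y <- X %*% rnorm(4) + rnorm(20, sd = 0.2)
  Xa <- cbind(X, 3, 7)   # two constant columns
  f1 <- fit_pls(X, y, 3)
  f2 <- fit_pls(Xa, y, 3)
  expect_lt(max(abs(f2$coefficients[5:6])), 1e-12)
  expect_lt(max(abs(f1$coefficients - f2$coefficients[1:4])), 1e-8)
})

test_that("cross-validation selects parsimonious, accurate models", {
  # noiseless single-component data: 1 LV explains everything
  set.seed(5)
  t <- rnorm(40)
  X <- outer(t, rnorm(10))
  cv <- cross_validate_pls(X, t, max_lv = 5, n_folds = 5, seed = 1)
  expect_lt(cv$rmsecv[1], 1e-6)
  expect_equal(cv$n_lv, 1L)

  # pure-noise response: the chosen LV count stays small
  chosen <- vapply(1:20, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 15), 40)
    y <- rnorm(40)
    cross_validate_pls(X, y, max_lv = 8, n_folds = 5, seed = seed)$n_lv
  }, integer(1))
  expect_lte(median(chosen), 2)

  expect_error(cross_validate_pls(X, t, 5, n_folds = 25), "at least 2")

  # blocked folds are deterministic regardless of seed
  c1 <- cross_validate_pls(X, t, 3, 4, seed = 1, fold_type = "blocked")
  c2 <- cross_validate_pls(X, t, 3, 4, seed = 2, fold_type = "blocked")
  expect_identical(c1$rmsecv, c2$rmsecv)
})

test_that("model serialization round-trips predictions", {
  set.seed(6)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  fit <- fit_pls(X, y, 2, variable_subset = c(3L, 5L, 8L, 9L))
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
  expect_identical(back$variable_subset, fit$variable_subset)
})
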