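# Independent oracles used to verify the implementation by a second route.

# Dense least-squares Savitzky-Golay oracle: for each interior point fit a
# polynomial of the given order to the surrounding window in wavenumber
# coordinates and read the derivative off the coefficients.
sg_oracle <- function(row, grid, window, polyorder, deriv) {
  p <- length(row)
  half <- (window - 1L) %/% 2L
  out <- rep(NA_real_, p)
  for (i in (half + 1L):(p - half)) {
    idx <- (i - half):(i + half)
    x <- grid[idx] - grid[i]
    fit <- stats::lm.fit(outer(x, 0:polyorder, `^`), row[idx])
    out[i] <- fit$coefficients[deriv + 1L] * factorial(deriv)
  }
  out
}

# SIMPLS (de Jong 1993) for univariate y -- an algorithm independent of the
# package's NIPALS route; returns the affine predictor.
simpls_oracle <- function(X, y, a) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  X0 <- sweep(X, 2L, x_mean)
  s <- crossprod(X0, y - y_mean)
  R <- matrix(0, ncol(X), a)
  P <- matrix(0, ncol(X), a)
  q <- numeric(a)
  V <- matrix(0, ncol(X), a)
  for (k in seq_len(a)) {
    r <- s
    t <- X0 %*% r
    t <- t - mean(t)
    normt <- sqrt(sum(t^2))
    r <- r / normt
    t <- t / normt
    pv <- crossprod(X0, t)
    q[k] <- sum((y - y_mean) * t)
    v <- pv
    if (k > 1L) {
      Vk <- V[, seq_len(k - 1L), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, pv)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, k] <- r; P[, k] <- pv; V[, k] <- v
  }
  beta <- R %*% q
  list(
    beta = beta[, 1L],
    intercept = y_mean - sum(x_mean * beta[, 1L]),
    predict = function(newX) {
      y_mean - sum(x_mean * beta[, 1L]) + (as.matrix(newX) %*% beta)[, 1L]
    }
  )
}

# Exhaustive per-step Kennard-Stone oracle for small n: recompute each
# argmax by brute force over all remaining candidates.
ks_oracle <- function(X, n_cal) {
  d <- as.matrix(stats::dist(X))
  n <- nrow(d)
  pairs <- which(d == max(d), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  sel <- as.integer(pairs[1L, ])
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    mind <- vapply(rest, function(i) min(d[i, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}

# Exhaustive best subset of a fixed size by residual sum of squares.
best_subset_oracle <- function(X, y, size) {
  combos <- utils::combn(ncol(X), size)
  rss <- apply(combos, 2L, function(idx) {
    f <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    sum(f$residuals^2)
  })
  sort(combos[, which.min(rss)])
}

# Closed-form mean of a normal truncated to [lo, hi].
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# Small fully-specified dataset for fast model tests: one analyte band on a
# short grid, optionally noiseless.
tiny_sim <- function(n = 30, p = 120, seed = 1, noiseless = FALSE, ...) {
  grid <- make_grid(10000, 4000, p)
  args <- list(
    n_samples = n, grid = grid,
    analyte_bands = list(c(7000, 120, 20)),
    interferent_bands = list(c(4600, 200, 0.25)),
    seed = seed
  )
  if (noiseless) {
    args[c("noise_sd", "scatter_sd", "baseline_offset_sd",
           "baseline_slope_sd", "reference_error_sd",
           "interferent_level_sd", "background_level_sd",
           "background_shift_sd")] <- 0
  }
  extra <- list(...)
  args[names(extra)] <- extra   # explicit overrides win
  simulate_serum_spectra(do.call(generator_config, args))
}
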