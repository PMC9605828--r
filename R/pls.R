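#' Fit a univariate partial least squares model (NIPALS)
#'
#' Sequential NIPALS extraction on mean-centred data (no variance scaling,
#' the convention for absorbance spectra). For a univariate response each
#' component needs no inner iteration: the weight vector is the covariance
#' direction `X'y`, scores are `X w`, and both `X` and `y` are deflated by
#' the extracted component. The fitted model is an affine predictor
#' `y_mean + (x - x_mean) . b` with `b = W (P'W)^{-1} q`.
#'
#' @param X Numeric matrix (samples x variables), all finite.
#' @param y Numeric response vector (mg/ml), non-constant.
#' @param n_lv Number of latent variables,
#'   `1 <= n_lv <= min(n_samples - 1, n_variables)`.
#' @param variable_subset Optional integer indices mapping the columns of
#'   `X` into a parent grid (bookkeeping for wavelength selection).
#' @return Object of class `pls_model`: `n_lv`, `x_mean`, `y_mean`,
#'   `weights`, `loadings`, `q` (per-component y loadings),
#'   `coefficients`, `intercept`, `scores`, `fitted`, `variable_subset`.
#' @export
fit_pls <- function(X, y, n_lv, variable_subset = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("y has zero variance", call. = FALSE)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, p)) {
    stop("need 1 <= n_lv <= min(n_samples - 1, n_variables)", call. = FALSE)
  }
  if (is.null(variable_subset)) variable_subset <- seq_len(p)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)[, 1L]
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break   # X residual carries no covariance with y left
    w <- w / wn
    t <- (Xc %*% w)[, 1L]
    tt <- sum(t^2)
    if (tt < 1e-28) break
    pv <- crossprod(Xc, t)[, 1L] / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) stop("no extractable PLS component (X'y is zero)",
                         call. = FALSE)
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]

  beta <- W %*% solve(crossprod(P, W), q)
  beta <- beta[, 1L]
  intercept <- y_mean - sum(x_mean * beta)
  fitted <- intercept + (X %*% beta)[, 1L]

  structure(
    list(n_lv = a_used, x_mean = x_mean, y_mean = y_mean,
         weights = W, loadings = P, q = q, coefficients = beta,
         intercept = intercept, scores = Tm, fitted = fitted,
         variable_subset = as.integer(variable_subset)),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d latent variable(s), %d variable(s)>\n",
              x$n_lv, length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A [fit_pls()] model.
#' @param newdata Numeric matrix whose columns match the variables the model
#'   was fitted on.
#' @param ... Unused.
#' @return Numeric vector of predictions (mg/ml).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients), call. = FALSE)
  }
  object$intercept + (newdata %*% object$coefficients)[, 1L]
}

#' Cross-validate the PLS latent-variable count
#'
#' Splits samples into folds (seeded-random by default, or contiguous
#' blocks), refits with 1..`max_lv` components on each training fold, pools
#' the out-of-fold residuals, and reports RMSECV per component count. The
#' chosen count is the global RMSECV minimum, ties resolved toward the
#' smaller (more parsimonious) model.
#'
#' @param X Numeric matrix (samples x variables).
#' @param y Numeric response.
#' @param max_lv Largest component count to evaluate (reduced if a training
#'   fold cannot support it).
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the random fold assignment.
#' @param fold_type `"random"` (seeded) or `"blocked"` (contiguous).
#' @return List of class `cv_curve`: `rmsecv` (one value per LV), `n_lv`
#'   (chosen), `max_lv`, `folds` (assignment vector), `fold_type`.
#' @export
cross_validate_pls <- function(X, y, max_lv = 10L, n_folds = 10L,
                               seed = 1L, fold_type = c("random", "blocked")) {
  fold_type <- match.arg(fold_type)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (n_folds > n %/% 2L) stop("each fold needs at least 2 samples",
                               call. = FALSE)
  folds <- rep(seq_len(n_folds), length.out = n)
  if (fold_type == "random") {
    set.seed(seed)
    folds <- sample(folds)
  } else {
    folds <- sort(folds)
  }
  feasible <- min(as.integer(max_lv), n - max(table(folds)) - 1L, ncol(X))
  if (feasible < 1L) stop("max_lv infeasible in every training fold",
                          call. = FALSE)

  press <- matrix(NA_real_, nrow = n, ncol = feasible)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fit <- fit_pls(X[tr, , drop = FALSE], y[tr], feasible)
    # reconstruct per-LV predictions from the sequential decomposition
    Xte <- sweep(X[!tr, , drop = FALSE], 2L, fit$x_mean)
    pred <- matrix(fit$y_mean, nrow = sum(!tr), ncol = fit$n_lv)
    for (a in seq_len(fit$n_lv)) {
      t_a <- (Xte %*% fit$weights[, a])[, 1L]
      add <- fit$q[a] * t_a
      pred[, a] <- (if (a == 1L) fit$y_mean else pred[, a - 1L]) + add
      Xte <- Xte - tcrossprod(t_a, fit$loadings[, a])
    }
    if (fit$n_lv < feasible) {
      pred <- cbind(pred, matrix(pred[, fit$n_lv], nrow = nrow(pred),
                                 ncol = feasible - fit$n_lv))
    }
    press[!tr, ] <- (pred - y[!tr])^2
  }
  rmsecv <- sqrt(colMeans(press))
  structure(
    list(rmsecv = rmsecv, n_lv = which.min(rmsecv),
         max_lv = feasible, folds = folds, fold_type = fold_type),
    class = "cv_curve"
  )
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve: chosen %d of %d LVs, RMSECV %.4g>\n",
              x$n_lv, x$max_lv, x$rmsecv[x$n_lv]))
  invisible(x)
}

#' Fit PLS with the latent-variable count chosen by cross-validation
#'
#' Convenience wrapper: [cross_validate_pls()] then [fit_pls()] at the
#' chosen count.
#'
#' @inheritParams cross_validate_pls
#' @param variable_subset Passed to [fit_pls()].
#' @return List with `model` (a `pls_model`) and `cv` (a `cv_curve`).
#' @export
fit_pls_cv <- function(X, y, max_lv = 10L, n_folds = 10L, seed = 1L,
                       fold_type = c("random", "blocked"),
                       variable_subset = NULL) {
  cv <- cross_validate_pls(X, y, max_lv, n_folds, seed, match.arg(fold_type))
  model <- fit_pls(X, y, cv$n_lv, variable_subset)
  list(model = model, cv = cv)
}

#' Serialize / restore a PLS model as plain JSON
#'
#' @param m A `pls_model`.
#' @param path Output path.
#' @return Invisibly, `path` (write) or the restored model (read).
#' @export
write_pls_model <- function(m, path) {
  stopifnot(inherits(m, "pls_model"))
  jsonlite::write_json(
    list(n_lv = m$n_lv, x_mean = m$x_mean, y_mean = m$y_mean,
         coefficients = m$coefficients, intercept = m$intercept,
         variable_subset = m$variable_subset),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(n_lv = as.integer(x$n_lv), x_mean = x$x_mean, y_mean = x$y_mean,
         weights = NULL, loadings = NULL, q = NULL,
         coefficients = x$coefficients, intercept = x$intercept,
         scores = NULL, fitted = NULL,
         variable_subset = as.integer(x$variable_subset)),
    class = "pls_model"
  )
}
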