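# OLS coefficient p-values via QR; returns NA for aliased columns
ols_pvalues <- function(X, y) {
  n <- nrow(X)
  X1 <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(X1)
  if (qr_x$rank < ncol(X1)) {
    return(list(p = rep(NA_real_, ncol(X)), coef = rep(NA_real_, ncol(X)),
                intercept = NA_real_, ok = FALSE))
  }
  cf <- qr.coef(qr_x, y)
  res <- y - X1 %*% cf
  df <- n - ncol(X1)
  if (df < 1L) {
    return(list(p = rep(NA_real_, ncol(X)), coef = cf[-1L],
                intercept = cf[1L], ok = FALSE))
  }
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  # a perfect fit (zero residual variance) makes every nonzero coefficient
  # infinitely significant rather than untestable
  tval <- ifelse(se > 0, cf / se, ifelse(cf != 0, Inf, 0))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(p = unname(p[-1L]), coef = unname(cf[-1L]),
       intercept = unname(cf[1L]), ok = TRUE)
}

#' Stepwise multiple linear regression over a wavenumber window
#'
#' Classical forward-entry / backward-removal stepwise ordinary least
#' squares on individual wavelength variables, restricted to a wavenumber
#' window. At each cycle the candidate with the smallest entry p-value is
#' introduced if that p-value, Bonferroni-adjusted for the number of
#' candidates scanned, falls below `p_enter` (without the adjustment the
#' minimum over hundreds of null candidates is almost surely significant and
#' stepwise selection fills up with noise wavelengths); then every retained
#' variable is re-checked and removed while its unadjusted p-value exceeds
#' `p_remove`. The procedure stops when no variable enters or leaves, or
#' when `max_vars` are retained.
#'
#' @param X Numeric matrix (samples x variables on the full grid).
#' @param y Numeric response (mg/ml).
#' @param grid Wavenumber grid matching the columns of `X`.
#' @param window Length-2 wavenumber range (cm\eqn{^{-1}}) delimiting the
#'   candidate variables; default is the full grid span.
#' @param p_enter Entry threshold (must be < `p_remove`).
#' @param p_remove Removal threshold.
#' @param max_vars Maximum number of retained variables.
#' @return Object of class `smlr_model`: `selected` (column indices),
#'   `coefficients`, `intercept`, `wavenumbers`, `n_lv = NULL`; predicts
#'   from full-width matrices via its `predict` method.
#' @export
smlr <- function(X, y, grid, window = range(grid),
                 p_enter = 0.05, p_remove = 0.10, max_vars = 10L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  assert_grid(grid)
  if (length(grid) != ncol(X)) {
    stop("grid length must match ncol(X)", call. = FALSE)
  }
  if (p_enter >= p_remove) stop("need p_enter < p_remove", call. = FALSE)
  cand <- which(grid >= min(window) & grid <= max(window))
  if (!length(cand)) stop("no variables inside the window", call. = FALSE)

  tss <- sum((y - mean(y))^2)
  selected <- integer(0)
  repeat {
    changed <- FALSE
    # forward entry -- skipped once the fit is numerically perfect, where
    # p-values on the remaining candidates are pure floating-point noise
    rss <- if (length(selected)) {
      sum(stats::lm.fit(cbind(1, X[, selected, drop = FALSE]),
                        y)$residuals^2)
    } else {
      tss
    }
    if (length(selected) < max_vars && rss > 1e-16 * tss) {
      pool <- setdiff(cand, selected)
      if (length(pool)) {
        entry_p <- vapply(pool, function(j) {
          f <- ols_pvalues(X[, c(selected, j), drop = FALSE], y)
          if (f$ok) f$p[length(f$p)] else NA_real_
        }, numeric(1))
        entry_p <- pmin(entry_p * length(pool), 1)   # Bonferroni over the scan
        if (any(!is.na(entry_p)) && min(entry_p, na.rm = TRUE) < p_enter) {
          j <- pool[which.min(entry_p)]
          selected <- c(selected, j)
          changed <- TRUE
        }
      }
    }
    # backward removal
    repeat {
      if (length(selected) < 2L) break
      f <- ols_pvalues(X[, selected, drop = FALSE], y)
      if (!f$ok || all(f$p <= p_remove, na.rm = TRUE)) break
      worst <- which.max(f$p)
      selected <- selected[-worst]
      changed <- TRUE
    }
    if (!changed) break
  }
  if (!length(selected)) {
    # null model: intercept only
    return(structure(
      list(selected = integer(0), coefficients = numeric(0),
           intercept = mean(y), wavenumbers = numeric(0), n_lv = NULL),
      class = "smlr_model"
    ))
  }
  fit <- ols_pvalues(X[, selected, drop = FALSE], y)
  structure(
    list(selected = selected, coefficients = fit$coef,
         intercept = fit$intercept, wavenumbers = grid[selected],
         n_lv = NULL),
    class = "smlr_model"
  )
}

#' @export
print.smlr_model <- function(x, ...) {
  cat(sprintf("<smlr_model: %d variable(s) selected%s>\n",
              length(x$selected),
              if (length(x$selected)) paste0(" at ",
                paste(sprintf("%.1f", x$wavenumbers), collapse = ", "),
                " cm-1") else ""))
  invisible(x)
}

#' Predict from a stepwise regression model
#'
#' @param object An [smlr()] model.
#' @param newdata Full-width spectral matrix (same columns as the training
#'   grid).
#' @param ... Unused.
#' @return Numeric vector of predictions (mg/ml).
#' @export
predict.smlr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!length(object$selected)) {
    return(rep(object$intercept, nrow(newdata)))
  }
  if (ncol(newdata) < max(object$selected)) {
    stop("newdata is narrower than the training grid", call. = FALSE)
  }
  object$intercept +
    (newdata[, object$selected, drop = FALSE] %*% object$coefficients)[, 1L]
}
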