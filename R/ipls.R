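#' Interval PLS wavelength-region selection
#'
#' Partitions the grid into `n_intervals` equal-width (in index space)
#' contiguous intervals, fits a cross-validated PLS model on each interval
#' and on the full spectrum, and selects the interval with the lowest
#' RMSECV. Intervals too narrow for the requested component count get a
#' reduced count with a message.
#'
#' @param X Numeric matrix (samples x variables).
#' @param y Numeric response (mg/ml).
#' @param grid Wavenumber grid matching the columns of `X`.
#' @param n_intervals Number of intervals (each must hold >= 2 variables);
#'   `n_intervals = 1` degenerates to a single full-spectrum interval.
#' @param max_lv Largest LV count offered to cross-validation.
#' @param n_folds,seed,fold_type Passed to [cross_validate_pls()].
#' @return Object of class `interval_model_set`:
#'   \describe{
#'     \item{intervals}{data.frame with `interval`, `first_index`,
#'       `last_index`, `wn_high`, `wn_low`, `n_vars`, `n_lv`, `rmsecv`}
#'     \item{models}{list of per-interval `pls_model`s (with
#'       `variable_subset` set)}
#'     \item{best}{index of the winning interval}
#'     \item{full_model, full_cv}{full-spectrum comparison fit}
#'   }
#' @export
ipls <- function(X, y, grid, n_intervals = 9L, max_lv = 10L, n_folds = 10L,
                 seed = 1L, fold_type = c("random", "blocked")) {
  fold_type <- match.arg(fold_type)
  X <- as.matrix(X)
  assert_grid(grid)
  p <- ncol(X)
  if (length(grid) != p) stop("grid length must match ncol(X)", call. = FALSE)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("need at least 1 interval", call. = FALSE)
  bounds <- round(seq(0L, p, length.out = n_intervals + 1L))
  sizes <- diff(bounds)
  if (any(sizes < 2L)) {
    stop("each interval must hold at least 2 variables", call. = FALSE)
  }

  models <- vector("list", n_intervals)
  rows <- vector("list", n_intervals)
  for (k in seq_len(n_intervals)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    lv_k <- min(max_lv, length(idx))
    if (lv_k < max_lv) {
      message(sprintf("interval %d holds %d variables; LVs capped at %d",
                      k, length(idx), lv_k))
    }
    # an interval carrying no covariance with y (e.g. constant columns on
    # clean data) cannot support a model; score it as unusable
    fit_k <- tryCatch({
      cv <- cross_validate_pls(X[, idx, drop = FALSE], y, lv_k, n_folds,
                               seed, fold_type)
      list(model = fit_pls(X[, idx, drop = FALSE], y, cv$n_lv,
                           variable_subset = idx),
           n_lv = cv$n_lv, rmsecv = cv$rmsecv[cv$n_lv])
    }, error = function(e) list(model = NULL, n_lv = NA_integer_,
                                rmsecv = Inf))
    models[[k]] <- fit_k$model
    rows[[k]] <- data.frame(
      interval = k, first_index = idx[1L], last_index = idx[length(idx)],
      wn_high = max(grid[idx]), wn_low = min(grid[idx]),
      n_vars = length(idx), n_lv = fit_k$n_lv, rmsecv = fit_k$rmsecv
    )
  }
  intervals <- do.call(rbind, rows)
  full <- fit_pls_cv(X, y, max_lv, n_folds, seed, fold_type)
  structure(
    list(intervals = intervals, models = models,
         best = which.min(intervals$rmsecv),
         full_model = full$model, full_cv = full$cv),
    class = "interval_model_set"
  )
}

#' @export
print.interval_model_set <- function(x, ...) {
  b <- x$intervals[x$best, ]
  cat(sprintf(
    "<interval_model_set: %d intervals; best #%d (%.2f-%.2f cm-1, RMSECV %.4g)>\n",
    nrow(x$intervals), x$best, b$wn_low, b$wn_high, b$rmsecv))
  invisible(x)
}
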