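#' Root-mean-square error of prediction
#'
#' `sqrt(mean((predicted - reference)^2))`; called RMSEC on the calibration
#' set, RMSEP on the validation set and RMSECV on pooled out-of-fold
#' cross-validation residuals.
#'
#' @param predicted,reference Numeric vectors of equal length (mg/ml).
#' @return RMSE in mg/ml.
#' @export
rmse <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference lengths differ", call. = FALSE)
  }
  if (length(predicted) < 1L) stop("need at least one value", call. = FALSE)
  sqrt(mean((predicted - reference)^2))
}

#' Correlation-type goodness coefficient
#'
#' `R = sqrt(max(0, 1 - SSE/SST))` with `SSE = sum((pred - ref)^2)` and
#' `SST = sum((ref - mean(ref))^2)`. For least-squares-calibrated
#' predictions this equals the absolute Pearson correlation between
#' predictions and reference values; for arbitrary predictions the two can
#' differ, and this explained-variance form is the canonical one here.
#'
#' @param predicted,reference Numeric vectors; `reference` must have nonzero
#'   variance.
#' @return R in [0, 1].
#' @export
r_coefficient <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference lengths differ", call. = FALSE)
  }
  sst <- sum((reference - mean(reference))^2)
  if (sst == 0) stop("reference values have zero variance", call. = FALSE)
  sse <- sum((predicted - reference)^2)
  sqrt(max(0, 1 - sse / sst))
}

#' Standard error of calibration / prediction
#'
#' Bias-corrected standard deviation of the residuals `d = predicted -
#' reference`: `sqrt(sum((d - mean(d))^2) / (n - 1))`. Called SEC on the
#' calibration set and SEP on the validation set.
#'
#' @param predicted,reference Numeric vectors of equal length, n >= 2.
#' @return Standard error in mg/ml.
#' @export
standard_error <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference lengths differ", call. = FALSE)
  }
  if (length(predicted) < 2L) stop("need at least 2 values", call. = FALSE)
  stats::sd(predicted - reference)
}

#' Residual predictive deviation
#'
#' `RPD = SD(reference) / SEP`: how much narrower the prediction error is
#' than the natural spread of the reference values. Values well above 2-3
#' indicate a usable calibration.
#'
#' @param reference Numeric vector of reference values.
#' @param sep Standard error of prediction (> 0).
#' @return Dimensionless ratio.
#' @export
rpd <- function(reference, sep) {
  if (sep <= 0) stop("sep must be > 0", call. = FALSE)
  stats::sd(reference) / sep
}

#' Mean prediction offset (bias)
#'
#' @param predicted,reference Numeric vectors of equal length.
#' @return `mean(predicted - reference)` in mg/ml.
#' @export
prediction_offset <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference lengths differ", call. = FALSE)
  }
  mean(predicted - reference)
}

#' Assemble the standard calibration report for one model
#'
#' Computes Rc/RMSEC/SEC on the calibration set, Rp/RMSEP/SEP/RPD on the
#' validation set, the validation offset, and carries the cross-validation
#' RMSECV when available. Pearson correlations are reported alongside the
#' canonical explained-variance R (they coincide for least-squares fits).
#'
#' @param model A fitted model with a `predict` method (`pls_model`,
#'   `smlr_model`, ...).
#' @param X_cal,y_cal Calibration predictors and reference values.
#' @param X_val,y_val Validation predictors and reference values (disjoint
#'   from the calibration set).
#' @param cv Optional `cv_curve` (for RMSECV).
#' @param label Model label for the comparison table.
#' @return One-row `data.frame` of class `model_report` with columns
#'   `label`, `n_lv`, `Rc`, `RMSEC`, `Rp`, `RMSEP`, `RMSECV`, `SEC`, `SEP`,
#'   `RPD`, `offset`, `Rc_pearson`, `Rp_pearson`, `n_cal`, `n_val`.
#' @export
build_report <- function(model, X_cal, y_cal, X_val, y_val, cv = NULL,
                         label = class(model)[1L]) {
  if (length(y_cal) < 1L || length(y_val) < 1L) {
    stop("calibration and validation sets must be non-empty", call. = FALSE)
  }
  pred_cal <- stats::predict(model, X_cal)
  pred_val <- stats::predict(model, X_val)
  sep <- standard_error(pred_val, y_val)
  out <- data.frame(
    label = label,
    n_lv = if (!is.null(model$n_lv)) model$n_lv else NA_integer_,
    Rc = r_coefficient(pred_cal, y_cal),
    RMSEC = rmse(pred_cal, y_cal),
    Rp = r_coefficient(pred_val, y_val),
    RMSEP = rmse(pred_val, y_val),
    RMSECV = if (!is.null(cv)) cv$rmsecv[cv$n_lv] else NA_real_,
    SEC = standard_error(pred_cal, y_cal),
    SEP = sep,
    RPD = if (sep > 0) rpd(y_val, sep) else Inf,
    offset = prediction_offset(pred_val, y_val),
    Rc_pearson = suppressWarnings(abs(stats::cor(pred_cal, y_cal))),
    Rp_pearson = suppressWarnings(abs(stats::cor(pred_val, y_val))),
    n_cal = length(y_cal),
    n_val = length(y_val),
    stringsAsFactors = FALSE
  )
  class(out) <- c("model_report", class(out))
  out
}
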