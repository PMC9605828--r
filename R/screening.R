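#' Mahalanobis distances of spectra in principal-component space
#'
#' The raw spectral covariance is singular whenever variables outnumber
#' samples, so distances are computed in a PCA score space: spectra are
#' centred, projected onto the leading `n_components` principal components,
#' and the Mahalanobis distance of each sample's score vector from the score
#' mean is returned. Distances are invariant to any common affine transform
#' of the spectra that preserves the retained score space.
#'
#' @param s A [spectrum_set()].
#' @param n_components Number of PCA components; default retains 99% of the
#'   spectral variance.
#' @return Numeric vector of distances (>= 0), one per sample, in the
#'   spectrum set's sample order.
#' @export
mahalanobis_distances <- function(s, n_components = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  n <- nrow(s$absorbance)
  pc <- stats::prcomp(s$absorbance, center = TRUE, scale. = FALSE)
  if (is.null(n_components)) {
    v <- pc$sdev^2
    n_components <- which(cumsum(v) / sum(v) >= 0.99)[1L]
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components >= n) {
    stop("need 1 <= n_components < n_samples", call. = FALSE)
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  cov_s <- stats::cov(scores)
  ev <- eigen(cov_s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) {
    stop("singular score covariance; reduce n_components", call. = FALSE)
  }
  sqrt(stats::mahalanobis(scores, colMeans(scores), cov_s))
}

# Dixon's Q critical values, two-tailed (Rorabacher 1991), n = 3..30.
# Variant switches with n: r10 (3-7), r11 (8-10), r21 (11-13), r22 (14-30).
dixon_critical <- function(n, alpha) {
  q05 <- c(0.970, 0.829, 0.710, 0.625, 0.568,          # r10, n 3-7
           0.615, 0.570, 0.534,                        # r11, n 8-10
           0.625, 0.592, 0.565,                        # r21, n 11-13
           0.590, 0.568, 0.548, 0.531, 0.516, 0.503,   # r22, n 14-19
           0.491, 0.480, 0.470, 0.461, 0.452, 0.445,   # n 20-25
           0.438, 0.432, 0.426, 0.419)                 # n 26-29... n30 below
  q05 <- c(q05, 0.414)
  q01 <- c(0.994, 0.926, 0.821, 0.740, 0.680,
           0.725, 0.677, 0.639,
           0.713, 0.675, 0.649,
           0.674, 0.647, 0.624, 0.605, 0.589, 0.575,
           0.562, 0.551, 0.541, 0.532, 0.524, 0.516,
           0.508, 0.501, 0.495, 0.489, 0.483)
  tab <- switch(as.character(alpha), "0.05" = q05, "0.01" = q01,
                stop("alpha must be 0.05 or 0.01 (tabulated levels)",
                     call. = FALSE))
  tab[n - 2L]
}

#' Dixon's Q test for a single outlier
#'
#' Computes the gap/range ratio for the more extreme of the two suspects
#' (minimum and maximum) using the standard sample-size-dependent variant
#' (r10 for n of 3-7, r11 for 8-10, r21 for 11-13, r22 for 14-30) and
#' compares it with the tabulated two-tailed critical value.
#'
#' @param values Numeric vector, 3 <= length <= 30.
#' @param alpha Significance level, 0.05 (default) or 0.01.
#' @return List: `flag` (logical), `Q` (statistic), `suspect` (index into
#'   `values` of the tested extreme), `critical`.
#' @export
dixon_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L || n > 30L) {
    stop("Dixon's test is tabulated for 3 <= n <= 30", call. = FALSE)
  }
  x <- sort(values)
  rng <- x[n] - x[1L]
  if (rng == 0) {
    return(list(flag = FALSE, Q = 0, suspect = which.max(values),
                critical = dixon_critical(n, alpha)))
  }
  # gap and denominator indices per variant
  if (n <= 7L)      { j <- 2L; k <- n      }   # r10: gap 1, full range
  else if (n <= 10L){ j <- 2L; k <- n - 1L }   # r11
  else if (n <= 13L){ j <- 3L; k <- n - 1L }   # r21
  else              { j <- 3L; k <- n - 2L }   # r22
  q_low  <- (x[j] - x[1L]) / (x[k] - x[1L])
  q_high <- (x[n] - x[n - j + 1L]) / (x[n] - x[n - k + 1L])
  if (q_high >= q_low) {
    q <- q_high; suspect <- which.max(values)
  } else {
    q <- q_low; suspect <- which.min(values)
  }
  crit <- dixon_critical(n, alpha)
  list(flag = q > crit, Q = q, suspect = suspect, critical = crit)
}

#' Chauvenet's criterion
#'
#' Flags a value when the expected number of equally extreme draws from the
#' fitted normal, `n * P(|Z| > |x - mean| / sd)`, falls below one half.
#'
#' @param values Numeric vector, length >= 4.
#' @return List: `flag` (logical vector), `expected_count` (numeric vector
#'   of `n * P`), single pass (no re-estimation after removal).
#' @export
chauvenet <- function(values) {
  n <- length(values)
  if (n < 4L) stop("Chauvenet's criterion needs n >= 4", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) {
    message("zero spread; Chauvenet flags nothing")
    return(list(flag = rep(FALSE, n), expected_count = rep(n, n)))
  }
  z <- abs(values - mean(values)) / s
  expected <- n * 2 * stats::pnorm(z, lower.tail = FALSE)
  list(flag = expected < 0.5, expected_count = expected)
}

#' Screen a spectrum set for outlying spectra
#'
#' Ranks samples by PCA-space Mahalanobis distance and tests the ranked
#' distances with Dixon's Q test and Chauvenet's criterion; a sample is
#' excluded when either test flags it. Dixon's test is only tabulated up to
#' n = 30, so for larger sets it is applied to the 30 largest distances
#' (only extremes can be flagged, so smaller distances are irrelevant).
#'
#' @param s A [spectrum_set()].
#' @param n_components Passed to [mahalanobis_distances()].
#' @param alpha Dixon significance level.
#' @return List of class `outlier_report`: `distance` (per sample, input
#'   order), `ranked_ids` (ids by descending distance), `dixon`
#'   (test result on the extreme distance), `chauvenet_flag`,
#'   `chauvenet_expected`, `excluded` (character vector of sample ids).
#' @export
screen_outliers <- function(s, n_components = NULL, alpha = 0.05) {
  stopifnot(inherits(s, "spectrum_set"))
  d <- mahalanobis_distances(s, n_components)
  ids <- s$sample_ids
  n <- length(d)

  # Dixon on the (at most) 30 largest distances
  ord <- order(d, decreasing = TRUE)
  top <- ord[seq_len(min(n, 30L))]
  dix <- dixon_test(d[top], alpha = alpha)
  dixon_excluded <- if (dix$flag && d[top[dix$suspect]] == max(d)) {
    ids[top[dix$suspect]]
  } else {
    character(0)
  }

  ch <- chauvenet(d)
  excluded <- union(dixon_excluded, ids[ch$flag])

  structure(
    list(distance = d, ranked_ids = ids[ord], dixon = dix,
         chauvenet_flag = ch$flag, chauvenet_expected = ch$expected_count,
         excluded = excluded),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report: %d samples, %d excluded%s>\n",
              length(x$distance), length(x$excluded),
              if (length(x$excluded)) paste0(" (",
                paste(x$excluded, collapse = ", "), ")") else ""))
  invisible(x)
}
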