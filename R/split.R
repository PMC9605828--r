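#' Kennard-Stone calibration/validation partition
#'
#' Deterministic max-min Euclidean distance selection: the first two
#' calibration samples are the most distant pair; each further selection
#' maximizes its minimum distance to the already-selected set. Ties are
#' broken by the lower sample index. The unselected samples form the
#' validation set.
#'
#' @param s A [spectrum_set()] (distances are computed on its rows).
#' @param n_cal Number of calibration samples, 2 <= n_cal < n_samples.
#' @return List of class `split_result`: `calibration` and `validation`
#'   (character vectors of sample ids), `calibration_idx`,
#'   `validation_idx` (integer indices), `method = "kennard_stone"`.
#' @export
kennard_stone <- function(s, n_cal) {
  stopifnot(inherits(s, "spectrum_set"))
  n <- nrow(s$absorbance)
  n_cal <- as.integer(n_cal)
  if (n_cal < 2L || n_cal >= n) {
    stop("need 2 <= n_cal < n_samples", call. = FALSE)
  }
  d <- as.matrix(stats::dist(s$absorbance))

  # seed pair: maximum distance, tie to the lexicographically lowest (i, j)
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
  sel <- as.integer(best[1L, ])

  min_dist <- unname(pmin(d[, sel[1L]], d[, sel[2L]]))
  while (length(sel) < n_cal) {
    min_dist[sel] <- -Inf
    nxt <- which.max(min_dist)   # which.max takes the first (lowest index) tie
    sel <- c(sel, nxt)
    min_dist <- pmin(min_dist, unname(d[, nxt]))
  }
  val <- setdiff(seq_len(n), sel)
  structure(
    list(calibration = s$sample_ids[sel], validation = s$sample_ids[val],
         calibration_idx = sel, validation_idx = val,
         method = "kennard_stone"),
    class = "split_result"
  )
}

#' Seeded random calibration/validation partition
#'
#' @param s A [spectrum_set()].
#' @param n_cal Number of calibration samples.
#' @param seed Integer seed.
#' @return A `split_result` (same shape as [kennard_stone()]).
#' @export
random_split <- function(s, n_cal, seed = 1L) {
  stopifnot(inherits(s, "spectrum_set"))
  n <- nrow(s$absorbance)
  n_cal <- as.integer(n_cal)
  if (n_cal < 2L || n_cal >= n) {
    stop("need 2 <= n_cal < n_samples", call. = FALSE)
  }
  set.seed(seed)
  sel <- sort(sample.int(n, n_cal))
  val <- setdiff(seq_len(n), sel)
  structure(
    list(calibration = s$sample_ids[sel], validation = s$sample_ids[val],
         calibration_idx = sel, validation_idx = val, method = "random"),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result (%s): %d calibration / %d validation>\n",
              x$method, length(x$calibration), length(x$validation)))
  invisible(x)
}

#' Cohort summary statistics
#'
#' The statistics reported per cohort in calibration studies: n, max, min,
#' mean, sample SD (n - 1 denominator) and coefficient of variation
#' CV = SD / mean.
#'
#' @param concs Numeric vector of concentrations (mg/ml), length >= 2.
#' @return List of class `cohort_stats` with fields `n`, `max`, `min`,
#'   `mean`, `sd`, `cv`.
#' @export
cohort_stats <- function(concs) {
  if (length(concs) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(concs)
  s <- stats::sd(concs)
  cv <- if (s == 0) 0 else {
    if (m <= 0) stop("cv undefined for non-positive mean", call. = FALSE)
    s / m
  }
  structure(list(n = length(concs), max = max(concs), min = min(concs),
                 mean = m, sd = s, cv = cv),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf(
    "<cohort_stats: n=%d, range [%.6f, %.6f], mean %.6f +/- %.6f, CV %.4f>\n",
    x$n, x$min, x$max, x$mean, x$sd, x$cv))
  invisible(x)
}

#' Compare calibration and validation concentration means
#'
#' Two-sided Welch two-sample t-test; a p-value above the chosen level
#' supports using the partition for calibration (no systematic difference
#' between the groups' means).
#'
#' @param a,b Numeric vectors, each length >= 2.
#' @return The p-value.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    stop("degenerate zero-variance groups with different means",
         call. = FALSE)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}
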