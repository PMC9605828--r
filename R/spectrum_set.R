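#' Construct a wavenumber grid
#'
#' Builds an evenly spaced wavenumber grid (cm\eqn{^{-1}}) with both endpoints
#' included. NIR instruments conventionally report spectra on a descending
#' grid (high to low wavenumber); descending order is produced whenever
#' `start_cm1 > end_cm1`.
#'
#' @param start_cm1 First wavenumber (cm\eqn{^{-1}}).
#' @param end_cm1 Last wavenumber (cm\eqn{^{-1}}); must differ from
#'   `start_cm1`.
#' @param n_points Number of grid points (>= 2). The default serum
#'   configuration uses 1557 points from 10000 to 4000 cm\eqn{^{-1}}.
#' @return Numeric vector of length `n_points`, strictly monotone.
#' @examples
#' g <- make_grid(10000, 4000, 1557)
#' head(g)
#' @export
make_grid <- function(start_cm1, end_cm1, n_points) {
  if (!is.finite(start_cm1) || !is.finite(end_cm1)) {
    stop("grid bounds must be finite", call. = FALSE)
  }
  if (start_cm1 == end_cm1) stop("grid bounds must differ", call. = FALSE)
  if (n_points < 2) stop("a grid needs at least 2 points", call. = FALSE)
  seq(start_cm1, end_cm1, length.out = n_points)
}

grid_spacing <- function(grid) {
  d <- diff(grid)
  if (length(unique(round(d, 9))) > 1L) {
    stop("grid is not evenly spaced", call. = FALSE)
  }
  d[1L]
}

assert_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L || anyNA(grid) ||
      any(!is.finite(grid))) {
    stop("grid must be a finite numeric vector of length >= 2", call. = FALSE)
  }
  d <- diff(grid)
  if (!(all(d > 0) || all(d < 0))) {
    stop("grid must be strictly monotone", call. = FALSE)
  }
  invisible(grid)
}

#' Bundle absorbance spectra with their wavenumber grid
#'
#' A `spectrum_set` is the package's container for a block of absorbance
#' spectra sharing one wavenumber grid: a numeric matrix with one row per
#' sample and one column per grid point, plus unique sample identifiers.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param grid Wavenumber grid from [make_grid()] (strictly monotone).
#' @param absorbance Numeric matrix, `length(sample_ids)` rows by
#'   `length(grid)` columns, all values finite.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(sample_ids, grid, absorbance) {
  assert_grid(grid)
  sample_ids <- as.character(sample_ids)
  absorbance <- as.matrix(absorbance)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(absorbance) != length(sample_ids)) {
    stop("absorbance must have one row per sample id", call. = FALSE)
  }
  if (ncol(absorbance) != length(grid)) {
    stop("absorbance must have one column per grid point", call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    stop("absorbance values must all be finite", call. = FALSE)
  }
  dimnames(absorbance) <- NULL
  structure(
    list(sample_ids = sample_ids, grid = as.numeric(grid),
         absorbance = absorbance),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set: %d samples x %d variables, %.2f to %.2f cm-1>\n",
              length(x$sample_ids), length(x$grid),
              x$grid[1L], x$grid[length(x$grid)]))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$absorbance)

# subset rows (samples) of a spectrum_set
subset_samples <- function(s, idx) {
  spectrum_set(s$sample_ids[idx], s$grid, s$absorbance[idx, , drop = FALSE])
}

#' Binary feature-retention vector
#'
#' Wavelength selection by simulated annealing operates on a binary vector
#' `V` over the grid variables: 1 retains a variable, 0 removes it; `m`
#' denotes the number of retained variables.
#'
#' @param v Vector of 0/1 (or logical) values, one per spectral variable;
#'   at least one variable must be retained.
#' @return Integer 0/1 vector of class `retention_vector` with attribute
#'   `m = sum(v)`.
#' @export
retention_vector <- function(v) {
  v <- as.integer(v)
  if (length(v) < 1L || anyNA(v) || !all(v %in% c(0L, 1L))) {
    stop("retention vector must be binary with no missing values",
         call. = FALSE)
  }
  m <- sum(v)
  if (m < 1L) stop("at least one variable must be retained", call. = FALSE)
  structure(v, m = m, class = "retention_vector")
}

#' @export
print.retention_vector <- function(x, ...) {
  cat(sprintf("<retention_vector: %d of %d variables retained>\n",
              attr(x, "m"), length(x)))
  invisible(x)
}
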