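#' Read a spectrum set from CSV
#'
#' Expects the package's CSV dialect: first column `sample_id`, remaining
#' column headers numeric wavenumbers in cm\eqn{^{-1}}, one row per sample
#' (RFC 4180, UTF-8, "." decimal). Descending wavenumber order is canonical;
#' an ascending grid is accepted and reversed with a message.
#'
#' @param path Path to a CSV file.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("spectra file needs sample_id plus at least one wavenumber column",
                          call. = FALSE)
  if (names(dt)[1L] != "sample_id") {
    stop("first column must be 'sample_id', found '", names(dt)[1L], "'",
         call. = FALSE)
  }
  grid <- suppressWarnings(as.numeric(names(dt)[-1L]))
  if (anyNA(grid)) {
    stop("non-numeric wavenumber header: ",
         paste(utils::head(names(dt)[-1L][is.na(grid)], 3L), collapse = ", "),
         call. = FALSE)
  }
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(dt[, -1L])
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    stop("non-numeric or non-finite absorbance cells in ", path,
         call. = FALSE)
  }
  if (length(grid) > 1L && diff(grid)[1L] > 0) {
    message("ascending wavenumber grid in ", path,
            "; reversing to canonical descending order")
    grid <- rev(grid)
    mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  }
  spectrum_set(ids, grid, mat)
}

#' Write a spectrum set to CSV
#'
#' Inverse of [read_spectra()]: header `sample_id` followed by the
#' wavenumbers, one row per sample, full floating-point precision so that a
#' write/read round trip is an identity to within float round-off.
#'
#' @param s A [spectrum_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectrum_set"))
  dt <- data.table::as.data.table(s$absorbance)
  data.table::setnames(dt, format(s$grid, digits = 15, trim = TRUE,
                                  scientific = FALSE))
  dt <- cbind(data.table::data.table(sample_id = s$sample_ids), dt)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a reference-concentration table from CSV
#'
#' Two columns: `sample_id` and `concentration` (mg/ml, finite and
#' positive).
#'
#' @param path Path to a CSV file.
#' @return Named numeric vector of concentrations, names = sample ids.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = 1L))
  if (ncol(dt) != 2L) {
    stop("reference file must have exactly two columns (sample_id, concentration)",
         call. = FALSE)
  }
  ids <- dt[[1L]]
  conc <- suppressWarnings(as.numeric(dt[[2L]]))
  if (anyNA(conc) || any(!is.finite(conc))) {
    stop("non-numeric concentration values in ", path, call. = FALSE)
  }
  if (any(conc <= 0)) {
    stop("concentrations must be positive; offending ids: ",
         paste(ids[conc <= 0], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(conc, ids)
}

#' Write a reference-concentration table to CSV
#'
#' @param reference Named numeric vector (names = sample ids, values mg/ml).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference <- function(reference, path) {
  data.table::fwrite(
    data.table::data.table(sample_id = names(reference),
                           concentration = as.numeric(reference)),
    path
  )
  invisible(path)
}

#' Align a reference table against a spectrum set
#'
#' Returns the concentrations in the spectrum set's sample order; every
#' sample must have a reference value.
#'
#' @param s A [spectrum_set()].
#' @param reference Named numeric vector as returned by [read_reference()].
#' @return Numeric vector of concentrations aligned to `s$sample_ids`.
#' @export
join_reference <- function(s, reference) {
  stopifnot(inherits(s, "spectrum_set"))
  missing <- setdiff(s$sample_ids, names(reference))
  if (length(missing)) {
    stop("no reference concentration for sample id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unname(reference[s$sample_ids])
}
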