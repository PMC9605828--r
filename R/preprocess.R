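#' Specify a spectral preprocessing treatment
#'
#' The five treatments compared in the calibration study are raw spectra and
#' first/second derivatives smoothed with either a Savitzky-Golay or a
#' Norris gap-segment filter. Derivatives are expressed per cm\eqn{^{-1}}
#' (grid-spacing aware), not per index, so results do not depend on how
#' densely the grid is sampled.
#'
#' @param derivative_order 0 (raw), 1 or 2.
#' @param smoother One of `"none"`, `"savitzky_golay"`, `"norris"`. A
#'   derivative order > 0 requires a smoother.
#' @param sg_window Savitzky-Golay window length (odd).
#' @param sg_polyorder Savitzky-Golay polynomial order (< window).
#' @param norris_segment Norris segment (moving-average) length (odd).
#' @param norris_gap Norris gap length (>= 1).
#' @return A list of class `preprocess_spec`.
#' @seealso [apply_preprocess()], [preprocess_labels()]
#' @export
preprocess_spec <- function(derivative_order = 0L,
                            smoother = c("none", "savitzky_golay", "norris"),
                            sg_window = 11L, sg_polyorder = 3L,
                            norris_segment = 5L, norris_gap = 5L) {
  smoother <- match.arg(smoother)
  derivative_order <- as.integer(derivative_order)
  if (!derivative_order %in% 0:2) {
    stop("derivative_order must be 0, 1 or 2", call. = FALSE)
  }
  if (derivative_order > 0L && smoother == "none") {
    stop("derivatives require a smoother (savitzky_golay or norris)",
         call. = FALSE)
  }
  if (sg_window %% 2L == 0L) stop("sg_window must be odd", call. = FALSE)
  if (sg_polyorder >= sg_window) {
    stop("sg_polyorder must be smaller than sg_window", call. = FALSE)
  }
  if (derivative_order > sg_polyorder && smoother == "savitzky_golay") {
    stop("derivative_order must not exceed sg_polyorder", call. = FALSE)
  }
  if (norris_segment %% 2L == 0L) {
    stop("norris_segment must be odd", call. = FALSE)
  }
  if (norris_gap < 1L) stop("norris_gap must be >= 1", call. = FALSE)
  structure(
    list(derivative_order = derivative_order, smoother = smoother,
         sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder),
         norris_segment = as.integer(norris_segment),
         norris_gap = as.integer(norris_gap)),
    class = "preprocess_spec"
  )
}

#' The five standard treatments by their comparison-table labels
#'
#' @param sg_window,sg_polyorder,norris_segment,norris_gap Filter parameters
#'   shared by all treatments.
#' @return Named list of [preprocess_spec()] objects with names
#'   `raw`, `1d-sg`, `1d-no`, `2d-sg`, `2d-no`.
#' @export
preprocess_labels <- function(sg_window = 11L, sg_polyorder = 3L,
                              norris_segment = 5L, norris_gap = 5L) {
  list(
    "raw"   = preprocess_spec(0L, "none"),
    "1d-sg" = preprocess_spec(1L, "savitzky_golay", sg_window, sg_polyorder),
    "1d-no" = preprocess_spec(1L, "norris",
                              norris_segment = norris_segment,
                              norris_gap = norris_gap),
    "2d-sg" = preprocess_spec(2L, "savitzky_golay", sg_window, sg_polyorder),
    "2d-no" = preprocess_spec(2L, "norris",
                              norris_segment = norris_segment,
                              norris_gap = norris_gap)
  )
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Per-row local least-squares polynomial filtering. The derivative is
#' scaled by the (signed) grid spacing so the output is per cm\eqn{^{-1}};
#' edge points come from the polynomial fits of the first and last windows.
#'
#' @param s A [spectrum_set()] on an evenly spaced grid.
#' @param window Window length (odd, <= number of variables).
#' @param polyorder Polynomial order (< window).
#' @param deriv Derivative order (<= polyorder).
#' @return A [spectrum_set()] of the same shape.
#' @export
savitzky_golay <- function(s, window = 11L, polyorder = 3L, deriv = 0L) {
  stopifnot(inherits(s, "spectrum_set"))
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (deriv > polyorder) stop("deriv must be <= polyorder", call. = FALSE)
  p <- length(s$grid)
  if (window > p) {
    stop("window (", window, ") exceeds the number of variables (", p, ")",
         call. = FALSE)
  }
  h <- grid_spacing(s$grid)
  out <- t(apply(s$absorbance, 1L, function(row) {
    signal::sgolayfilt(row, p = polyorder, n = window, m = deriv, ts = h)
  }))
  spectrum_set(s$sample_ids, s$grid, out)
}

#' Norris gap-segment derivative
#'
#' The classic chemometric gap derivative: each spectrum is first smoothed
#' by a centred moving average of `segment` points, then differenced across
#' `gap` points. The first derivative is the forward difference quotient
#' `(s[i+gap] - s[i]) / (nu[i+gap] - nu[i])`; the second derivative is the
#' central second difference across two gaps divided by the squared gap
#' interval, so affine baselines are annihilated exactly. Edge points whose
#' stencil leaves the grid are filled with the nearest valid value.
#'
#' @param s A [spectrum_set()] on an evenly spaced grid.
#' @param segment Segment (moving-average) length, odd, >= 1.
#' @param gap Gap length in grid points, >= 1.
#' @param deriv 1 or 2.
#' @return A [spectrum_set()] of the same shape, in absorbance per
#'   cm\eqn{^{-1}} (first) or per cm\eqn{^{-2}} (second derivative).
#' @export
norris_derivative <- function(s, segment = 5L, gap = 5L, deriv = 1L) {
  stopifnot(inherits(s, "spectrum_set"))
  if (!deriv %in% 1:2) stop("deriv must be 1 or 2", call. = FALSE)
  if (segment %% 2L == 0L || segment < 1L) {
    stop("segment must be odd and >= 1", call. = FALSE)
  }
  if (gap < 1L) stop("gap must be >= 1", call. = FALSE)
  p <- length(s$grid)
  half <- (segment - 1L) %/% 2L
  if (segment + 2L * gap > p) {
    stop("Norris stencil wider than the number of variables", call. = FALSE)
  }
  h <- grid_spacing(s$grid)

  smooth_row <- function(row) {
    # centred moving average; edges keep a shrunken one-sided window
    sm <- stats::filter(row, rep(1 / segment, segment), sides = 2L)
    sm <- as.numeric(sm)
    if (half > 0L) {
      for (i in seq_len(half)) {
        sm[i] <- mean(row[1:(i + half)])
        sm[p - i + 1L] <- mean(row[(p - i + 1L - half):p])
      }
    }
    sm
  }

  fill_nearest <- function(x, valid) {
    idx <- which(valid)
    x[seq_len(idx[1L] - 1L)] <- x[idx[1L]]
    last <- idx[length(idx)]
    if (last < length(x)) x[(last + 1L):length(x)] <- x[last]
    x
  }

  out <- t(apply(s$absorbance, 1L, function(row) {
    sm <- smooth_row(row)
    d <- rep(NA_real_, p)
    if (deriv == 1L) {
      i <- seq_len(p - gap)
      d[i] <- (sm[i + gap] - sm[i]) / (gap * h)
      valid <- !is.na(d)
    } else {
      i <- (gap + 1L):(p - gap)
      d[i] <- (sm[i + gap] - 2 * sm[i] + sm[i - gap]) / (gap * h)^2
      valid <- !is.na(d)
    }
    fill_nearest(d, valid)
  }))
  spectrum_set(s$sample_ids, s$grid, out)
}

#' Apply a preprocessing treatment
#'
#' Dispatches a [preprocess_spec()] to the matching filter; order 0 with no
#' smoother is the identity.
#'
#' @param spec A [preprocess_spec()] or one of the labels
#'   `"raw"`, `"1d-sg"`, `"1d-no"`, `"2d-sg"`, `"2d-no"`.
#' @param s A [spectrum_set()].
#' @return The preprocessed [spectrum_set()].
#' @export
apply_preprocess <- function(spec, s) {
  if (is.character(spec)) {
    labels <- preprocess_labels()
    if (!spec %in% names(labels)) {
      stop("unknown preprocessing label '", spec, "'; expected one of ",
           paste(names(labels), collapse = ", "), call. = FALSE)
    }
    spec <- labels[[spec]]
  }
  stopifnot(inherits(spec, "preprocess_spec"))
  if (spec$derivative_order == 0L) return(s)
  switch(spec$smoother,
    savitzky_golay = savitzky_golay(s, spec$sg_window, spec$sg_polyorder,
                                    spec$derivative_order),
    norris = norris_derivative(s, spec$norris_segment, spec$norris_gap,
                               spec$derivative_order),
    stop("derivatives require a smoother", call. = FALSE)
  )
}
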