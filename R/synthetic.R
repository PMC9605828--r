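#' Broad-band absorption panel of the serum matrix
#'
#' Serum is a complex mixture: beyond water, its proteins, lipids and small
#' metabolites contribute dozens of broad, overlapping NIR bands whose
#' levels vary from sample to sample and interfere with any single analyte.
#' This fixed panel of 25 broad Gaussian bands (centres across the working
#' range, widths 100-300 cm\eqn{^{-1}}, amplitudes 0.02-0.12 absorbance
#' units at unit level) emulates that matrix; it is the default
#' `interferent_bands` of [generator_config()].
#'
#' @return List of 25 `c(center, width, amplitude)` bands.
#' @export
serum_matrix_bands <- function() {
  list(
    c(8966.5, 129.5, 0.036),
    c(8025.0, 152.3, 0.054),
    c(6602.6, 251.4, 0.071),
    c(5412.9, 156.1, 0.062),
    c(9411.4, 175.4, 0.100),
    c(5844.8, 179.3, 0.080),
    c(9596.1, 251.9, 0.066),
    c(9039.9, 259.9, 0.117),
    c(7239.0, 129.5, 0.093),
    c(4866.6, 267.7, 0.096),
    c(5723.1, 265.5, 0.087),
    c(6910.0, 285.1, 0.055),
    c(6127.6, 113.9, 0.051),
    c(4991.2, 266.7, 0.098),
    c(5677.2, 123.2, 0.119),
    c(8952.8, 117.1, 0.071),
    c(4805.6, 159.9, 0.058),
    c(5748.3, 156.1, 0.087),
    c(8145.6, 150.6, 0.099),
    c(4495.6, 188.8, 0.080),
    c(8818.7, 209.2, 0.047),
    c(9294.1, 161.6, 0.038),
    c(8325.9, 105.2, 0.115),
    c(5940.5, 236.6, 0.120),
    c(6822.4, 123.3, 0.095)
  )
}

#' Configuration for the serum-like spectrum generator
#'
#' Collects every knob of the synthetic NIR generator. The defaults emulate
#' the serum proline cohort the package targets: 207 samples on a 1557-point
#' grid spanning 10000 to 4000 cm\eqn{^{-1}}, proline concentrations with
#' mean 0.005234 and SD 0.001866 mg/ml truncated to
#' [0.001917, 0.008198] mg/ml, analyte absorption in the characteristic
#' proline bands near 7352, 8620 and 5988 cm\eqn{^{-1}}, and a dominant
#' water-like broad background (serum is about 90% water).
#'
#' Bands are given as `list(c(center, width, amplitude))`: a Gaussian at
#' `center` cm\eqn{^{-1}} with standard deviation `width` cm\eqn{^{-1}} and
#' peak amplitude `amplitude` (absorbance units per mg/ml for the analyte;
#' absorbance units for background/interferents at unit component level).
#'
#' @param n_samples Number of samples to simulate (>= 2).
#' @param grid Wavenumber grid from [make_grid()].
#' @param analyte_bands List of analyte `c(center, width, amplitude)` bands.
#' @param interferent_bands List of interferent bands; each entry is one
#'   band of an interfering solute whose per-sample level varies
#'   independently of the analyte. Default: the broad serum matrix panel
#'   of [serum_matrix_bands()].
#' @param background_bands List of broad background bands (water overtone /
#'   combination regions); their amplitudes dwarf the analyte signal.
#' @param conc_mean,conc_sd Mean and SD (mg/ml) of the analyte concentration
#'   law (normal, rejection-truncated to `[conc_min, conc_max]`).
#' @param conc_min,conc_max Truncation bounds (mg/ml).
#' @param baseline_offset_sd SD of the per-sample additive baseline offset
#'   (absorbance units).
#' @param baseline_slope_sd SD of the per-sample baseline tilt, expressed as
#'   absorbance change across the full grid span.
#' @param scatter_sd SD of the per-sample multiplicative scatter factor
#'   (dimensionless, factor = 1 + N(0, scatter_sd)).
#' @param background_level_sd Relative SD of the per-sample level of each
#'   background band (water content varies from sample to sample).
#' @param background_shift_sd SD (cm\eqn{^{-1}}) of the per-sample shift of
#'   each background band's centre, emulating the thermal displacement of
#'   the broad water bands. Being broad, shifted backgrounds are largely
#'   annihilated by second-derivative preprocessing while narrow analyte
#'   bands survive.
#' @param noise_sd SD of iid additive noise per grid point (absorbance).
#' @param reference_error_sd SD (mg/ml) of the additive error of the
#'   reference method (stands in for HPLC uncertainty); default 2% of
#'   `conc_mean`.
#' @param interferent_level_sd SD of the per-sample interferent level around
#'   its unit mean (dimensionless).
#' @param seed Integer seed; identical configurations give identical data.
#' @return A validated list of class `generator_config`.
#' @seealso [simulate_serum_spectra()], [sparse_signal_config()],
#'   [baseline_drift_config()]
#' @export
generator_config <- function(n_samples = 207,
                             grid = make_grid(10000, 4000, 1557),
                             analyte_bands = list(
                               c(7352, 40, 1.5),
                               c(8620, 45, 0.9),
                               c(5988, 35, 1.2)
                             ),
                             interferent_bands = serum_matrix_bands(),
                             background_bands = list(
                               c(5200, 400, 1.0),
                               c(6900, 300, 0.6)
                             ),
                             conc_mean = 0.005234,
                             conc_sd = 0.001866,
                             conc_min = 0.001917,
                             conc_max = 0.008198,
                             baseline_offset_sd = 0.01,
                             baseline_slope_sd = 0.01,
                             scatter_sd = 0.01,
                             background_level_sd = 0.05,
                             background_shift_sd = 10,
                             noise_sd = 2e-4,
                             reference_error_sd = 0.02 * conc_mean,
                             interferent_level_sd = 0.15,
                             seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), grid = grid,
    analyte_bands = analyte_bands, interferent_bands = interferent_bands,
    background_bands = background_bands,
    conc_mean = conc_mean, conc_sd = conc_sd,
    conc_min = conc_min, conc_max = conc_max,
    baseline_offset_sd = baseline_offset_sd,
    baseline_slope_sd = baseline_slope_sd,
    scatter_sd = scatter_sd,
    background_level_sd = background_level_sd,
    background_shift_sd = background_shift_sd,
    noise_sd = noise_sd,
    reference_error_sd = reference_error_sd,
    interferent_level_sd = interferent_level_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  assert_grid(cfg$grid)
  if (cfg$n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  if (!(cfg$conc_min < cfg$conc_mean && cfg$conc_mean < cfg$conc_max)) {
    stop("need conc_min < conc_mean < conc_max", call. = FALSE)
  }
  sds <- c(cfg$conc_sd, cfg$baseline_offset_sd, cfg$baseline_slope_sd,
           cfg$scatter_sd, cfg$noise_sd, cfg$reference_error_sd,
           cfg$interferent_level_sd, cfg$background_level_sd,
           cfg$background_shift_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  span <- range(cfg$grid)
  for (b in c(cfg$analyte_bands, cfg$interferent_bands,
              cfg$background_bands)) {
    if (length(b) != 3L) {
      stop("each band must be c(center, width, amplitude)", call. = FALSE)
    }
    if (b[1L] < span[1L] || b[1L] > span[2L]) {
      stop(sprintf("band center %.1f lies outside the grid span", b[1L]),
           call. = FALSE)
    }
    if (b[2L] < 0) stop("band width must be non-negative", call. = FALSE)
  }
  cfg
}

#' Read a generator configuration from a YAML file
#'
#' Accepts a flat key-value YAML file mirroring the [generator_config()]
#' arguments; bands are given as lists of 3-element `[center, width,
#' amplitude]` sequences. Missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown generator config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("analyte_bands", "interferent_bands", "background_bands")) {
    if (!is.null(raw[[key]])) raw[[key]] <- lapply(raw[[key]], as.numeric)
  }
  if (!is.null(raw$grid)) raw$grid <- as.numeric(raw$grid)
  do.call(generator_config, raw)
}

#' Draw analyte concentrations under the configured truncated-normal law
#'
#' Samples `cfg$n_samples` concentrations from
#' N(`conc_mean`, `conc_sd`\eqn{^2}) and rejection-truncates to
#' `[conc_min, conc_max]`. With `conc_sd = 0` all draws equal the mean
#' (which must then lie inside the bounds).
#'
#' @param cfg A [generator_config()].
#' @return Numeric vector of concentrations (mg/ml), deterministic given
#'   `cfg$seed`.
#' @export
sample_concentrations <- function(cfg) {
  cfg <- validate_generator_config(cfg)
  set.seed(cfg$seed)
  draw_concentrations(cfg$n_samples, cfg$conc_mean, cfg$conc_sd,
                      cfg$conc_min, cfg$conc_max)
}

# rejection-truncated normal draws using the current RNG stream
draw_concentrations <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate concentration law (sd = 0) with mean outside bounds",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)), mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Evaluate a pure-component spectrum as a sum of Gaussian bands
#'
#' NIR absorption bands are approximated as Gaussians in wavenumber; a pure
#' component is the sum of its bands evaluated on the grid.
#'
#' @param bands List of `c(center, width, amplitude)` bands (possibly empty).
#' @param grid Wavenumber grid.
#' @return Non-negative absorbance vector, one value per grid point.
#' @export
pure_component_spectrum <- function(bands, grid) {
  assert_grid(grid)
  out <- numeric(length(grid))
  for (b in bands) {
    if (b[2L] < 0) stop("band width must be non-negative", call. = FALSE)
    if (b[2L] == 0) {
      k <- which.min(abs(grid - b[1L]))
      out[k] <- out[k] + b[3L]
    } else {
      out <- out + b[3L] * exp(-(grid - b[1L])^2 / (2 * b[2L]^2))
    }
  }
  out
}

#' Simulate a serum-like NIR dataset with known ground truth
#'
#' Generates spectra under a Beer-Lambert mixture: each sample's spectrum is
#' `scatter * (background + conc * analyte + sum(level_j * interferent_j))
#' + baseline + noise`, with a per-sample multiplicative scatter factor, an
#' affine (offset + tilt) baseline, and iid additive noise. The dominant
#' broad background itself varies per sample: each background band's level
#' is jittered by `background_level_sd` (relative) and its centre by
#' `background_shift_sd` (cm\eqn{^{-1}}), emulating water-content and
#' thermal water-band variation between serum samples. The reference
#' concentrations carry an additive error emulating the reference assay.
#'
#' @param cfg A [generator_config()].
#' @return List with elements
#'   \describe{
#'     \item{spectra}{a [spectrum_set()] of `n_samples` spectra}
#'     \item{truth}{a list of class `ground_truth`: `true_concentrations`,
#'       `reference_concentrations` (truth plus reference-method error,
#'       floored at a tiny positive value), and `informative_mask`, a
#'       [retention_vector()] marking grid points where the analyte
#'       component exceeds 1% of its own maximum}
#'   }
#'   Reproducible: identical `cfg` (including seed) gives identical output.
#' @examples
#' sim <- simulate_serum_spectra(generator_config(n_samples = 10, seed = 7))
#' dim(sim$spectra$absorbance)
#' @export
simulate_serum_spectra <- function(cfg) {
  cfg <- validate_generator_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  grid <- cfg$grid
  p <- length(grid)

  conc <- draw_concentrations(n, cfg$conc_mean, cfg$conc_sd,
                              cfg$conc_min, cfg$conc_max)
  analyte <- pure_component_spectrum(cfg$analyte_bands, grid)

  # per-sample background: level and centre jitter of each broad band
  n_bg <- length(cfg$background_bands)
  background <- matrix(0, nrow = n, ncol = p)
  bg_levels <- matrix(1 + stats::rnorm(n * n_bg, 0, cfg$background_level_sd),
                      nrow = n, ncol = n_bg)
  bg_shifts <- matrix(stats::rnorm(n * n_bg, 0, cfg$background_shift_sd),
                      nrow = n, ncol = n_bg)
  for (j in seq_len(n_bg)) {
    b <- cfg$background_bands[[j]]
    for (i in seq_len(n)) {
      background[i, ] <- background[i, ] + bg_levels[i, j] *
        pure_component_spectrum(list(c(b[1L] + bg_shifts[i, j], b[2L],
                                       b[3L])), grid)
    }
  }

  n_int <- length(cfg$interferent_bands)
  interferents <- matrix(0, nrow = n_int, ncol = p)
  for (j in seq_len(n_int)) {
    interferents[j, ] <-
      pure_component_spectrum(cfg$interferent_bands[j], grid)
  }
  # per-sample interferent levels, unit mean, floored at zero
  levels <- matrix(pmax(0, stats::rnorm(n * n_int, 1, cfg$interferent_level_sd)),
                   nrow = n, ncol = n_int)

  scatter <- 1 + stats::rnorm(n, 0, cfg$scatter_sd)
  offset <- stats::rnorm(n, 0, cfg$baseline_offset_sd)
  tilt <- stats::rnorm(n, 0, cfg$baseline_slope_sd)
  # tilt is expressed as absorbance change across the full span
  ramp <- (grid - mean(grid)) / abs(diff(range(grid)))

  chem <- background + outer(conc, analyte) + levels %*% interferents
  spectra <- scatter * chem + outer(offset, rep(1, p)) + outer(tilt, ramp) +
    matrix(stats::rnorm(n * p, 0, cfg$noise_sd), nrow = n)

  ref <- conc + stats::rnorm(n, 0, cfg$reference_error_sd)
  ref <- pmax(ref, .Machine$double.eps)

  mask <- as.integer(analyte > 0.01 * max(analyte))
  if (sum(mask) < 1L) mask[which.min(abs(grid - cfg$analyte_bands[[1L]][1L]))] <- 1L

  ids <- sprintf("s%03d", seq_len(n))
  truth <- structure(
    list(true_concentrations = conc,
         reference_concentrations = ref,
         informative_mask = retention_vector(mask)),
    class = "ground_truth"
  )
  list(spectra = spectrum_set(ids, grid, spectra), truth = truth)
}

#' Sparse-signal benchmark configuration
#'
#' A benchmark preset for wavelength-selection experiments: a single analyte
#' band implanted wholly inside the fourth of nine equal spectral intervals
#' (roughly 7350-8000 cm\eqn{^{-1}} on the default grid), sized so that
#' about 5% of the 1557 variables are informative, under realistic noise,
#' scatter and baseline variation.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
sparse_signal_config <- function(seed = 1L, ...) {
  generator_config(
    analyte_bands = list(c(7667, 50, 1.5)),
    seed = seed,
    ...
  )
}

#' Strong-baseline benchmark configuration
#'
#' Preset with pronounced per-sample baseline offset and tilt variation,
#' used to demonstrate that derivative preprocessing outperforms raw spectra
#' when baseline drift dominates.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
baseline_drift_config <- function(seed = 1L, ...) {
  generator_config(
    analyte_bands = list(c(7667, 50, 1.5)),
    baseline_offset_sd = 0.2,
    baseline_slope_sd = 0.2,
    seed = seed,
    ...
  )
}
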