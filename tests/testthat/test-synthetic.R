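test_that("make_grid produces evenly spaced, endpoint-inclusive grids", {
  g <- make_grid(10000, 4000, 1557)
  expect_length(g, 1557)
  expect_equal(g[1], 10000)
  expect_equal(g[1557], 4000)
  expect_equal(unique(round(diff(g), 9)), -(10000 - 4000) / 1556)

  expect_equal(make_grid(10, 0, 2), c(10, 0))
  expect_equal(make_grid(10000, 4000, 3), c(10000, 7000, 4000))
  expect_error(make_grid(Inf, 0, 5), "finite")
  expect_error(make_grid(5, 5, 3), "differ")
  expect_error(make_grid(10, 0, 1), "at least 2")
})

test_that("concentration sampling honours the truncated-normal law", {
  cfg0 <- generator_config(n_samples = 7, conc_sd = 0, conc_mean = 0.005,
                           conc_min = 0.001, conc_max = 0.009)
  expect_equal(sample_concentrations(cfg0), rep(0.005, 7))

  cfg <- generator_config(n_samples = 10000, seed = 11)
  x <- sample_concentrations(cfg)
  expect_true(all(x >= cfg$conc_min & x <= cfg$conc_max))
  # oracle: closed-form truncated-normal mean
  mu_trunc <- truncnorm_mean(cfg$conc_mean, cfg$conc_sd,
                             cfg$conc_min, cfg$conc_max)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu_trunc), 4 * se)
  # truncation barely moves the cohort mean off the configured value
  expect_lt(abs(mean(x) - cfg$conc_mean), 1e-4)

  expect_identical(x, sample_concentrations(cfg))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_samples = 1), "n_samples")
  expect_error(generator_config(conc_mean = 0.01), "conc_min < conc_mean")
  expect_error(generator_config(noise_sd = -1), "SDs")
  expect_error(generator_config(analyte_bands = list(c(12000, 50, 1))),
               "outside the grid span")
})

test_that("pure component spectra are sums of Gaussian bands", {
  g <- make_grid(10000, 4000, 1557)
  expect_equal(pure_component_spectrum(list(), g), numeric(1557))

  one <- pure_component_spectrum(list(c(7352, 50, 1)), g)
  expect_equal(which.max(one), which.min(abs(g - 7352)))
  expect_true(all(one >= 0))

  b1 <- list(c(7352, 50, 1)); b2 <- list(c(5000, 40, 2))
  expect_equal(pure_component_spectrum(c(b1, b2), g),
               pure_component_spectrum(b1, g) + pure_component_spectrum(b2, g))
  expect_error(pure_component_spectrum(list(c(7352, -1, 1)), g),
               "non-negative")
})

test_that("simulation is deterministic and has the configured shape", {
  cfg <- generator_config(seed = 42)
  a <- simulate_serum_spectra(cfg)
  b <- simulate_serum_spectra(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$spectra$absorbance), c(207L, 1557L))
  expect_equal(length(a$truth$true_concentrations), 207L)
  expect_gt(cor(a$truth$true_concentrations,
                a$truth$reference_concentrations), 0)
})

test_that("noiseless simulation follows Beer-Lambert exactly", {
  # analyte band centred exactly on a grid point so the configured
  # amplitude is recoverable without interpolation error
  g <- make_grid(10000, 4000, 1557)
  center <- g[which.min(abs(g - 7352))]
  cfg <- generator_config(
    n_samples = 25, grid = g,
    analyte_bands = list(c(center, 50, 20)),
    interferent_bands = list(),
    noise_sd = 0, scatter_sd = 0,
    baseline_offset_sd = 0, baseline_slope_sd = 0,
    background_level_sd = 0, background_shift_sd = 0,
    reference_error_sd = 0, seed = 5
  )
  sim <- simulate_serum_spectra(cfg)
  conc <- sim$truth$true_concentrations
  background <- pure_component_spectrum(cfg$background_bands, g)
  analyte <- pure_component_spectrum(cfg$analyte_bands, g)
  # spectra are exact scalar multiples of the analyte plus background
  resid <- sweep(sim$spectra$absorbance, 2L, background) -
    outer(conc, analyte)
  expect_lt(max(abs(resid)), 1e-12)

  # OLS at the band maximum recovers the configured amplitude
  k <- which.max(analyte)
  slope <- coef(lm(sim$spectra$absorbance[, k] ~ conc))[["conc"]]
  expect_lt(abs(slope - 20) / 20, 1e-8)

  # informative mask marks exactly the >1% region of the analyte component
  expect_equal(as.integer(sim$truth$informative_mask),
               as.integer(analyte > 0.01 * max(analyte)))
})

test_that("generator configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_samples: 12",
    "conc_mean: 0.005",
    "conc_sd: 0.001",
    "conc_min: 0.002",
    "conc_max: 0.008",
    "seed: 9",
    "analyte_bands:",
    "  - [7352, 40, 20]"
  ), path)
  cfg <- read_generator_config(path)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n_samples, 12L)
  expect_equal(cfg$analyte_bands, list(c(7352, 40, 20)))
  writeLines("bogus_key: 1", path)
  expect_error(read_generator_config(path), "unknown generator config keys")
})
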