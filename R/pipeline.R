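# deterministic per-stage sub-seed: stages never share or consume the
# global RNG stream directly, so stage results are order-independent
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(global_seed) * 48271 + h * 9973) %% 2147483587)
}

#' Configure the end-to-end calibration experiment
#'
#' Defaults mirror the serum proline study conditions: the default
#' generator, second-derivative + Norris preprocessing, outlier screening
#' on, a 118/89 Kennard-Stone partition, an SMLR window of
#' 9503.48-7347.46 cm\eqn{^{-1}}, 9 iPLS intervals, and 5 inner latent
#' variables for the annealing search.
#'
#' @param generator A [generator_config()].
#' @param preprocess A [preprocess_spec()] or label (`"2d-no"` default).
#' @param screening Logical: exclude outlying spectra before splitting?
#' @param n_cal Calibration-set size (validation = remainder).
#' @param split_method `"kennard_stone"` (default) or `"random"`.
#' @param smlr_window Wavenumber range for [smlr()].
#' @param smlr_max_vars Maximum SMLR variables.
#' @param n_intervals iPLS interval count.
#' @param max_lv Largest LV count offered to cross-validation.
#' @param n_folds Cross-validation folds.
#' @param sa An [anneal_config()] (its seed is overridden by the derived
#'   stage seed).
#' @param seed Global seed; every stochastic stage derives its own seed from
#'   it and the stage name.
#' @param outdir Output directory for tables and artifacts, or `NULL` to
#'   skip writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            preprocess = "2d-no",
                            screening = TRUE,
                            n_cal = 118L,
                            split_method = c("kennard_stone", "random"),
                            smlr_window = c(9503.48, 7347.46),
                            smlr_max_vars = 10L,
                            n_intervals = 9L,
                            max_lv = 10L,
                            n_folds = 10L,
                            sa = anneal_config(),
                            seed = 1L,
                            outdir = NULL) {
  if (is.character(preprocess)) preprocess <- preprocess_labels()[[preprocess]]
  stopifnot(inherits(generator, "generator_config"),
            inherits(preprocess, "preprocess_spec"),
            inherits(sa, "anneal_config"))
  structure(
    list(generator = generator, preprocess = preprocess,
         screening = isTRUE(screening), n_cal = as.integer(n_cal),
         split_method = match.arg(split_method),
         smlr_window = smlr_window, smlr_max_vars = as.integer(smlr_max_vars),
         n_intervals = as.integer(n_intervals), max_lv = as.integer(max_lv),
         n_folds = as.integer(n_folds), sa = sa, seed = as.integer(seed),
         outdir = outdir),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(
      class = c("pipeline_stage_error", "error", "condition"),
      list(message = sprintf("[stage:%s] %s", stage, conditionMessage(e)),
           call = NULL, stage = stage)
    ))
  })
}

# generate -> preprocess -> screen -> split, shared by the experiment drivers
prepare_dataset <- function(cfg) {
  gen <- cfg$generator
  gen$seed <- stage_seed(cfg$seed, "generate")
  sim <- run_stage("generate", simulate_serum_spectra(gen))

  pre <- run_stage("preprocess", apply_preprocess(cfg$preprocess, sim$spectra))

  excluded <- character(0)
  report <- NULL
  if (cfg$screening) {
    report <- run_stage("screen", screen_outliers(pre))
    excluded <- report$excluded
  }
  keep <- !(pre$sample_ids %in% excluded)
  pre_kept <- subset_samples(pre, which(keep))
  y <- sim$truth$reference_concentrations[keep]

  n_cal <- min(cfg$n_cal, nrow(pre_kept$absorbance) - 1L)
  split <- run_stage("split", switch(cfg$split_method,
    kennard_stone = kennard_stone(pre_kept, n_cal),
    random = random_split(pre_kept, n_cal, stage_seed(cfg$seed, "split"))
  ))

  list(sim = sim, spectra = pre_kept, y = y, split = split,
       screen_report = report, excluded = excluded)
}

#' Run the four-strategy calibration experiment
#'
#' Generates (or accepts) a dataset, preprocesses it, screens outliers,
#' partitions calibration/validation, trains the four calibration strategies
#' (SMLR, full-spectrum PLS, iPLS, simulated-annealing PLS) and assembles
#' the four-row comparison table. With `cfg$outdir` set, all intermediate
#' tables (spectra, reference, screening report, split, annealing trace,
#' retained wavenumbers, comparison) and a JSON run manifest with the stage
#' seeds are written there.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_result`: `comparison` (one
#'   [build_report()] row per strategy), `models`, `split`,
#'   `screen_report`, `anneal`, `ipls`, `data` (the prepared dataset).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ds <- prepare_dataset(cfg)
  grid <- ds$spectra$grid
  ci <- ds$split$calibration_idx
  vi <- ds$split$validation_idx
  X_cal <- ds$spectra$absorbance[ci, , drop = FALSE]
  X_val <- ds$spectra$absorbance[vi, , drop = FALSE]
  y_cal <- ds$y[ci]
  y_val <- ds$y[vi]
  cv_seed <- stage_seed(cfg$seed, "cv")

  m_smlr <- run_stage("smlr",
    smlr(X_cal, y_cal, grid, cfg$smlr_window, max_vars = cfg$smlr_max_vars))
  rep_smlr <- build_report(m_smlr, X_cal, y_cal, X_val, y_val, label = "SMLR")

  f_pls <- run_stage("pls",
    fit_pls_cv(X_cal, y_cal, cfg$max_lv, cfg$n_folds, cv_seed))
  rep_pls <- build_report(f_pls$model, X_cal, y_cal, X_val, y_val,
                          cv = f_pls$cv, label = "PLS")

  m_ipls <- run_stage("ipls",
    ipls(X_cal, y_cal, grid, cfg$n_intervals, cfg$max_lv, cfg$n_folds,
         cv_seed))
  bi <- m_ipls$models[[m_ipls$best]]$variable_subset
  rep_ipls <- build_report(m_ipls$models[[m_ipls$best]],
                           X_cal[, bi, drop = FALSE], y_cal,
                           X_val[, bi, drop = FALSE], y_val, label = "iPLS")
  rep_ipls$RMSECV <- m_ipls$intervals$rmsecv[m_ipls$best]

  sa_cfg <- cfg$sa
  sa_cfg$seed <- stage_seed(cfg$seed, "sa")
  m_sa <- run_stage("sa", anneal(X_cal, y_cal, X_val, y_val, sa_cfg))
  si <- m_sa$model$variable_subset
  rep_sa <- build_report(m_sa$model, X_cal[, si, drop = FALSE], y_cal,
                         X_val[, si, drop = FALSE], y_val, label = "SA")

  comparison <- rbind(rep_smlr, rep_pls, rep_ipls, rep_sa)

  res <- structure(
    list(comparison = comparison,
         models = list(SMLR = m_smlr, PLS = f_pls$model,
                       iPLS = m_ipls$models[[m_ipls$best]],
                       SA = m_sa$model),
         split = ds$split, screen_report = ds$screen_report,
         anneal = m_sa, ipls = m_ipls, data = ds),
    class = "pipeline_result"
  )
  if (!is.null(cfg$outdir)) write_pipeline_artifacts(res, cfg)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$comparison[, c("label", "n_lv", "Rc", "RMSEC", "Rp", "RMSEP")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

write_pipeline_artifacts <- function(res, cfg) {
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ds <- res$data
  write_spectra(ds$sim$spectra, file.path(out, "spectra_raw.csv"))
  write_reference(
    stats::setNames(ds$sim$truth$reference_concentrations,
                    ds$sim$spectra$sample_ids),
    file.path(out, "reference.csv")
  )
  if (!is.null(res$screen_report)) {
    data.table::fwrite(
      data.table::data.table(
        sample_id = ds$sim$spectra$sample_ids,
        mahalanobis = res$screen_report$distance,
        chauvenet_flag = res$screen_report$chauvenet_flag,
        excluded = ds$sim$spectra$sample_ids %in% res$screen_report$excluded
      ),
      file.path(out, "screening.csv")
    )
  }
  data.table::fwrite(
    data.table::data.table(
      sample_id = c(res$split$calibration, res$split$validation),
      subset = rep(c("calibration", "validation"),
                   c(length(res$split$calibration),
                     length(res$split$validation)))
    ),
    file.path(out, "split.csv")
  )
  data.table::fwrite(res$comparison, file.path(out, "comparison.csv"))
  data.table::fwrite(res$anneal$trace, file.path(out, "anneal_trace.csv"))
  write_retention(res$anneal$mask, ds$spectra$grid,
                  file.path(out, "retained_wavenumbers.csv"))
  manifest <- list(
    seed = cfg$seed,
    stage_seeds = list(generate = stage_seed(cfg$seed, "generate"),
                       split = stage_seed(cfg$seed, "split"),
                       cv = stage_seed(cfg$seed, "cv"),
                       sa = stage_seed(cfg$seed, "sa")),
    n_samples = cfg$generator$n_samples,
    n_excluded = length(ds$excluded),
    files = list.files(out)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Compare the five preprocessing treatments under full-spectrum PLS
#'
#' Trains a cross-validated full-spectrum PLS model under each of the five
#' treatments (raw, first/second derivative with Savitzky-Golay or Norris
#' smoothing) on one generated dataset and reports the standard metrics per
#' treatment.
#'
#' @param cfg A [pipeline_config()]; its `preprocess` field is ignored
#'   (all five treatments are run).
#' @return `data.frame` with one [build_report()] row per treatment, labels
#'   `raw`, `1d-sg`, `1d-no`, `2d-sg`, `2d-no`.
#' @export
compare_preprocessing <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  gen <- cfg$generator
  gen$seed <- stage_seed(cfg$seed, "generate")
  sim <- run_stage("generate", simulate_serum_spectra(gen))
  cv_seed <- stage_seed(cfg$seed, "cv")

  rows <- lapply(names(preprocess_labels()), function(lab) {
    pre <- run_stage("preprocess", apply_preprocess(lab, sim$spectra))
    n_cal <- min(cfg$n_cal, nrow(pre$absorbance) - 1L)
    split <- run_stage("split", switch(cfg$split_method,
      kennard_stone = kennard_stone(pre, n_cal),
      random = random_split(pre, n_cal, stage_seed(cfg$seed, "split"))
    ))
    y <- sim$truth$reference_concentrations
    X_cal <- pre$absorbance[split$calibration_idx, , drop = FALSE]
    X_val <- pre$absorbance[split$validation_idx, , drop = FALSE]
    fit <- run_stage("pls",
      fit_pls_cv(X_cal, y[split$calibration_idx], cfg$max_lv, cfg$n_folds,
                 cv_seed))
    build_report(fit$model, X_cal, y[split$calibration_idx],
                 X_val, y[split$validation_idx], cv = fit$cv, label = lab)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(out, file.path(cfg$outdir,
                                      "preprocessing_comparison.csv"))
  }
  out
}
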