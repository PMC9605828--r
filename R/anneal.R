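#' Metropolis acceptance probability
#'
#' The annealing acceptance rule: a move whose objective change is
#' non-positive (an improvement or a tie) is accepted with probability 1;
#' a worsening move is accepted with probability `exp(-delta_e / temperature)`.
#' The sign convention is `delta_e = objective_previous - objective_new`
#' (objectives are maximized), so improvements give `delta_e <= 0`.
#'
#' @param delta_e Objective change (previous minus new).
#' @param temperature Temperature, > 0.
#' @return Acceptance probability in (0, 1].
#' @export
metropolis_probability <- function(delta_e, temperature) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be > 0", call. = FALSE)
  }
  if (delta_e <= 0) 1 else exp(-delta_e / temperature)
}

#' Metropolis acceptance draw
#'
#' Consumes exactly one uniform draw from the current RNG stream and accepts
#' with [metropolis_probability()].
#'
#' @inheritParams metropolis_probability
#' @return Logical: accept the move?
#' @export
metropolis_accept <- function(delta_e, temperature) {
  stats::runif(1L) < metropolis_probability(delta_e, temperature)
}

#' Propose a retention vector with a given number of retained features
#'
#' Rearranges the feature-retention mask: returns a uniformly random binary
#' mask of the same length with exactly `m` ones, drawn from the current RNG
#' stream (the current mask only fixes the length).
#'
#' @param V Current retention vector (or any vector of the right length).
#' @param m Number of features to retain, 1 <= m <= length(V).
#' @return A [retention_vector()].
#' @export
propose_mask <- function(V, m) {
  p <- length(V)
  m <- as.integer(m)
  if (m < 1L || m > p) stop("need 1 <= m <= length(V)", call. = FALSE)
  v <- integer(p)
  v[sample.int(p, m)] <- 1L
  retention_vector(v)
}

#' Annealing objective: validation-set correlation of a masked PLS fit
#'
#' Fits PLS on the calibration rows restricted to the retained columns and
#' returns the correlation coefficient Rp between predictions and reference
#' values on the validation rows. The component count is lowered to the
#' retained-feature count (or calibration rank) when necessary.
#'
#' @param V Retention vector over the columns of `X_cal` / `X_val`.
#' @param X_cal,y_cal Calibration set.
#' @param X_val,y_val Validation set.
#' @param n_lv Requested latent-variable count.
#' @return Rp in [0, 1].
#' @export
sa_objective <- function(V, X_cal, y_cal, X_val, y_val, n_lv = 5L) {
  idx <- which(as.integer(V) == 1L)
  if (!length(idx)) stop("empty retention vector", call. = FALSE)
  n_lv_eff <- min(as.integer(n_lv), length(idx), nrow(X_cal) - 1L)
  fit <- fit_pls(X_cal[, idx, drop = FALSE], y_cal, n_lv_eff,
                 variable_subset = idx)
  r_coefficient(predict(fit, X_val[, idx, drop = FALSE]), y_val)
}

#' Configuration of the simulated-annealing wavelength search
#'
#' @param t0 Initial temperature; `NULL` (default) calibrates it in a short
#'   warm-up so that about 80% of worsening moves would be accepted.
#' @param alpha Geometric cooling factor in (0, 1); the temperature is
#'   multiplied by `alpha` after every `steps_per_temp` proposals.
#' @param steps_per_temp Proposals evaluated per temperature step.
#' @param max_iterations Total number of proposals (the stopping rule).
#' @param n_lv Latent-variable count of the inner PLS fits.
#' @param shrink Fraction applied to the retained-feature count `m` after
#'   each global improvement (`m <- max(ceiling(shrink * m), n_lv)`);
#'   `shrink = 1` disables shrinking.
#' @param initial_m Initial retained-feature count; default half the grid.
#' @param warmup Number of warm-up proposals used to calibrate `t0`.
#' @param seed Integer seed.
#' @return A validated list of class `anneal_config`.
#' @export
anneal_config <- function(t0 = NULL, alpha = 0.95, steps_per_temp = 50L,
                          max_iterations = 500L, n_lv = 5L, shrink = 0.95,
                          initial_m = NULL, warmup = 30L, seed = 1L) {
  if (!is.null(t0) && (!is.finite(t0) || t0 <= 0)) {
    stop("t0 must be > 0 (or NULL for auto-calibration)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("need 0 < alpha < 1", call. = FALSE)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (steps_per_temp < 1L) stop("steps_per_temp must be >= 1", call. = FALSE)
  if (shrink <= 0 || shrink > 1) stop("need 0 < shrink <= 1", call. = FALSE)
  if (n_lv < 1L) stop("n_lv must be >= 1", call. = FALSE)
  structure(
    list(t0 = t0, alpha = alpha, steps_per_temp = as.integer(steps_per_temp),
         max_iterations = as.integer(max_iterations), n_lv = as.integer(n_lv),
         shrink = shrink, initial_m = initial_m,
         warmup = as.integer(warmup), seed = as.integer(seed)),
    class = "anneal_config"
  )
}

#' Simulated-annealing wavelength selection for PLS calibration
#'
#' Searches the space of binary feature-retention vectors `V` for the mask
#' whose masked PLS model maximizes the validation-set correlation Rp.
#' The loop: initialize `V` with `m` retained features (`m` below the full
#' variable count); repeatedly rearrange the mask at the current `m`, score
#' it, and Metropolis-accept the move (worsening moves pass with probability
#' `exp(-delta_e / T)`); stop after `max_iterations` proposals. Whenever a
#' proposal improves on the global best, `m` is shrunk by the configured
#' fraction (floored at `n_lv`), steering the search toward sparser masks.
#' The temperature cools geometrically every `steps_per_temp` proposals.
#'
#' Because the objective is scored on the validation set, the reported Rp of
#' the selected mask is selection-biased; judge generalization on a third
#' held-out set if one is available.
#'
#' @param X_cal,y_cal Calibration spectra (samples x variables) and
#'   reference values.
#' @param X_val,y_val Validation spectra and reference values (disjoint
#'   samples).
#' @param cfg An [anneal_config()].
#' @return List of class `anneal_result`:
#'   \describe{
#'     \item{mask}{best-ever [retention_vector()]}
#'     \item{model}{`pls_model` refit on the best mask (with
#'       `variable_subset`)}
#'     \item{objective}{best-ever Rp}
#'     \item{trace}{data.frame per proposal: `iteration`, `temperature`,
#'       `m`, `objective`, `delta_e`, `accepted`, `best_objective`}
#'     \item{t0}{initial temperature actually used}
#'   }
#' @export
anneal <- function(X_cal, y_cal, X_val, y_val, cfg = anneal_config()) {
  stopifnot(inherits(cfg, "anneal_config"))
  X_cal <- as.matrix(X_cal); X_val <- as.matrix(X_val)
  p <- ncol(X_cal)
  if (ncol(X_val) != p) stop("calibration and validation widths differ",
                             call. = FALSE)
  m_floor <- min(cfg$n_lv, p)
  m <- if (is.null(cfg$initial_m)) max(p %/% 2L, m_floor) else
    as.integer(cfg$initial_m)
  if (m < 1L || m > p) stop("initial_m out of range", call. = FALSE)

  set.seed(cfg$seed)
  score <- function(V) sa_objective(V, X_cal, y_cal, X_val, y_val, cfg$n_lv)

  V_cur <- if (m == p) retention_vector(rep(1L, p)) else
    propose_mask(integer(p), m)
  e_cur <- score(V_cur)
  V_best <- V_cur
  e_best <- e_cur

  t_now <- cfg$t0
  if (is.null(t_now)) {
    # warm-up: size T0 so ~80% of observed worsening moves would be accepted
    worsen <- numeric(0)
    for (i in seq_len(cfg$warmup)) {
      d <- e_cur - score(propose_mask(V_cur, m))
      if (d > 0) worsen <- c(worsen, d)
    }
    t_now <- if (length(worsen)) mean(worsen) / -log(0.8) else 0.05
  }
  t0 <- t_now

  it <- integer(cfg$max_iterations)
  tr_temp <- tr_obj <- tr_de <- tr_best <- numeric(cfg$max_iterations)
  tr_m <- integer(cfg$max_iterations)
  tr_acc <- logical(cfg$max_iterations)

  for (i in seq_len(cfg$max_iterations)) {
    V_new <- propose_mask(V_cur, m)
    e_new <- score(V_new)
    d <- e_cur - e_new
    acc <- metropolis_accept(d, t_now)
    if (acc) {
      V_cur <- V_new
      e_cur <- e_new
    }
    if (e_new > e_best) {
      V_best <- V_new
      e_best <- e_new
      m <- max(ceiling(cfg$shrink * m), m_floor)
    }
    it[i] <- i; tr_temp[i] <- t_now; tr_m[i] <- m
    tr_obj[i] <- e_new; tr_de[i] <- d; tr_acc[i] <- acc; tr_best[i] <- e_best
    if (i %% cfg$steps_per_temp == 0L) t_now <- cfg$alpha * t_now
  }

  idx <- which(as.integer(V_best) == 1L)
  n_lv_eff <- min(cfg$n_lv, length(idx), nrow(X_cal) - 1L)
  model <- fit_pls(X_cal[, idx, drop = FALSE], y_cal, n_lv_eff,
                   variable_subset = idx)
  structure(
    list(mask = V_best, model = model, objective = e_best,
         trace = data.frame(iteration = it, temperature = tr_temp, m = tr_m,
                            objective = tr_obj, delta_e = tr_de,
                            accepted = tr_acc, best_objective = tr_best),
         t0 = t0),
    class = "anneal_result"
  )
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf(
    "<anneal_result: %d of %d variables retained, best Rp %.4f (%d proposals)>\n",
    attr(x$mask, "m"), length(x$mask), x$objective, nrow(x$trace)))
  invisible(x)
}

#' Export a retention mask as a wavenumber/flag table
#'
#' @param mask A [retention_vector()].
#' @param grid Matching wavenumber grid.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_retention <- function(mask, grid, path) {
  if (length(mask) != length(grid)) {
    stop("mask and grid lengths differ", call. = FALSE)
  }
  data.table::fwrite(
    data.table::data.table(wavenumber = grid, retained = as.integer(mask)),
    path
  )
  invisible(path)
}
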