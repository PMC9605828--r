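test_that("Metropolis probability follows the two-branch criterion", {
  for (de in c(-5, -0.01, 0)) {
    expect_identical(metropolis_probability(de, 1), 1)
    expect_identical(metropolis_probability(de, 1e-9), 1)
  }
  expect_equal(metropolis_probability(0.1, 0.1), exp(-1))
  expect_error(metropolis_probability(0.1, 0), "temperature")
  expect_error(metropolis_probability(0.1, -1), "temperature")

  # monotone: non-increasing in delta_e at fixed T, non-decreasing in T
  for (T in c(0.05, 0.2, 1)) {
    p <- vapply(c(0.01, 0.1, 0.5), metropolis_probability, numeric(1),
                temperature = T)
    expect_true(all(diff(p) < 0))
  }
  for (de in c(0.01, 0.1, 0.5)) {
    p <- vapply(c(0.05, 0.2, 1), function(T) metropolis_probability(de, T),
                numeric(1))
    expect_true(all(diff(p) > 0))
  }
})

test_that("Metropolis acceptance frequency matches its probability", {
  set.seed(123)
  acc <- vapply(seq_len(1e5), function(i) metropolis_accept(0.1, 0.1),
                logical(1))
  expect_lt(abs(mean(acc) - exp(-1)), 0.005)
  # improvements and ties are always accepted
  expect_true(all(vapply(1:50, function(i) metropolis_accept(-0.01, 0.5),
                         logical(1))))
  expect_true(all(vapply(1:50, function(i) metropolis_accept(0, 0.5),
                         logical(1))))
})

test_that("mask proposals are uniform over m-subsets", {
  expect_equal(as.integer(propose_mask(integer(4), 4)), rep(1L, 4))
  expect_equal(sum(propose_mask(integer(50), 1)), 1)
  expect_error(propose_mask(integer(5), 0), "1 <= m")
  expect_error(propose_mask(integer(5), 6), "1 <= m")

  set.seed(42)
  draws <- replicate(1e4, paste(as.integer(propose_mask(integer(6), 3)),
                                collapse = ""))
  freq <- table(draws) / 1e4
  expect_length(freq, choose(6, 3))
  expect_true(all(abs(freq - 0.05) < 0.01))
})

test_that("the annealing objective reduces to full-spectrum PLS and ranks
           informative masks above noise masks", {
  # a whisper of noise keeps the uninformative columns non-constant so a
  # noise-only mask is fittable (and still hopeless)
  sim <- tiny_sim(n = 30, p = 120, seed = 7, noiseless = TRUE,
                  noise_sd = 1e-6)
  pre <- sim$spectra
  y <- sim$truth$reference_concentrations
  sp <- kennard_stone(pre, 20)
  Xc <- pre$absorbance[sp$calibration_idx, ]
  Xv <- pre$absorbance[sp$validation_idx, ]
  yc <- y[sp$calibration_idx]; yv <- y[sp$validation_idx]

  all_ones <- retention_vector(rep(1L, 120))
  full <- fit_pls(Xc, yc, 5)
  expect_equal(sa_objective(all_ones, Xc, yc, Xv, yv, 5),
               r_coefficient(predict(full, Xv), yv), tolerance = 1e-12)

  informative <- sim$truth$informative_mask
  r_info <- sa_objective(informative, Xc, yc, Xv, yv, 5)
  expect_gt(r_info, 0.999)

  noise_mask <- retention_vector(1L - as.integer(informative))
  r_noise <- sa_objective(noise_mask, Xc, yc, Xv, yv, 5)
  expect_lt(r_noise, r_info)
})

test_that("annealing traces are monotone in the global best and respect the
           termination and greedy contracts", {
  sim <- tiny_sim(n = 30, p = 80, seed = 8)
  pre <- apply_preprocess("2d-no", sim$spectra)
  y <- sim$truth$reference_concentrations
  sp <- kennard_stone(pre, 20)
  Xc <- pre$absorbance[sp$calibration_idx, ]
  Xv <- pre$absorbance[sp$validation_idx, ]
  yc <- y[sp$calibration_idx]; yv <- y[sp$validation_idx]

  res <- anneal(Xc, yc, Xv, yv,
                anneal_config(max_iterations = 60, steps_per_temp = 15,
                              seed = 2))
  expect_true(all(diff(res$trace$best_objective) >= 0))
  expect_equal(nrow(res$trace), 60L)
  expect_equal(attr(res$mask, "m"), sum(res$mask))
  expect_equal(res$objective, max(res$trace$best_objective))
  # the refit model predicts with the best mask's variables
  expect_equal(sort(res$model$variable_subset), which(res$mask == 1L))

  # greedy limit: only non-worsening moves are accepted
  greedy <- anneal(Xc, yc, Xv, yv,
                   anneal_config(t0 = 1e-12, max_iterations = 40, seed = 3))
  expect_true(all(greedy$trace$delta_e[greedy$trace$accepted] <= 0))

  # single iteration: evaluated initial mask, trace of length 1
  one <- anneal(Xc, yc, Xv, yv,
                anneal_config(t0 = 0.1, max_iterations = 1, seed = 4))
  expect_equal(nrow(one$trace), 1L)
})

test_that("with an all-ones start, no shrink and greedy acceptance the best
           objective never drops below full-spectrum PLS", {
  sim <- tiny_sim(n = 26, p = 60, seed = 9)
  pre <- sim$spectra
  y <- sim$truth$reference_concentrations
  sp <- kennard_stone(pre, 18)
  Xc <- pre$absorbance[sp$calibration_idx, ]
  Xv <- pre$absorbance[sp$validation_idx, ]
  yc <- y[sp$calibration_idx]; yv <- y[sp$validation_idx]

  full <- fit_pls(Xc, yc, 5)
  rp_full <- r_coefficient(predict(full, Xv), yv)
  res <- anneal(Xc, yc, Xv, yv,
                anneal_config(t0 = 1e-12, shrink = 1, initial_m = 60,
                              max_iterations = 30, seed = 5))
  expect_gte(res$objective, rp_full - 1e-12)
})

test_that("the retained-feature count floors at the inner LV count", {
  sim <- tiny_sim(n = 20, p = 30, seed = 10, noiseless = TRUE,
                  noise_sd = 1e-6)
  y <- sim$truth$reference_concentrations
  sp <- kennard_stone(sim$spectra, 14)
  Xc <- sim$spectra$absorbance[sp$calibration_idx, ]
  Xv <- sim$spectra$absorbance[sp$validation_idx, ]
  res <- anneal(Xc, y[sp$calibration_idx], Xv, y[sp$validation_idx],
                anneal_config(max_iterations = 120, n_lv = 3, shrink = 0.5,
                              initial_m = 10, seed = 6))
  expect_true(all(res$trace$m >= 3))
})
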