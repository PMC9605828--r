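make_set <- function(mat, grid) {
  spectrum_set(sprintf("s%d", seq_len(nrow(mat))), grid, mat)
}

test_that("Savitzky-Golay reproduces analytic derivatives", {
  g <- make_grid(10000, 4000, 200)

  # interpolating fit (polyorder = window - 1) is the identity at deriv 0
  set.seed(1)
  s <- make_set(matrix(rnorm(2 * 200), 2), g)
  out <- savitzky_golay(s, window = 5, polyorder = 4, deriv = 0)
  expect_lt(max(abs(out$absorbance - s$absorbance)), 1e-10)

  # f(nu) = nu^2: second derivative is the constant 2 (per cm^-2)
  sq <- make_set(matrix(g^2, 1), g)
  d2 <- savitzky_golay(sq, window = 11, polyorder = 3, deriv = 2)
  interior <- 6:195
  expect_lt(max(abs(d2$absorbance[1, interior] - 2)), 1e-8)

  # first derivative of a constant spectrum is zero
  const <- make_set(matrix(1.7, 1, 200), g)
  d1 <- savitzky_golay(const, window = 11, polyorder = 3, deriv = 1)
  expect_lt(max(abs(d1$absorbance)), 1e-12)

  expect_error(savitzky_golay(make_set(matrix(1, 1, 5), make_grid(10, 0, 5)),
                              window = 7, polyorder = 2, deriv = 1),
               "exceeds")
})

test_that("Savitzky-Golay agrees with a dense per-window polynomial fit", {
  g <- make_grid(8000, 5000, 64)
  set.seed(7)
  for (case in list(c(7, 2, 1), c(11, 3, 2), c(9, 4, 0))) {
    row <- rnorm(64)
    got <- savitzky_golay(make_set(matrix(row, 1), g),
                          window = case[1], polyorder = case[2],
                          deriv = case[3])$absorbance[1, ]
    want <- sg_oracle(row, g, case[1], case[2], case[3])
    keep <- !is.na(want)
    expect_lt(max(abs(got[keep] - want[keep])), 1e-8)
  }
})

test_that("Norris derivative annihilates and differentiates affine spectra", {
  g <- make_grid(10000, 4000, 150)
  a <- 3e-4; b <- 0.2
  aff <- make_set(matrix(a * g + b, 1), g)

  d2 <- norris_derivative(aff, segment = 5, gap = 5, deriv = 2)
  interior <- 10:141   # clear of the filled edge stencil
  expect_lt(max(abs(d2$absorbance[1, interior])), 1e-15)

  d1 <- norris_derivative(aff, segment = 5, gap = 5, deriv = 1)
  expect_lt(max(abs(d1$absorbance[1, interior] - a)), 1e-10)

  # segment 1, gap 1 first derivative reduces to the adjacent
  # difference quotient
  set.seed(3)
  row <- rnorm(150)
  got <- norris_derivative(make_set(matrix(row, 1), g),
                           segment = 1, gap = 1, deriv = 1)$absorbance[1, ]
  want <- diff(row) / diff(g)
  expect_equal(got[1:149], want)
  expect_equal(got[150], want[149])   # edge fill: nearest valid value

  expect_error(norris_derivative(make_set(matrix(1, 1, 8), make_grid(8, 1, 8)),
                                 segment = 5, gap = 5, deriv = 2),
               "stencil")
})

test_that("all preprocessing filters are linear operators", {
  g <- make_grid(9000, 5000, 90)
  set.seed(11)
  A <- matrix(rnorm(3 * 90), 3)
  B <- matrix(rnorm(3 * 90), 3)
  for (lab in c("1d-sg", "1d-no", "2d-sg", "2d-no")) {
    fA <- apply_preprocess(lab, make_set(A, g))$absorbance
    fB <- apply_preprocess(lab, make_set(B, g))$absorbance
    fAB <- apply_preprocess(lab, make_set(A + B, g))$absorbance
    expect_lt(max(abs(fAB - (fA + fB))), 1e-10)
  }
})

test_that("apply_preprocess dispatches correctly", {
  sim <- tiny_sim(n = 4, p = 80, seed = 9)
  s <- sim$spectra

  expect_identical(apply_preprocess("raw", s), s)
  expect_identical(apply_preprocess(preprocess_spec(0, "none"), s), s)

  expect_equal(apply_preprocess("2d-no", s),
               norris_derivative(s, 5, 5, 2))
  expect_equal(apply_preprocess("1d-sg", s),
               savitzky_golay(s, 11, 3, 1))
  expect_error(apply_preprocess("3d-xx", s), "unknown preprocessing label")
})

test_that("inconsistent preprocessing specs are rejected", {
  expect_error(preprocess_spec(1, "none"), "require a smoother")
  expect_error(preprocess_spec(0, "none", sg_window = 4), "odd")
  expect_error(preprocess_spec(0, "none", sg_window = 5, sg_polyorder = 5),
               "smaller than")
  expect_error(preprocess_spec(2, "savitzky_golay", sg_polyorder = 1),
               "exceed")
  expect_error(preprocess_spec(1, "norris", norris_gap = 0), "gap")
})
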