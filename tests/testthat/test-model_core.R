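test_that("placebo effect forms start at zero and approach their extremum", {
  forms <- list(
    list(form = "emax", et50 = 7.99),
    list(form = "sigmoid_emax", et50 = 7.99, hill = 1.7),
    list(form = "exponential", k_onset = 0.09),
    list(form = "inverse_bateman", k_onset = 0.2, k_offset = 0.01))
  for (f in forms) {
    v0 <- do.call(placebo_effect,
                  c(list(t = 0, beta = -1.87), f))
    expect_identical(unname(v0), 0)
    tt <- seq(0, 200, by = 0.5)
    v <- do.call(placebo_effect, c(list(t = tt, beta = -1.87), f))
    expect_true(all(abs(v) <= abs(-1.87) + 1e-12))
  }
  expect_error(placebo_effect(1, beta = -1, et50 = 8, form = "banana"),
               "unknown placebo form")
})

test_that("Emax placebo reaches half its extent at ET50 and is monotone", {
  expect_equal(placebo_effect(7.99, beta = -1.87, et50 = 7.99), -0.935)
  expect_equal(placebo_effect(26, beta = -2.43, et50 = 7.99), -1.858782,
               tolerance = 1e-6)
  v <- placebo_effect(seq(0, 300, by = 1), beta = -1.87, et50 = 7.99)
  expect_true(all(diff(v) < 0))                  # monotone toward beta
  expect_gt(min(v), -1.87)                       # asymptote never crossed
})

test_that("inverse Bateman peaks at beta and rejects bad rate constants", {
  tt <- seq(0, 400, by = 0.05)
  v <- placebo_effect(tt, beta = -2, k_onset = 0.15, k_offset = 0.02,
                      form = "inverse_bateman")
  expect_equal(min(v), -2, tolerance = 1e-6)     # extremum equals beta
  expect_lt(abs(v[length(v)]), 0.01)             # effect washes out
  expect_error(placebo_effect(1, beta = -2, k_onset = 0.01, k_offset = 0.02,
                              form = "inverse_bateman"))
})

test_that("structural response is the published curve at subgroup parameters", {
  p <- population_parameters(alpha = 0.112, beta = -1.87, et50 = 7.99)
  expect_identical(structural_response(0, 0.1, -2, p), 0)
  expect_equal(structural_response(26, 6.11 / 52, -1.50, p), 1.907604,
               tolerance = 1e-6)
  expect_equal(structural_response(26, 5.45 / 52, -2.43, p), 0.866218,
               tolerance = 1e-6)
})

test_that("structural response is linear in alpha_i and beta_i", {
  p <- population_parameters(alpha = 0.1, beta = -2, et50 = 8)
  tt <- c(4, 12, 26, 52)
  for (k in 1:5) {
    a1 <- 0.03 * k; a2 <- -0.01 * k; b1 <- -1.1 * k; b2 <- 0.4 * k
    expect_equal(structural_response(tt, a1 + a2, b1 + b2, p),
                 structural_response(tt, a1, b1, p) +
                   structural_response(tt, a2, b2, p))
  }
})

test_that("every covariate form returns exactly 1 at the reference value", {
  set.seed(42)
  for (k in 1:20) {
    theta <- stats::runif(1, -3, 3)
    ref <- stats::runif(1, 10, 60)
    for (form in c("power", "linear", "inverse_u"))
      expect_identical(covariate_multiplier(ref, ref, theta, form), 1)
  }
})

test_that("age power factor reproduces the 60-vs-80 progression ratio", {
  ratio <- covariate_multiplier(60, 73.5, -2.17, "power") /
    covariate_multiplier(80, 73.5, -2.17, "power")
  expect_equal(ratio, 1.866883, tolerance = 1e-6)
  expect_equal(round(ratio, 2), 1.87)
})

test_that("inverse-U factor peaks at half the scale and its kernel is symmetric", {
  grid <- seq(0.01, 69.99, by = 0.01)
  f <- covariate_multiplier(grid, 24.5, 1.53, "inverse_u")
  expect_equal(grid[which.max(f)], 35.0)
  # kernel v*(70 - v) symmetry about 35
  v <- c(5, 12.3, 20, 30)
  expect_equal(covariate_multiplier(v, 24.5, 1.53, "inverse_u"),
               covariate_multiplier(70 - v, 24.5, 1.53, "inverse_u"))
  expect_error(covariate_multiplier(75, 24.5, 1.53, "inverse_u",
                                    covariate = "baseline_adas"),
               "baseline_adas")
})

test_that("individual parameters reproduce the typical published values", {
  p <- final_model_parameters()
  refs <- list(baseline_adas = 24.5, baseline_age = 73.5)
  ind <- individual_parameters(p, c(0, 0), refs)
  expect_equal(unname(ind), c(0.112, -1.87))
  expect_equal(ind[["alpha_i"]] * 52, 5.824)     # 5.82 points/year
  expect_equal(round(ind[["alpha_i"]] * 52, 2), 5.82)
  # proportional model: eta = -1 zeroes the study-level parameter
  expect_identical(individual_parameters(p, c(-1, 0), refs)[["alpha_i"]], 0)
  expect_error(individual_parameters(p, c(0, 0), list(baseline_adas = 24.5)),
               "missing covariate")
})

test_that("covariate factors multiply before the random-effect perturbation", {
  p <- final_model_parameters()
  covs <- list(baseline_adas = 30, baseline_age = 68)
  fac <- covariate_multiplier(30, 24.5, 1.53, "inverse_u") *
    covariate_multiplier(68, 73.5, -2.17, "power")
  ind <- individual_parameters(p, c(0.25, -0.4), covs)
  expect_equal(ind[["alpha_i"]], 0.112 * fac * 1.25)
  expect_equal(ind[["beta_i"]], -1.87 * 0.6)     # no covariates on beta
})

test_that("residual SD scales with the inverse square root of sample size", {
  expect_identical(residual_sd(5.64, 1), 5.64)
  expect_equal(residual_sd(5.64, 100), 0.564)
  n <- c(11, 25, 102, 300, 746)
  expect_true(all(diff(residual_sd(5.64, n)) < 0))
  expect_error(residual_sd(5.64, 0))
})
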