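test_that("generation is deterministic in the master seed", {
  a <- generate_trial_set(default_config(n_studies = 12, seed = 5))
  b <- generate_trial_set(default_config(n_studies = 12, seed = 5))
  c <- generate_trial_set(default_config(n_studies = 12, seed = 6))
  expect_identical(a$trial_set, b$trial_set)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$trial_set$observations$mean_change,
                         c$trial_set$observations$mean_change))
})

test_that("per-study substreams: adding studies never perturbs earlier ones", {
  small <- generate_trial_set(default_config(n_studies = 15, seed = 9))
  large <- generate_trial_set(default_config(n_studies = 40, seed = 9))
  expect_identical(small$trial_set$arms, large$trial_set$arms[1:15, ])
  expect_identical(small$truth, large$truth[1:15, ])
})

test_that("the noise-free limit reproduces the structural curve exactly", {
  p <- final_model_parameters()
  p$omega_alpha <- p$omega_beta <- p$rho <- 0
  p$delta <- 0
  cfg <- reference_profile_config(1, p, seed = 3,
                                  schedule_pool = list(c(4, 12, 26, 52)))
  sim <- generate_trial_set(cfg)
  o <- sim$trial_set$observations
  expect_equal(o$mean_change, 0.112 * o$time - 1.87 * o$time / (7.99 + o$time),
               tolerance = 1e-12)
  expect_equal(sim$truth$alpha_i, 0.112)
  expect_equal(sim$truth$beta_i, -1.87)
})

test_that("default configuration matches the published literature profile", {
  cfg <- default_config()
  expect_equal(cfg$n_studies, 140L)
  expect_equal(unname(cfg$true_params$alpha), 0.112)
  expect_equal(sum(cfg$region_probs), 1)
  expect_true(all(unlist(cfg$schedule_pool) <= 104))
  sim <- generate_trial_set(default_config(n_studies = 400, seed = 2))
  a <- sim$trial_set$arms
  expect_true(all(a$baseline_age >= 58.0 & a$baseline_age <= 81.7))
  expect_true(all(a$baseline_adas >= 13.1 & a$baseline_adas <= 39.3))
  expect_true(all(a$randomized_n >= 11 & a$randomized_n <= 746))
  expect_true(all(a$region %in% c("International", "NorthAmerica",
                                  "EuropeOceania", "EastAsia", "MiddleAsia",
                                  "SouthAmerica")))
  expect_equal(median(a$baseline_adas), 24.5, tolerance = 0.35)
  expect_equal(median(a$baseline_age), 73.5, tolerance = 0.35)
})

test_that("generator output always satisfies the data-quality rules", {
  for (seed in c(1, 77, 1234)) {
    sim <- generate_trial_set(default_config(n_studies = 30, seed = seed))
    expect_identical(nrow(validate_trials(sim$trial_set)), 0L)
  }
})

test_that("random-effect draws reproduce the published correlation", {
  sim <- generate_trial_set(default_config(n_studies = 10000, seed = 4))
  r <- cor(sim$truth$eta_alpha, sim$truth$eta_beta)
  expect_equal(r, -0.717, tolerance = 0.03)      # |r + 0.717| <= ~0.02 + MC
  expect_lt(abs(r + 0.717), 0.02 + 3 * (1 - 0.717^2) / sqrt(10000))
  expect_equal(sd(sim$truth$eta_alpha), 0.148, tolerance = 0.02)
  expect_equal(sd(sim$truth$eta_beta), 0.725, tolerance = 0.03)
})

test_that("observation noise scales as delta^2 / n across arm sizes", {
  p <- null_truth_params()
  p$omega_alpha <- p$omega_beta <- p$rho <- 0   # isolate the residual term
  cfg <- reference_profile_config(1500, p, seed = 8,
                                  schedule_pool = list(c(12, 26, 52)))
  sim <- generate_trial_set(cfg)
  o <- sim$trial_set$observations
  mu <- 0.112 * o$time - 1.87 * o$time / (7.99 + o$time)
  r2 <- (o$mean_change - mu)^2
  slope <- coef(lm(r2 ~ 0 + I(1 / o$n)))[[1]]   # through the origin
  expect_equal(slope, 5.64^2, tolerance = 0.12)
})

test_that("degenerate random-effect configs are rejected", {
  p <- null_truth_params()
  p$rho <- -1.3
  expect_error(default_config(n_studies = 5, true_params = p), "rho")
  expect_error(simulation_config(
    n_studies = 5, true_params = null_truth_params(),
    covariate_generators = list(), schedule_pool = list(26),
    arm_size_spec = list(), region_probs = c(a = 0.4, b = 0.4)),
    "region_probs")
})
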