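# Shared fixtures: all data are built in code at test time.

# three-arm hand-built trial set with known covariates and times
tiny_trial_set <- function() {
  arms <- data.frame(
    study_id = c("A", "B", "C"),
    publication_year = c(2001, 2012, 2015),
    region = c("NorthAmerica", "EastAsia", "banana republic"),
    add_on = c(FALSE, TRUE, FALSE),
    baseline_adas = c(24.5, 28.0, 20.0),
    baseline_age = c(73.5, 70.0, 76.0),
    randomized_n = c(100, 50, 200),
    stringsAsFactors = FALSE)
  obs <- data.frame(
    study_id = rep(c("A", "B", "C"), times = c(3, 2, 4)),
    time = c(12, 26, 52, 12, 26, 12, 26, 52, 104),
    mean_change = c(0.5, 1.4, 3.2, -0.2, 0.9, 0.8, 1.9, 4.0, 8.5),
    n = c(95, 90, 85, 48, 45, 190, 180, 170, 150),
    stringsAsFactors = FALSE)
  trial_set(arms, obs)
}

# generating parameters without covariate effects (null screening truth)
null_truth_params <- function() {
  population_parameters(alpha = 0.112, beta = -1.87, et50 = 7.99,
                        omega_alpha = 0.148, omega_beta = 0.725,
                        rho = -0.717, delta = 5.64)
}

# degenerate covariate generators: every study sits at the reference profile
reference_profile_config <- function(n_studies, true_params, seed = 1L,
                                     schedule_pool = NULL) {
  cfg <- default_config(n_studies = n_studies, true_params = true_params,
                        seed = seed)
  cfg$covariate_generators$baseline_adas <-
    list(mean = 24.5, sd = 0, lower = 24.5, upper = 24.5)
  cfg$covariate_generators$baseline_age <-
    list(mean = 73.5, sd = 0, lower = 73.5, upper = 73.5)
  if (!is.null(schedule_pool)) {
    cfg$schedule_pool <- schedule_pool
    cfg$schedule_weights <- rep(1 / length(schedule_pool),
                                length(schedule_pool))
  }
  cfg
}

# fit_result shell at known parameters (no optimization), for code paths
# that only need converged estimates
fake_fit <- function(p, spec = NULL) {
  structure(list(estimates = p, converged = TRUE,
                 spec = if (is.null(spec))
                   model_spec(p$placebo_form, p$covariate_model) else spec),
            class = "fit_result")
}

# 1e-6 is the package's stated convergence tolerance; looser settings can
# stall warm-started covariate fits on the theta = 0 plateau
fast_ctrl <- list(rel.tol = 1e-6)
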