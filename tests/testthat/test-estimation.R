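test_that("with no random effects the OFV is the weighted LS deviance", {
  ts <- tiny_trial_set()
  p <- population_parameters(alpha = 0.1, beta = -1.5, et50 = 8,
                             delta = 5)
  o <- ts$observations
  f <- 0.1 * o$time - 1.5 * o$time / (8 + o$time)
  dev <- sum((o$mean_change - f)^2 * o$n / 25 + log(2 * pi * 25 / o$n))
  expect_equal(neg2ll(ts, p), dev, tolerance = 1e-10)
})

test_that("Laplace agrees with adaptive Gauss-Hermite quadrature", {
  set.seed(11)
  for (k in 1:8) {
    p <- population_parameters(
      alpha = 0.112 * runif(1, 0.7, 1.4), beta = -1.87 * runif(1, 0.7, 1.4),
      et50 = 7.99 * runif(1, 0.7, 1.4),
      omega_alpha = runif(1, 0.05, 0.3), omega_beta = runif(1, 0.3, 0.9),
      rho = runif(1, -0.9, 0), delta = 5.64 * runif(1, 0.7, 1.3))
    sim <- generate_trial_set(
      default_config(n_studies = 5, true_params = null_truth_params(),
                     seed = 100 + k))
    lap <- neg2ll(sim$trial_set, p, method = "laplace")
    agq <- neg2ll(sim$trial_set, p, method = "agq", agq_nodes = 15)
    expect_lt(abs(lap - agq), 0.5)
  }
})

test_that("OFV decomposes over independent studies and ignores row order", {
  sim <- generate_trial_set(default_config(n_studies = 8, seed = 21))
  ts <- sim$trial_set
  p <- final_model_parameters()
  base <- neg2ll(ts, p)
  # duplicating every study doubles the OFV
  arms2 <- ts$arms
  arms2$study_id <- paste0(arms2$study_id, "dup")
  obs2 <- ts$observations
  obs2$study_id <- paste0(obs2$study_id, "dup")
  doubled <- trial_set(rbind(ts$arms, arms2), rbind(ts$observations, obs2),
                       ts$covariate_refs)
  expect_equal(neg2ll(doubled, p), 2 * base, tolerance = 1e-8)
  # permuting studies and observation rows changes nothing
  set.seed(1)
  perm <- trial_set(ts$arms[sample(8), ],
                    ts$observations[sample(nrow(ts$observations)), ],
                    ts$covariate_refs)
  expect_equal(neg2ll(perm, p), base, tolerance = 1e-10)
})

test_that("fitting noise-free data recovers the generating slope exactly", {
  p <- final_model_parameters()
  p$omega_alpha <- p$omega_beta <- p$rho <- 0
  p$delta <- 0.02
  cfg <- default_config(n_studies = 20, true_params = p, seed = 31)
  sim <- generate_trial_set(cfg)
  spec <- final_model_spec()
  spec$estimate_iiv <- FALSE
  fr <- fit_progression(sim$trial_set, spec)
  expect_true(fr$converged)
  expect_lt(abs(fr$estimates$alpha - 0.112), 1e-3)
  expect_lt(abs(fr$estimates$et50 - 7.99), 0.1)
})

test_that("fitting is deterministic given identical inputs", {
  sim <- generate_trial_set(default_config(n_studies = 25, seed = 41))
  f1 <- fit_progression(sim$trial_set, final_model_spec(),
                        control = fast_ctrl)
  f2 <- fit_progression(sim$trial_set, final_model_spec(),
                        control = fast_ctrl)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$ofv, f2$ofv)
  expect_identical(f1$ebe, f2$ebe)
})

test_that("reported uncertainty is internally consistent", {
  sim <- generate_trial_set(default_config(n_studies = 60, seed = 51))
  fr <- fit_progression(sim$trial_set, final_model_spec())
  expect_true(fr$converged)
  expect_equal(fr$aic, fr$ofv + 2 * fr$n_par)
  expect_true(is.na(fr$se[["rho"]]))             # correlation without an SE
  expect_equal(unname(fr$rse_percent[["alpha"]]),
               100 * fr$se[["alpha"]] / abs(fr$natural[["alpha"]]))
  # vcov symmetric PSD on the natural scale
  ev <- eigen(fr$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(abs(ev))))
  expect_equal(nrow(fr$ebe), 60L)
  tab <- parameter_table(fr)
  expect_true(all(tab$ci_lower <= tab$estimate & tab$estimate <= tab$ci_upper,
                  na.rm = TRUE))
})

test_that("empirical-Bayes modes shrink to zero as omega vanishes", {
  sim <- generate_trial_set(default_config(n_studies = 10, seed = 61))
  p <- final_model_parameters()
  p$omega_beta <- 0
  p$rho <- 0
  ebe <- empirical_bayes(sim$trial_set, fake_fit(p))
  expect_identical(ebe$eta_beta, rep(0, 10))
  expect_true(any(ebe$eta_alpha != 0))
})

test_that("data-rich studies recover their generating random effects", {
  p <- null_truth_params()
  p$delta <- 1.5                                 # low noise, dense design
  cfg <- reference_profile_config(
    12, p, seed = 71, schedule_pool = list(c(4, 8, 12, 18, 26, 39, 52, 78)))
  cfg$arm_size_spec <- list(median = 600, sdlog = 0.05, lower = 500,
                            upper = 746)
  sim <- generate_trial_set(cfg)
  ebe <- empirical_bayes(sim$trial_set, fake_fit(p))
  expect_equal(ebe$eta_alpha, sim$truth$eta_alpha, tolerance = 0.15)
  expect_gt(cor(ebe$eta_beta, sim$truth$eta_beta), 0.95)
})

test_that("sparse designs shrink far more than rich designs", {
  p <- null_truth_params()
  p$rho <- 0            # isolate per-effect information content
  sparse <- generate_trial_set(reference_profile_config(
    100, p, seed = 81, schedule_pool = list(c(26))))
  rich <- generate_trial_set(reference_profile_config(
    100, p, seed = 81, schedule_pool = list(c(4, 8, 12, 18, 24, 26, 39, 52))))
  sh_sparse <- attr(empirical_bayes(sparse$trial_set, fake_fit(p)),
                    "shrinkage")
  sh_rich <- attr(empirical_bayes(rich$trial_set, fake_fit(p)), "shrinkage")
  expect_gt(sh_sparse[["alpha"]], sh_rich[["alpha"]] + 0.15)
})

test_that("structural selection ranks by AIC with stable tie order", {
  sim <- generate_trial_set(default_config(n_studies = 50, seed = 91))
  tab <- select_structural(sim$trial_set, c("emax", "exponential"),
                           control = fast_ctrl)
  expect_true(all(tab$aic[tab$converged] ==
                    tab$ofv[tab$converged] + 2 * tab$n_par[tab$converged]))
  expect_equal(tab$form[1], "emax")              # generating form wins
  twice <- select_structural(sim$trial_set, c("emax", "emax"),
                             control = fast_ctrl)
  expect_equal(twice$aic[1], twice$aic[2])
  expect_equal(twice$form, c("emax", "emax"))
})

test_that("fit results serialize to JSON and back", {
  sim <- generate_trial_set(default_config(n_studies = 15, seed = 95))
  fr <- fit_progression(sim$trial_set, base_model_spec(),
                        control = fast_ctrl)
  js <- jsonlite::fromJSON(fit_to_json(fr))
  expect_equal(js$estimates$alpha, fr$natural[["alpha"]])
  expect_equal(js$ofv, fr$ofv)
  expect_true(js$converged)
})
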