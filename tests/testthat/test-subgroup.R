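test_that("covariate correction rescales to the reference profile", {
  p <- final_model_parameters()
  arms <- data.frame(
    study_id = c("ref", "young"),
    baseline_adas = c(24.5, 24.5), baseline_age = c(73.5, 60),
    randomized_n = c(100, 100))
  obs <- data.frame(study_id = rep(c("ref", "young"), each = 2),
                    time = rep(c(12, 26), 2),
                    mean_change = c(0.4, 1.2, 1.0, 2.4), n = 100)
  ts <- trial_set(arms, obs)
  ebe <- data.frame(study_id = c("ref", "young"),
                    alpha_i = c(0.112, 0.174), se_alpha_i = c(0.01, 0.01),
                    beta_i = c(-1.9, -1.8), se_beta_i = c(0.3, 0.3))
  out <- correct_estimates(ebe, ts, fake_fit(p))
  expect_equal(out$alpha_corr[1], 0.112)         # reference study unchanged
  expect_equal(out$alpha_corr[2], 0.1120196, tolerance = 1e-6)
  expect_equal(out$se_alpha_corr[2], 0.01 / 1.5532999, tolerance = 1e-6)
  expect_equal(out$beta_corr, out$beta_i)        # no covariates on beta
  expect_false(any(out$flagged))
})

test_that("correction removes the covariate-induced trend in the rate", {
  sim <- generate_trial_set(default_config(n_studies = 250, seed = 12))
  ts <- sim$trial_set
  fr <- fake_fit(final_model_parameters())
  ebe <- empirical_bayes(ts, fr)
  out <- correct_estimates(ebe, ts, fr)
  r_raw <- cor(out$alpha_i, ts$arms$baseline_age)
  r_corr <- cor(out$alpha_corr, ts$arms$baseline_age)
  expect_lt(r_raw, -0.3)                         # age slows progression
  expect_lt(abs(r_corr), 0.15)
  expect_lt(abs(r_corr), abs(r_raw) / 3)
})

test_that("DerSimonian-Laird pooling matches the hand-computed oracle", {
  # values {5, 7}, SEs {0.5, 0.5}: Q = 8, C = 4, tau2 = (8-1)/4 = 1.75,
  # weights 1/(0.25+1.75) -> pooled 6, SE = 1, CI = 6 +/- 1.96
  r <- pool_random_effects(c(5, 7), c(0.5, 0.5))
  expect_equal(r$mean, 6)
  expect_equal(r$tau2, 1.75)
  expect_equal(r$se, 1)
  expect_equal(r$ci_lower, 6 - 1.96 * 1, tolerance = 1e-4)
  expect_equal(r$ci_upper, 6 + 1.96 * 1, tolerance = 1e-4)
  expect_equal(r$k, 2)
})

test_that("pooling edge cases and invariances hold", {
  # identical values with equal SEs: tau2 = 0, pooled = common value
  r <- pool_random_effects(c(4.2, 4.2, 4.2), c(0.3, 0.3, 0.3))
  expect_equal(r$mean, 4.2)
  expect_equal(r$tau2, 0)
  # with tau2 = 0 and equal SEs the pooled mean is the arithmetic mean
  vals <- c(5.1, 5.6, 6.2, 5.9)
  r2 <- pool_random_effects(vals, rep(2, 4))     # large SE -> Q < df, tau2=0
  expect_equal(r2$tau2, 0)
  expect_equal(r2$mean, mean(vals))
  # order invariance
  set.seed(3)
  v <- rnorm(9, 5, 1); s <- runif(9, 0.2, 0.8)
  a <- pool_random_effects(v, s)
  b <- pool_random_effects(rev(v), rev(s))
  expect_equal(a$mean, b$mean)
  expect_equal(a$tau2, b$tau2)
  # single estimate pools to itself
  one <- pool_random_effects(5.82, 0.2)
  expect_equal(one$mean, 5.82)
  expect_equal(one$tau2, 0)
  expect_equal(one$ci_lower, 5.82 - 1.96 * 0.2)
})

test_that("the subgroup table annualizes, stratifies and stays order-invariant", {
  sim <- generate_trial_set(default_config(n_studies = 50, seed = 13))
  ts <- sim$trial_set
  fr <- fake_fit(final_model_parameters())
  fr$ebe <- empirical_bayes(ts, fr)
  tab <- subgroup_table(ts, fr, strata = "era")
  expect_true(all(c("Overall", "pre2008", "post2008") %in% tab$stratum))
  expect_equal(sum(tab$k[tab$stratifier == "era"]), 50)
  # annualization: table values / 52 equal weekly pooled means exactly
  corr <- correct_estimates(fr$ebe, ts, fr)
  sel <- ts$arms$era == "pre2008"
  weekly <- pool_random_effects(corr$alpha_corr[sel],
                                corr$se_alpha_corr[sel])
  expect_equal(tab$alpha_corrected[tab$stratum == "pre2008"] / 52,
               weekly$mean)
  # single-stratum table row equals the direct pooled result
  over <- pool_random_effects(corr$alpha_corr * 52, corr$se_alpha_corr * 52)
  expect_equal(tab$alpha_corrected[tab$stratum == "Overall"], over$mean)
  expect_equal(tab$tau2_corrected[tab$stratum == "Overall"], over$tau2)
  # permuting arm order leaves the table unchanged (up to row order)
  set.seed(4)
  perm <- trial_set(ts$arms[sample(50), ], ts$observations,
                    ts$covariate_refs)
  fr2 <- fake_fit(final_model_parameters())
  fr2$ebe <- empirical_bayes(perm, fr2)
  tab2 <- subgroup_table(perm, fr2, strata = "era")
  m <- match(paste(tab$stratifier, tab$stratum),
             paste(tab2$stratifier, tab2$stratum))
  expect_equal(tab2$alpha_corrected[m], tab$alpha_corrected)
})

test_that("a built-in regional rate deficit survives covariate correction", {
  hits <- 0
  for (k in 1:8) {
    cfg <- default_config(n_studies = 120, seed = 500 + k)
    cfg$region_alpha_mult[["EastAsia"]] <- 0.93
    cfg$region_probs <- c(International = 0.35, NorthAmerica = 0.25,
                          EuropeOceania = 0.10, EastAsia = 0.24,
                          MiddleAsia = 0.03, SouthAmerica = 0.03)
    sim <- generate_trial_set(cfg)
    fr <- fake_fit(final_model_parameters())
    fr$ebe <- empirical_bayes(sim$trial_set, fr)
    tab <- subgroup_table(sim$trial_set, fr, strata = "region")
    ea <- tab$alpha_corrected[tab$stratum == "EastAsia"]
    intl <- tab$alpha_corrected[tab$stratum == "International"]
    if (length(ea) && length(intl) && ea < intl) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("typical time courses hit the published six-month values", {
  ea <- typical_time_course(5.45, -2.43, et50 = 7.99, times = c(0, 26))
  na <- typical_time_course(6.11, -1.50, et50 = 7.99, times = c(0, 26))
  expect_equal(ea$typical[ea$time == 26], 0.866218, tolerance = 1e-6)
  expect_equal(round(ea$typical[ea$time == 26], 1), 0.9)
  expect_equal(na$typical[na$time == 26], 1.907604, tolerance = 1e-6)
  expect_equal(round(na$typical[na$time == 26], 2), 1.91)
  # zero at t = 0 with a zero-width interval
  withci <- typical_time_course(5.45, -2.43, alpha_se = 0.26, beta_se = 0.52,
                                times = c(0, 26), seed = 2)
  expect_identical(withci$typical[1], 0)
  expect_identical(withci$lower[1], 0)
  expect_identical(withci$upper[1], 0)
  expect_lt(withci$lower[2], withci$typical[2])
  expect_gt(withci$upper[2], withci$typical[2])
})
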