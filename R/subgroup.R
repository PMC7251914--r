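# Two-step subgroup analysis: per-study empirical-Bayes estimates are
# rescaled to the reference covariate profile ("covariate-corrected", so
# strata become comparable), then pooled per stratum by a random-effects
# meta-analysis of a single mean.

#' Covariate-corrected per-study estimates
#'
#' Rescales each study's empirical-Bayes parameter estimate to the
#' reference covariate profile by dividing out that study's covariate
#' factor: `alpha_star_i = alpha_i / prod(factors_i)`; standard errors
#' scale by the same factor. Parameters without covariates in the model
#' (here `beta`) pass through unchanged. Studies whose covariate factor is
#' non-positive or undefined are flagged in the `flagged` column.
#'
#' @param ebe Empirical-Bayes table from [empirical_bayes()] (taken from
#'   `fr$ebe` when `NULL`).
#' @param ts The fitted [trial_set()].
#' @param fr A converged `fit_result` whose spec includes the covariate
#'   factors to invert.
#' @return `ebe` augmented with `alpha_corr`, `se_alpha_corr`,
#'   `beta_corr`, `se_beta_corr`, `flagged`.
#' @export
correct_estimates <- function(ebe = NULL, ts, fr) {
  if (is.null(ebe)) ebe <- fr$ebe
  p <- fr$estimates
  arms <- ts$arms[match(ebe$study_id, ts$arms$study_id), , drop = FALSE]
  fac <- tryCatch(covariate_factors(p, arms), error = function(e) NULL)
  if (is.null(fac)) stop("covariate factors undefined for this trial set")
  fa <- rep(fac$alpha, length.out = nrow(ebe))
  fb <- rep(fac$beta, length.out = nrow(ebe))
  flagged <- !is.finite(fa) | fa <= 0 | !is.finite(fb) | fb <= 0
  fa[flagged] <- NA_real_
  fb[flagged] <- NA_real_
  ebe$alpha_corr <- ebe$alpha_i / fa
  ebe$se_alpha_corr <- ebe$se_alpha_i / fa
  ebe$beta_corr <- ebe$beta_i / fb
  ebe$se_beta_corr <- ebe$se_beta_i / fb
  ebe$flagged <- flagged
  ebe
}

#' Random-effects pooling of a single mean
#'
#' DerSimonian-Laird between-study variance with inverse-variance weights
#' `1/(SE^2 + tau^2)` and a Wald 95% CI. A single estimate pools to itself
#' with `tau^2 = 0`.
#'
#' @param values Numeric vector of per-study estimates.
#' @param ses Positive standard errors, same length.
#' @param method `"DL"` (DerSimonian-Laird) or `"REML"`.
#' @return List: `mean`, `ci_lower`, `ci_upper`, `se`, `tau2`, `k`.
#' @export
pool_random_effects <- function(values, ses, method = c("DL", "REML")) {
  method <- match.arg(method)
  stopifnot(length(values) >= 1, length(values) == length(ses),
            all(ses > 0))
  if (length(values) == 1) {
    return(list(mean = values, ci_lower = values - 1.96 * ses,
                ci_upper = values + 1.96 * ses, se = ses, tau2 = 0, k = 1L))
  }
  r <- metafor::rma(yi = values, sei = ses, method = method)
  list(mean = as.numeric(r$b), ci_lower = r$ci.lb, ci_upper = r$ci.ub,
       se = r$se, tau2 = r$tau2, k = r$k)
}

#' Subgroup table of progression rate and placebo extent
#'
#' For each requested stratifier (publication era, add-on design, region)
#' and for the overall set, pools the uncorrected progression rate, the
#' covariate-corrected progression rate (both annualized, points/year) and
#' the maximum placebo extent (points, uncorrected: no covariate entered
#' the model on `beta`) across the studies in each stratum. Empty strata
#' are omitted and listed in the `"omitted"` attribute.
#'
#' @param ts A [trial_set()].
#' @param fr A converged `fit_result`.
#' @param strata Character vector of arm columns to stratify by.
#' @param method Pooling method, see [pool_random_effects()].
#' @return Data frame, one row per (stratifier, stratum) plus `"Overall"`,
#'   with pooled means and 95% CIs for the three quantities and the
#'   between-study `tau2` of the corrected rate.
#' @export
subgroup_table <- function(ts, fr, strata = c("era", "add_on", "region"),
                           method = "DL") {
  corr <- correct_estimates(NULL, ts, fr)
  corr <- corr[!corr$flagged, , drop = FALSE]
  arms <- ts$arms[match(corr$study_id, ts$arms$study_id), , drop = FALSE]
  omitted <- character()
  pool_rows <- function(stratifier, stratum, sel) {
    if (!any(sel)) {
      omitted <<- c(omitted, paste(stratifier, stratum, sep = ":"))
      return(NULL)
    }
    u <- pool_random_effects(corr$alpha_i[sel] * 52,
                             corr$se_alpha_i[sel] * 52, method)
    a <- pool_random_effects(corr$alpha_corr[sel] * 52,
                             corr$se_alpha_corr[sel] * 52, method)
    b <- pool_random_effects(corr$beta_i[sel], corr$se_beta_i[sel], method)
    data.frame(stratifier = stratifier, stratum = stratum, k = u$k,
               alpha_uncorrected = u$mean, alpha_uncorrected_lo = u$ci_lower,
               alpha_uncorrected_hi = u$ci_upper,
               alpha_corrected = a$mean, alpha_corrected_lo = a$ci_lower,
               alpha_corrected_hi = a$ci_upper, alpha_corrected_se = a$se,
               tau2_corrected = a$tau2,
               beta = b$mean, beta_lo = b$ci_lower, beta_hi = b$ci_upper,
               beta_se = b$se, stringsAsFactors = FALSE)
  }
  rows <- list(pool_rows("overall", "Overall", rep(TRUE, nrow(corr))))
  for (v in strata) {
    col <- arms[[v]]
    if (is.null(col)) {
      omitted <- c(omitted, v)
      next
    }
    for (lev in unique(stats::na.omit(col)))
      rows[[length(rows) + 1]] <- pool_rows(v, as.character(lev),
                                            !is.na(col) & col == lev)
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Typical time course of the placebo response
#'
#' Deterministic typical curve `alpha * t + beta * t/(ET50 + t)` for a
#' stratum's pooled parameters, with a pointwise 95% CI propagated from
#' the pooled-mean standard errors by parametric draws (between-study
#' heterogeneity is not re-added; the band reflects uncertainty in the
#' stratum means).
#'
#' @param alpha_annual Pooled progression rate, points/year.
#' @param beta Pooled maximum placebo extent, points.
#' @param et50 Placebo half-time, weeks (global estimate).
#' @param alpha_se,beta_se Standard errors of the pooled means
#'   (`alpha_se` on the annual scale); zero gives a zero-width band.
#' @param horizon Simulation horizon, weeks.
#' @param times Evaluation times (default weekly grid to `horizon`).
#' @param n_draws Parametric draws for the CI.
#' @param seed RNG seed.
#' @return Data frame: `time`, `typical`, `lower`, `upper`.
#' @export
typical_time_course <- function(alpha_annual, beta, et50 = 7.99,
                                alpha_se = 0, beta_se = 0, horizon = 104,
                                times = NULL, n_draws = 2000, seed = 1L) {
  stopifnot(horizon > 0)
  if (is.null(times)) times <- seq(0, horizon, by = 1)
  p <- population_parameters(alpha = alpha_annual / 52, beta = beta,
                             et50 = et50)
  typ <- structural_response(times, p$alpha, p$beta, p)
  if (alpha_se > 0 || beta_se > 0) {
    draws <- with_seed(seed, {
      a <- stats::rnorm(n_draws, alpha_annual / 52, alpha_se / 52)
      b <- stats::rnorm(n_draws, beta, beta_se)
      vapply(times, function(tt)
        stats::quantile(structural_response(tt, a, b, p),
                        probs = c(0.025, 0.975), names = FALSE),
        numeric(2))
    })
    lower <- draws[1, ]; upper <- draws[2, ]
  } else {
    lower <- upper <- typ
  }
  data.frame(time = times, typical = typ, lower = lower, upper = upper)
}
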