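#' Placebo-effect time course
#'
#' Evaluates the transient placebo component of the aggregate placebo
#' response at time `t` (weeks since randomization). The default Emax form
#' is `beta * t / (et50 + t)`: `beta` (points on the ADAS-cog scale,
#' negative = improvement) is the maximum extent of the placebo effect and
#' `et50` (weeks) the time at which half of it is reached. Alternative
#' shapes kept for structural-model selection:
#'
#' * `"sigmoid_emax"`: `beta * t^hill / (et50^hill + t^hill)`;
#' * `"exponential"`: `beta * (1 - exp(-k_onset * t))`;
#' * `"inverse_bateman"`: `beta * (exp(-k_offset*t) - exp(-k_onset*t))`
#'   rescaled so the extremum of the curve equals `beta`
#'   (requires `k_onset > k_offset > 0`; the effect washes out at late times).
#'
#' Every form satisfies `Pbo(0) = 0`.
#'
#' @param t Time in weeks, non-negative numeric vector.
#' @param beta Maximum placebo-effect extent in ADAS-cog points, or a
#'   [population_parameters()] object from which `beta`, `et50`, the form and
#'   any shape constants are taken.
#' @param et50 Half-maximal time in weeks (Emax / sigmoid Emax forms).
#' @param form One of `"emax"`, `"sigmoid_emax"`, `"exponential"`,
#'   `"inverse_bateman"`.
#' @param hill Hill coefficient (> 0), sigmoid Emax only.
#' @param k_onset,k_offset Onset/offset rate constants (per week),
#'   exponential and inverse-Bateman forms.
#' @return Numeric vector of placebo-effect values in ADAS-cog points.
#' @examples
#' placebo_effect(7.99, beta = -1.87, et50 = 7.99)  # half of -1.87
#' @export
placebo_effect <- function(t, beta, et50 = NULL, form = "emax",
                           hill = NULL, k_onset = NULL, k_offset = NULL) {
  if (inherits(beta, "population_parameters")) {
    p <- beta
    return(placebo_effect(t, beta = p$beta, et50 = p$et50,
                          form = p$placebo_form, hill = p$hill,
                          k_onset = p$k_onset, k_offset = p$k_offset))
  }
  stopifnot(is.numeric(t), all(t >= 0))
  unit <- placebo_unit(t, et50 = et50, form = form, hill = hill,
                       k_onset = k_onset, k_offset = k_offset)
  beta * unit
}

# Placebo curve normalized so beta multiplies it (unit extremum); shared by
# the likelihood machinery, where it is the dPbo/dbeta design column.
placebo_unit <- function(t, et50 = NULL, form = "emax", hill = NULL,
                         k_onset = NULL, k_offset = NULL) {
  switch(form,
    emax = {
      if (is.null(et50) || et50 <= 0) stop("emax form requires et50 > 0")
      t / (et50 + t)
    },
    sigmoid_emax = {
      if (is.null(et50) || et50 <= 0) stop("sigmoid_emax form requires et50 > 0")
      if (is.null(hill) || hill <= 0) stop("sigmoid_emax form requires hill > 0")
      th <- t^hill
      th / (et50^hill + th)
    },
    exponential = {
      if (is.null(k_onset) || k_onset <= 0)
        stop("exponential form requires k_onset > 0")
      1 - exp(-k_onset * t)
    },
    inverse_bateman = {
      if (is.null(k_onset) || is.null(k_offset) ||
          !(k_onset > k_offset) || k_offset <= 0)
        stop("inverse_bateman form requires k_onset > k_offset > 0")
      tmax <- log(k_onset / k_offset) / (k_onset - k_offset)
      norm <- exp(-k_offset * tmax) - exp(-k_onset * tmax)
      (exp(-k_offset * t) - exp(-k_onset * t)) / norm
    },
    stop("unknown placebo form: ", form)
  )
}

#' Structural placebo-response model
#'
#' The aggregate placebo response (mean change from baseline in ADAS-cog)
#' decomposes into linear disease progression and a transient placebo
#' effect: `S(t) = alpha_i * t + Pbo(t)`. `alpha_i` is the study-level
#' progression rate in points/week (annualize with `* 52`) and `beta_i`
#' the study-level maximum placebo extent.
#'
#' @param t Time in weeks, non-negative.
#' @param alpha_i Disease-progression slope, points/week.
#' @param beta_i Maximum placebo extent, points.
#' @param p A [population_parameters()] object supplying the placebo form
#'   and its shape constants (`et50`, `hill`, rate constants).
#' @return Predicted mean change from baseline, points.
#' @examples
#' p <- population_parameters(alpha = 0.112, beta = -1.87, et50 = 7.99)
#' structural_response(26, alpha_i = 6.11 / 52, beta_i = -1.50, p = p)
#' @export
structural_response <- function(t, alpha_i, beta_i, p) {
  alpha_i * t + beta_i * placebo_unit(t, et50 = p$et50, form = p$placebo_form,
                                      hill = p$hill, k_onset = p$k_onset,
                                      k_offset = p$k_offset)
}

#' Covariate multiplier functions
#'
#' Multiplicative covariate factors applied to a typical parameter value,
#' each normalized to 1 exactly at the reference covariate value:
#'
#' * `"power"`: `(value/ref)^theta`;
#' * `"linear"`: `1 + theta * (value/ref - 1)`;
#' * `"inverse_u"`: `((value/ref) * (scale_max - value)/(scale_max - ref))^theta`,
#'   the bounded-scale form used for the baseline ADAS-cog effect on the
#'   progression rate. Its kernel `value * (scale_max - value)` peaks at
#'   `scale_max/2`, encoding fastest progression at mid-scale severity.
#'
#' @param value Covariate value(s), in the covariate's units.
#' @param ref Reference value (same units); factors equal 1 there.
#' @param theta Dimensionless exponent (power, inverse-U) or slope (linear).
#' @param form `"power"`, `"linear"` or `"inverse_u"`.
#' @param scale_max Ceiling of the bounded scale for `"inverse_u"`;
#'   70 for the 11-item ADAS-cog.
#' @param covariate Optional name used in error messages.
#' @return Dimensionless multiplicative factor(s).
#' @examples
#' # a 60-year-old population progresses ~1.87x as fast as an 80-year-old one
#' covariate_multiplier(60, 73.5, -2.17, "power") /
#'   covariate_multiplier(80, 73.5, -2.17, "power")
#' @export
covariate_multiplier <- function(value, ref, theta,
                                 form = c("power", "linear", "inverse_u"),
                                 scale_max = 70, covariate = "covariate") {
  form <- match.arg(form)
  if (form %in% c("power", "inverse_u") && any(value <= 0))
    stop(covariate, ": power/inverse_u forms require value > 0")
  if (form == "inverse_u") {
    if (any(value >= scale_max) || ref <= 0 || ref >= scale_max)
      stop(covariate, ": inverse_u requires 0 < value, ref < scale_max")
    return(((value / ref) * (scale_max - value) / (scale_max - ref))^theta)
  }
  if (form == "power") return((value / ref)^theta)
  1 + theta * (value / ref - 1)
}

#' Map population parameters and random effects to study-level parameters
#'
#' Study-level parameters follow a proportional random-effect model so the
#' study value can change sign (worsening vs nocebo-like behaviour):
#' `alpha_i = alpha_typ * prod(covariate factors) * (1 + eta_alpha)` and
#' `beta_i = beta_typ * prod(covariate factors) * (1 + eta_beta)`.
#' Covariate factors multiply the typical value before the `(1 + eta)`
#' perturbation, so `eta = 0` gives the typical covariate-adjusted value.
#'
#' @param p A [population_parameters()] object; its `covariate_model` and
#'   `theta` define which factors apply to which parameter.
#' @param eta Length-2 numeric `(eta_alpha, eta_beta)`.
#' @param covariates Named list/vector with an entry for every covariate
#'   named in `p$covariate_model`.
#' @return Named numeric vector `c(alpha_i, beta_i)`.
#' @examples
#' p <- final_model_parameters()
#' individual_parameters(p, c(0, 0),
#'                       list(baseline_adas = 24.5, baseline_age = 73.5))
#' @export
individual_parameters <- function(p, eta = c(0, 0), covariates = list()) {
  stopifnot(length(eta) == 2)
  fac <- covariate_factors(p, covariates)
  c(alpha_i = p$alpha * fac[["alpha"]] * (1 + eta[[1]]),
    beta_i  = p$beta  * fac[["beta"]]  * (1 + eta[[2]]))
}

# Product of covariate multipliers on each structural parameter.
# `covariates` may be a named list (scalars) or data.frame (vectorized).
covariate_factors <- function(p, covariates) {
  cm <- p$covariate_model
  out <- list(alpha = 1, beta = 1)
  if (is.null(cm) || nrow(cm) == 0) return(out)
  for (k in seq_len(nrow(cm))) {
    cov_name <- cm$covariate[k]
    if (is.null(covariates[[cov_name]]))
      stop("missing covariate: ", cov_name)
    th_name <- cm$theta_name[k]
    f <- covariate_multiplier(covariates[[cov_name]], ref = cm$ref[k],
                              theta = p$theta[[th_name]], form = cm$form[k],
                              scale_max = p$scale_max, covariate = cov_name)
    tgt <- cm$parameter[k]
    out[[tgt]] <- out[[tgt]] * f
  }
  out
}

#' Residual standard deviation of an aggregate observation
#'
#' The additive residual on a reported mean change is weighted by the
#' inverse square root of the per-time-point analyzed sample size:
#' `sd = delta / sqrt(n)`, where `delta` is the residual SD on the
#' single-subject scale (points).
#'
#' @param delta Residual SD, points (> 0).
#' @param n Analyzed sample size at the time point (>= 1).
#' @return Standard deviation of the reported mean change, points.
#' @export
residual_sd <- function(delta, n) {
  stopifnot(delta > 0, all(n >= 1))
  delta / sqrt(n)
}
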