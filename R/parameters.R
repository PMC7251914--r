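#' Population parameters of the disease-progression model
#'
#' Container for the fixed effects, covariate coefficients, and variance
#' components of the aggregate placebo-response model.
#'
#' @param alpha Typical disease-progression rate, points/week.
#' @param beta Typical maximum placebo-effect extent, points
#'   (negative = transient improvement).
#' @param et50 Placebo-effect half-time, weeks (Emax / sigmoid Emax).
#' @param placebo_form One of `"emax"`, `"sigmoid_emax"`, `"exponential"`,
#'   `"inverse_bateman"`.
#' @param hill Hill coefficient (sigmoid Emax only).
#' @param k_onset,k_offset Rate constants per week (exponential /
#'   inverse-Bateman forms).
#' @param covariate_model Data frame describing covariate effects, as built
#'   by [covariate_effect()]; may be `NULL`.
#' @param theta Named numeric vector of covariate coefficients; names must
#'   match `covariate_model$theta_name`.
#' @param omega_alpha,omega_beta Inter-study SDs of the proportional random
#'   effects on `alpha` and `beta` (dimensionless; 0.148 means 14.8%).
#' @param rho Correlation of the two random effects, in `[-1, 1]`.
#' @param delta Residual SD on the single-subject scale, points.
#' @param scale_max Ceiling of the outcome scale used by inverse-U
#'   covariate factors (70 for ADAS-cog 11).
#' @return An object of class `population_parameters`.
#' @seealso [final_model_parameters()] for the published estimates.
#' @export
population_parameters <- function(alpha, beta, et50 = NULL,
                                  placebo_form = "emax",
                                  hill = NULL, k_onset = NULL, k_offset = NULL,
                                  covariate_model = NULL, theta = numeric(),
                                  omega_alpha = 0, omega_beta = 0, rho = 0,
                                  delta = 1, scale_max = 70) {
  p <- structure(list(
    alpha = alpha, beta = beta, et50 = et50, placebo_form = placebo_form,
    hill = hill, k_onset = k_onset, k_offset = k_offset,
    covariate_model = covariate_model, theta = theta,
    omega_alpha = omega_alpha, omega_beta = omega_beta, rho = rho,
    delta = delta, scale_max = scale_max), class = "population_parameters")
  validate_population_parameters(p)
  p
}

validate_population_parameters <- function(p) {
  if (p$placebo_form %in% c("emax", "sigmoid_emax") &&
      (is.null(p$et50) || p$et50 <= 0))
    stop("et50 must be > 0")
  if (p$delta < 0) stop("delta must be >= 0")
  if (p$omega_alpha < 0 || p$omega_beta < 0) stop("omega SDs must be >= 0")
  if (abs(p$rho) > 1) stop("|rho| must be <= 1")
  if (!is.null(p$hill) && p$hill <= 0) stop("hill must be > 0")
  cm <- p$covariate_model
  if (!is.null(cm) && nrow(cm) > 0 &&
      !all(cm$theta_name %in% names(p$theta)))
    stop("theta must carry a named entry for every covariate effect")
  invisible(p)
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("Population parameters (", x$placebo_form, " placebo model)\n", sep = "")
  cat(sprintf("  alpha %.4g pts/week (%.3g pts/year)   beta %.4g pts\n",
              x$alpha, x$alpha * 52, x$beta))
  if (!is.null(x$et50)) cat(sprintf("  ET50 %.4g weeks\n", x$et50))
  if (length(x$theta))
    cat("  theta:", paste(sprintf("%s=%.3g", names(x$theta), x$theta),
                          collapse = ", "), "\n")
  cat(sprintf("  omega_alpha %.3g  omega_beta %.3g  rho %.3g  delta %.3g\n",
              x$omega_alpha, x$omega_beta, x$rho, x$delta))
  invisible(x)
}

#' Declare a covariate effect on a structural parameter
#'
#' @param covariate Column name of the study-level covariate
#'   (e.g. `"baseline_adas"`, `"baseline_age"`).
#' @param parameter Structural parameter the factor multiplies:
#'   `"alpha"` or `"beta"`.
#' @param form Functional form, see [covariate_multiplier()].
#' @param ref Reference value; `NA` means "resolve from the trial set's
#'   `covariate_refs` at fit time".
#' @return One-row data frame; rows from several calls can be `rbind`-ed
#'   into a covariate model table.
#' @export
covariate_effect <- function(covariate, parameter = c("alpha", "beta"),
                             form = c("power", "linear", "inverse_u"),
                             ref = NA_real_) {
  parameter <- match.arg(parameter)
  form <- match.arg(form)
  data.frame(covariate = covariate, parameter = parameter, form = form,
             ref = ref,
             theta_name = paste(parameter, covariate, form, sep = "."),
             stringsAsFactors = FALSE)
}

#' Published estimates of the final disease-progression model
#'
#' Typical progression rate 0.112 points/week (5.82 points/year at the
#' reference profile of age 73.5 years and baseline ADAS-cog 24.5), maximum
#' placebo extent -1.87 points with half-time 7.99 weeks, an inverse-U
#' baseline-ADAS factor (theta 1.53) and a power age factor (theta -2.17)
#' on the progression rate, inter-study SDs 14.8% (alpha) and 72.5% (beta)
#' with correlation -0.717, and residual SD 5.64 points.
#'
#' @param adas_ref,age_ref Reference covariate values.
#' @return A [population_parameters()] object.
#' @export
final_model_parameters <- function(adas_ref = 24.5, age_ref = 73.5) {
  cm <- rbind(covariate_effect("baseline_adas", "alpha", "inverse_u", adas_ref),
              covariate_effect("baseline_age", "alpha", "power", age_ref))
  population_parameters(
    alpha = 0.112, beta = -1.87, et50 = 7.99, placebo_form = "emax",
    covariate_model = cm,
    theta = c(alpha.baseline_adas.inverse_u = 1.53,
              alpha.baseline_age.power = -2.17),
    omega_alpha = 0.148, omega_beta = 0.725, rho = -0.717, delta = 5.64)
}

#' Model specification for fitting
#'
#' Describes which structural form, covariate effects and variance
#' components a fit should estimate. Random effects are always the
#' bivariate proportional pair on (`alpha`, `beta`); the half-time and any
#' shape constants carry no inter-study variability (their empirical-Bayes
#' shrinkage is essentially complete in designs of this kind, so their
#' variance is fixed at 0).
#'
#' @param placebo_form Structural placebo form, see [placebo_effect()].
#' @param covariate_model Covariate table from [covariate_effect()] rows,
#'   or `NULL` for the base (covariate-free) model.
#' @param estimate_iiv Logical: estimate the 2x2 inter-study covariance?
#'   `FALSE` fixes both omegas at 0 (fixed-effects fit).
#' @param scale_max Outcome-scale ceiling for inverse-U factors.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(placebo_form = "emax", covariate_model = NULL,
                       estimate_iiv = TRUE, scale_max = 70) {
  if (!is.null(covariate_model) && nrow(covariate_model) == 0)
    covariate_model <- NULL
  if (!is.null(covariate_model)) {
    key <- paste(covariate_model$parameter, covariate_model$covariate)
    if (anyDuplicated(key))
      stop("duplicate covariate effect on the same parameter")
  }
  structure(list(placebo_form = placebo_form,
                 covariate_model = covariate_model,
                 estimate_iiv = isTRUE(estimate_iiv),
                 scale_max = scale_max),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec: ", x$placebo_form, " placebo form, ",
      if (x$estimate_iiv) "bivariate IIV on (alpha, beta)" else "no IIV",
      "\n", sep = "")
  cm <- x$covariate_model
  if (!is.null(cm))
    for (k in seq_len(nrow(cm)))
      cat(sprintf("  %s on %s (%s)\n", cm$covariate[k], cm$parameter[k],
                  cm$form[k]))
  invisible(x)
}

#' @rdname model_spec
#' @details `base_model_spec()` is the covariate-free Emax model;
#'   `final_model_spec()` carries the published covariate structure
#'   (inverse-U baseline ADAS-cog and power age, both on `alpha`).
#' @export
base_model_spec <- function(placebo_form = "emax") {
  model_spec(placebo_form = placebo_form)
}

#' @rdname model_spec
#' @export
final_model_spec <- function() {
  model_spec(
    placebo_form = "emax",
    covariate_model = rbind(
      covariate_effect("baseline_adas", "alpha", "inverse_u"),
      covariate_effect("baseline_age", "alpha", "power")))
}
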