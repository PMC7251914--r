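# Marginal-likelihood machinery for the aggregate disease-progression model.
#
# Each study contributes a small vector of mean changes y with additive
# residual sd delta/sqrt(n), and a bivariate proportional random effect
# eta = (eta_alpha, eta_beta). Because eta enters only through
# (1 + eta) factors on alpha and beta, the conditional mean is linear in
# eta: F(eta) = f0 + Z eta with Z1 = alpha_typ*C_i*t and
# Z2 = beta_typ*C_i*Pbo_unit(t). The Laplace approximation therefore uses a
# single exact Newton step to land on the conditional mode and is the exact
# Gaussian marginal; the adaptive Gauss-Hermite method re-derives the same
# integral by generic tensor quadrature and serves as an oracle in tests.

# ---- parameter transforms ---------------------------------------------------

par_names <- function(spec) {
  shape <- switch(spec$placebo_form,
                  emax = "log_et50",
                  sigmoid_emax = c("log_et50", "log_hill"),
                  exponential = "log_k_onset",
                  inverse_bateman = c("log_k_offset", "log_dk"),
                  stop("unknown placebo form: ", spec$placebo_form))
  nm <- c("alpha", "beta", shape)
  cm <- spec$covariate_model
  if (!is.null(cm)) nm <- c(nm, cm$theta_name)
  if (spec$estimate_iiv) nm <- c(nm, "l11", "l21", "l22")
  c(nm, "log_delta")
}

# transformed vector -> population_parameters (refs already resolved in spec)
unpack_params <- function(par, spec) {
  nm <- par_names(spec)
  names(par) <- nm
  et50 <- hill <- k_on <- k_off <- NULL
  if (spec$placebo_form %in% c("emax", "sigmoid_emax"))
    et50 <- exp(par[["log_et50"]])
  if (spec$placebo_form == "sigmoid_emax") hill <- exp(par[["log_hill"]])
  if (spec$placebo_form == "exponential") k_on <- exp(par[["log_k_onset"]])
  if (spec$placebo_form == "inverse_bateman") {
    k_off <- exp(par[["log_k_offset"]])
    k_on <- k_off + exp(par[["log_dk"]])
  }
  cm <- spec$covariate_model
  theta <- if (is.null(cm)) numeric() else {
    th <- par[cm$theta_name]
    names(th) <- cm$theta_name
    th
  }
  if (spec$estimate_iiv) {
    L11 <- exp(par[["l11"]]); L21 <- par[["l21"]]; L22 <- exp(par[["l22"]])
    omega_alpha <- L11
    omega_beta <- sqrt(L21^2 + L22^2)
    rho <- L21 / omega_beta
  } else {
    omega_alpha <- omega_beta <- rho <- 0
  }
  population_parameters(
    alpha = par[["alpha"]], beta = par[["beta"]], et50 = et50,
    placebo_form = spec$placebo_form, hill = hill,
    k_onset = k_on, k_offset = k_off,
    covariate_model = cm, theta = theta,
    omega_alpha = omega_alpha, omega_beta = omega_beta, rho = rho,
    delta = exp(par[["log_delta"]]), scale_max = spec$scale_max)
}

pack_params <- function(p, spec) {
  par <- c(alpha = p$alpha, beta = p$beta)
  par <- switch(spec$placebo_form,
    emax = c(par, log_et50 = log(p$et50)),
    sigmoid_emax = c(par, log_et50 = log(p$et50), log_hill = log(p$hill)),
    exponential = c(par, log_k_onset = log(p$k_onset)),
    inverse_bateman = c(par, log_k_offset = log(p$k_offset),
                        log_dk = log(p$k_onset - p$k_offset)))
  cm <- spec$covariate_model
  if (!is.null(cm)) {
    th <- p$theta[cm$theta_name]
    names(th) <- cm$theta_name
    par <- c(par, th)
  }
  if (spec$estimate_iiv) {
    L <- chol_omega(max(p$omega_alpha, 1e-4), max(p$omega_beta, 1e-4), p$rho)
    par <- c(par, l11 = log(L[1, 1]), l21 = L[2, 1], l22 = log(L[2, 2]))
  }
  c(par, log_delta = log(p$delta))
}

# natural-scale view used for reporting and delta-method SEs
natural_params <- function(par, spec) {
  p <- unpack_params(par, spec)
  out <- c(alpha = p$alpha, beta = p$beta)
  if (!is.null(p$et50)) out <- c(out, et50 = p$et50)
  if (!is.null(p$hill)) out <- c(out, hill = p$hill)
  if (!is.null(p$k_onset)) out <- c(out, k_onset = p$k_onset)
  if (!is.null(p$k_offset)) out <- c(out, k_offset = p$k_offset)
  out <- c(out, p$theta)
  if (spec$estimate_iiv)
    out <- c(out, omega_alpha = p$omega_alpha, omega_beta = p$omega_beta,
             rho = p$rho)
  c(out, delta = p$delta)
}

# ---- likelihood data --------------------------------------------------------

# resolve NA covariate refs in a spec against the trial set's reference map
resolve_spec <- function(spec, ts) {
  cm <- spec$covariate_model
  if (!is.null(cm)) {
    for (k in seq_len(nrow(cm))) {
      if (is.na(cm$ref[k])) {
        ref <- ts$covariate_refs[[cm$covariate[k]]]
        if (is.null(ref)) stop("no reference value for ", cm$covariate[k])
        cm$ref[k] <- ref
      }
    }
    spec$covariate_model <- cm
  }
  spec
}

likelihood_data <- function(ts) {
  a <- ts$arms
  o <- ts$observations
  idx <- match(o$study_id, a$study_id)
  if (anyNA(idx)) stop("observations reference unknown study ids")
  m <- as.integer(table(factor(idx, levels = seq_len(nrow(a)))))
  if (any(m == 0)) stop("every arm needs at least one observation")
  list(t = o$time, y = o$mean_change, n = o$n, study = idx, arms = a,
       n_studies = nrow(a), n_obs = nrow(o), obs_per_study = m,
       sum_log_n = as.vector(rowsum(log(o$n), idx)))
}

# ---- public likelihood ------------------------------------------------------

#' Objective function value (-2 log approximate marginal likelihood)
#'
#' Integrates the bivariate study-level random effects out of the
#' likelihood. `"laplace"` (and its alias `"foce"`: with a purely additive
#' residual the interaction term of FOCE-I vanishes, making the two
#' equivalent here) expands about the conditional mode of `eta`; since the
#' conditional model is linear in `eta` the expansion is exact.
#' `"agq"` is a generic adaptive Gauss-Hermite tensor quadrature
#' (`agq_nodes` points per dimension) used as an independent numerical
#' oracle. With both inter-study SDs equal to zero the value reduces to
#' the weighted least-squares deviance
#' `sum((y - F)^2 * n / delta^2 + log(2*pi*delta^2/n))`.
#'
#' The returned value keeps the full -2 log-likelihood constant (the
#' 2*pi terms are not dropped); model comparisons use differences, so the
#' convention is harmless and is recorded in fit results.
#'
#' @param ts A [trial_set()].
#' @param p [population_parameters()] at which to evaluate.
#' @param spec [model_spec()] describing form and covariates.
#' @param method `"laplace"`, `"foce"` or `"agq"`.
#' @param agq_nodes Quadrature nodes per dimension (>= 9 recommended).
#' @return The objective function value (scalar).
#' @export
neg2ll <- function(ts, p, spec = NULL,
                   method = c("laplace", "foce", "agq"), agq_nodes = 15) {
  method <- match.arg(method)
  if (is.null(spec))
    spec <- model_spec(p$placebo_form, p$covariate_model,
                       estimate_iiv = p$omega_alpha > 0 || p$omega_beta > 0,
                       scale_max = p$scale_max)
  spec <- resolve_spec(spec, ts)
  if (p$delta <= 0) stop("delta must be > 0 for likelihood evaluation")
  ld <- likelihood_data(ts)
  if (method == "agq") return(neg2ll_agq(p, spec, ld, agq_nodes))
  p$covariate_model <- spec$covariate_model  # refs resolved against ts
  laplace_kernel(p, ld)$ofv
}

# vectorized Laplace kernel (exact Newton inner step; see file header) --
# operates on a population_parameters object, including exact-zero omegas
laplace_kernel <- function(p, ld) {
  fac <- covariate_factors(p, ld$arms)
  Ca <- rep(fac$alpha, length.out = ld$n_studies)
  Cb <- rep(fac$beta, length.out = ld$n_studies)
  unit <- placebo_unit(ld$t, et50 = p$et50, form = p$placebo_form,
                       hill = p$hill, k_onset = p$k_onset,
                       k_offset = p$k_offset)
  Z1 <- (p$alpha * Ca)[ld$study] * ld$t
  Z2 <- (p$beta * Cb)[ld$study] * unit
  r0 <- ld$y - Z1 - Z2
  w <- ld$n / p$delta^2
  S <- rowsum(cbind(w * Z1 * Z1, w * Z1 * Z2, w * Z2 * Z2,
                    w * Z1 * r0, w * Z2 * r0, w * r0 * r0), ld$study)
  S11 <- S[, 1]; S12 <- S[, 2]; S22 <- S[, 3]
  b1 <- S[, 4]; b2 <- S[, 5]; Srr <- S[, 6]
  loggauss <- ld$obs_per_study * log(2 * pi * p$delta^2) - ld$sum_log_n
  wa <- p$omega_alpha > 0
  wb <- p$omega_beta > 0
  eta1 <- eta2 <- rep(0, ld$n_studies)
  v11 <- v12 <- v22 <- rep(0, ld$n_studies)
  if (wa && wb) {
    det_om <- (p$omega_alpha * p$omega_beta)^2 * (1 - p$rho^2)
    if (det_om <= 0) return(list(ofv = Inf))
    oi11 <- p$omega_beta^2 / det_om
    oi22 <- p$omega_alpha^2 / det_om
    oi12 <- -p$rho * p$omega_alpha * p$omega_beta / det_om
    H11 <- S11 + oi11; H12 <- S12 + oi12; H22 <- S22 + oi22
    detH <- H11 * H22 - H12^2
    eta1 <- (H22 * b1 - H12 * b2) / detH
    eta2 <- (H11 * b2 - H12 * b1) / detH
    v11 <- H22 / detH; v22 <- H11 / detH; v12 <- -H12 / detH
    ofv_i <- loggauss + Srr - (b1 * eta1 + b2 * eta2) +
      log(det_om) + log(detH)
  } else if (wa || wb) {
    om2 <- if (wa) p$omega_alpha^2 else p$omega_beta^2
    Skk <- if (wa) S11 else S22
    bk <- if (wa) b1 else b2
    H <- Skk + 1 / om2
    ek <- bk / H
    if (wa) { eta1 <- ek; v11 <- 1 / H } else { eta2 <- ek; v22 <- 1 / H }
    ofv_i <- loggauss + Srr - bk * ek + log(om2) + log(H)
  } else {
    ofv_i <- loggauss + Srr
  }
  list(ofv = sum(ofv_i), ofv_i = ofv_i, eta = cbind(eta1, eta2),
       cond_var = cbind(v11, v12, v22),
       alpha_typ_i = p$alpha * Ca, beta_typ_i = p$beta * Cb, p = p)
}

# generic adaptive Gauss-Hermite quadrature: per-study numeric inner mode
# search + tensor-grid integration of the conditional density, independent
# of the linear-algebra shortcut used by the Laplace path
neg2ll_agq <- function(p, spec, ld, k = 15) {
  gh <- pracma::gaussHermite(k)
  om <- c(p$omega_alpha, p$omega_beta)
  active <- which(om > 0)
  Sig <- chol_omega(p$omega_alpha, p$omega_beta, p$rho)
  Sig <- Sig %*% t(Sig)
  total <- 0
  for (i in seq_len(ld$n_studies)) {
    sel <- ld$study == i
    ti <- ld$t[sel]; yi <- ld$y[sel]; ni <- ld$n[sel]
    covs <- as.list(ld$arms[i, , drop = FALSE])
    cond_m2ll <- function(eta2) {
      ind <- individual_parameters(p, eta2, covs)
      f <- structural_response(ti, ind[["alpha_i"]], ind[["beta_i"]], p)
      sum((yi - f)^2 * ni / p$delta^2 + log(2 * pi * p$delta^2 / ni))
    }
    if (length(active) == 0) {
      total <- total + cond_m2ll(c(0, 0))
      next
    }
    Sa <- Sig[active, active, drop = FALSE]
    Sa_inv <- solve(Sa)
    q <- length(active)
    g <- function(ea) {
      eta2 <- c(0, 0); eta2[active] <- ea
      0.5 * cond_m2ll(eta2) + 0.5 * drop(ea %*% Sa_inv %*% ea) +
        0.5 * (q * log(2 * pi) + determinant(Sa)$modulus[1])
    }
    opt <- stats::nlminb(rep(0, q), g)
    if (!is.finite(opt$objective))
      stop("non-finite inner mode search for study ", ld$arms$study_id[i])
    mode <- opt$par
    Hi <- pracma::hessian(g, mode)
    A <- t(chol(solve((Hi + t(Hi)) / 2)))
    if (q == 1) {
      zs <- matrix(gh$x, ncol = 1)
      lw <- log(gh$w)
    } else {
      grid <- expand.grid(gh$x, gh$x)
      zs <- as.matrix(grid)
      lw <- log(gh$w[rep(seq_len(k), times = k)]) +
        log(gh$w[rep(seq_len(k), each = k)])
    }
    vals <- vapply(seq_len(nrow(zs)), function(j) {
      z <- zs[j, ]
      ea <- mode + sqrt(2) * drop(A %*% z)
      -g(ea) + sum(z^2)
    }, numeric(1))
    lse <- max(vals + lw)
    log_int <- lse + log(sum(exp(vals + lw - lse))) +
      (q / 2) * log(2) + sum(log(diag(A)))
    total <- total - 2 * log_int
  }
  total
}

# ---- fitting ----------------------------------------------------------------

default_starts <- function(ld, spec) {
  wfit <- stats::lm(ld$y ~ 0 + ld$t, weights = ld$n)
  alpha0 <- unname(stats::coef(wfit)[1])
  if (!is.finite(alpha0) || alpha0 == 0) alpha0 <- 0.1
  early <- ld$t <= 16
  beta0 <- if (any(early)) {
    r <- ld$y[early] - alpha0 * ld$t[early]
    stats::weighted.mean(r, ld$n[early]) * 2  # unit(t) ~ 0.5 near ET50
  } else -1
  if (!is.finite(beta0) || beta0 == 0) beta0 <- -1
  res <- ld$y - alpha0 * ld$t - beta0 * ld$t / (8 + ld$t)
  delta0 <- sqrt(stats::weighted.mean(res^2 * ld$n, rep(1, length(res))))
  delta0 <- min(max(delta0, 0.5), 20)
  p0 <- c(alpha = alpha0, beta = beta0)
  p0 <- switch(spec$placebo_form,
    emax = c(p0, log_et50 = log(8)),
    sigmoid_emax = c(p0, log_et50 = log(8), log_hill = 0),
    exponential = c(p0, log_k_onset = log(log(2) / 8)),
    inverse_bateman = c(p0, log_k_offset = log(0.005), log_dk = log(0.08)))
  cm <- spec$covariate_model
  if (!is.null(cm)) {
    th <- rep(0, nrow(cm))
    names(th) <- cm$theta_name
    p0 <- c(p0, th)
  }
  if (spec$estimate_iiv)
    p0 <- c(p0, l11 = log(0.2), l21 = 0, l22 = log(0.5))
  c(p0, log_delta = log(delta0))
}

#' Fit the disease-progression model by approximate marginal likelihood
#'
#' Minimizes [neg2ll()] over transformed parameters (log for half-times,
#' rate constants, residual and random-effect scales; the 2x2 inter-study
#' covariance is parameterized by its Cholesky factor so it stays positive
#' semidefinite; atanh-free identity transforms for `alpha`, `beta` and the
#' covariate coefficients). Standard errors come from the finite-difference
#' observed-information Hessian, mapped to the natural scale by the delta
#' method; the random-effect correlation is reported without a standard
#' error. Empirical-Bayes estimates of the study-level effects are attached
#' to the result.
#'
#' @param ts A validated [trial_set()].
#' @param spec A [model_spec()].
#' @param starts Optional named start vector on the transformed scale
#'   (or a [population_parameters()] object).
#' @param n_restarts Number of multi-starts; restarts beyond the first
#'   jitter the starting values by factors up to x/÷3.
#' @param control `nlminb` control list (defaults: `iter.max = 500`,
#'   `rel.tol = 1e-6`).
#' @param compute_se Set `FALSE` to skip the Hessian (used by bootstrap
#'   replicates).
#' @return An object of class `fit_result`: `estimates`
#'   ([population_parameters()]), `par` (transformed optimum), `ofv`,
#'   `aic`, `n_par`, `converged`, `se`, `rse_percent`, `ci95`, `vcov`,
#'   `ebe` (per-study effects), `shrinkage`, and bookkeeping fields.
#' @export
fit_progression <- function(ts, spec = final_model_spec(), starts = NULL,
                            n_restarts = 1, control = list(),
                            compute_se = TRUE) {
  spec <- resolve_spec(spec, ts)
  ld <- likelihood_data(ts)
  ctrl <- utils::modifyList(list(iter.max = 500, eval.max = 2000,
                                 rel.tol = 1e-6), control)
  nm <- par_names(spec)
  par0 <- if (is.null(starts)) default_starts(ld, spec)
  else if (inherits(starts, "population_parameters")) pack_params(starts, spec)
  else starts
  if (length(par0) != length(nm))
    stop("starts must have ", length(nm), " parameters (",
         paste(nm, collapse = ", "), ")")
  fn <- function(par) {
    p <- tryCatch(unpack_params(par, spec), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- laplace_kernel(p, ld)$ofv
    if (!is.finite(v)) 1e10 else v
  }
  lower <- ifelse(grepl("^(log_|l11|l22)", nm), -12, -1e3)
  upper <- ifelse(grepl("^(log_|l11|l22)", nm), 12, 1e3)
  best <- NULL
  diagnostics <- list()
  for (r in seq_len(max(1, n_restarts))) {
    start_r <- par0
    if (r > 1) {
      # deterministic jitter pattern, x/÷3 max, independent of the global RNG
      u <- sin(seq_along(par0) * 1.7 + r * 2.3)
      start_r <- par0 + u * log(3) *
        ifelse(grepl("^(log_|l11|l22)", nm), 1, 0.3)
      start_r[nm == "alpha"] <- par0[nm == "alpha"] * 3^u[which(nm == "alpha")]
      start_r[nm == "beta"] <- par0[nm == "beta"] * 3^u[which(nm == "beta")]
    }
    opt <- tryCatch(
      stats::nlminb(start_r, fn, lower = lower, upper = upper,
                    control = ctrl),
      error = function(e) list(par = start_r, objective = Inf,
                               convergence = 1L, message = conditionMessage(e)))
    diagnostics[[r]] <- list(restart = r, objective = opt$objective,
                             convergence = opt$convergence,
                             message = opt$message)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  converged <- is.finite(best$objective) && best$objective < 1e10
  par_hat <- best$par
  names(par_hat) <- nm
  p_hat <- unpack_params(par_hat, spec)
  parts <- laplace_kernel(p_hat, ld)
  k_par <- length(par_hat)
  se <- rse <- rep(NA_real_, length(natural_params(par_hat, spec)))
  vcov_nat <- NULL
  nat <- natural_params(par_hat, spec)
  if (compute_se && converged) {
    H <- tryCatch(stats::optimHess(par_hat, fn), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
      if (!is.null(V) && all(is.finite(V))) {
        J <- pracma::jacobian(function(x) natural_params(x, spec), par_hat)
        vcov_nat <- J %*% V %*% t(J)
        dimnames(vcov_nat) <- list(names(nat), names(nat))
        dg <- diag(vcov_nat)
        se <- ifelse(dg >= 0, sqrt(dg), NA_real_)
        rse <- 100 * se / abs(nat)
        if ("rho" %in% names(nat)) {       # reported without an SE
          se[names(nat) == "rho"] <- NA_real_
          rse[names(nat) == "rho"] <- NA_real_
        }
      }
    }
  }
  names(se) <- names(rse) <- names(nat)
  ci <- cbind(lower = nat - 1.96 * se, upper = nat + 1.96 * se)
  ebe <- data.frame(study_id = ld$arms$study_id,
                    eta_alpha = parts$eta[, 1], eta_beta = parts$eta[, 2],
                    se_eta_alpha = sqrt(pmax(parts$cond_var[, 1], 0)),
                    se_eta_beta = sqrt(pmax(parts$cond_var[, 3], 0)),
                    alpha_i = parts$alpha_typ_i * (1 + parts$eta[, 1]),
                    beta_i = parts$beta_typ_i * (1 + parts$eta[, 2]),
                    stringsAsFactors = FALSE)
  ebe$se_alpha_i <- abs(parts$alpha_typ_i) * ebe$se_eta_alpha
  ebe$se_beta_i <- abs(parts$beta_typ_i) * ebe$se_eta_beta
  shrink <- c(alpha = NA_real_, beta = NA_real_)
  if (p_hat$omega_alpha > 0)
    shrink[["alpha"]] <- 1 - stats::sd(ebe$eta_alpha) / p_hat$omega_alpha
  if (p_hat$omega_beta > 0)
    shrink[["beta"]] <- 1 - stats::sd(ebe$eta_beta) / p_hat$omega_beta
  structure(list(estimates = p_hat, par = par_hat, spec = spec,
                 natural = nat, se = se, rse_percent = rse, ci95 = ci,
                 vcov = vcov_nat, ofv = best$objective,
                 aic = best$objective + 2 * k_par, n_par = k_par,
                 converged = converged, diagnostics = diagnostics,
                 ebe = ebe, shrinkage = shrink,
                 ofv_convention = "full -2 log-likelihood incl. 2*pi terms",
                 n_studies = ld$n_studies, n_obs = ld$n_obs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s placebo form): OFV %.3f, AIC %.3f, %s\n",
              x$spec$placebo_form, x$ofv, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  tab <- parameter_table(x)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parameter table of a fit (estimate, RSE%, 95% CI)
#'
#' @param fr A `fit_result`.
#' @return Data frame with one row per reported parameter.
#' @export
parameter_table <- function(fr) {
  data.frame(parameter = names(fr$natural),
             estimate = unname(fr$natural),
             rse_percent = unname(fr$rse_percent),
             ci_lower = unname(fr$ci95[, "lower"]),
             ci_upper = unname(fr$ci95[, "upper"]),
             stringsAsFactors = FALSE)
}

#' Serialize a fit result to JSON
#'
#' @param fr A `fit_result`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fr, path = NULL) {
  obj <- list(placebo_form = fr$spec$placebo_form,
              estimates = as.list(fr$natural),
              rse_percent = as.list(fr$rse_percent),
              ofv = fr$ofv, aic = fr$aic, n_par = fr$n_par,
              converged = fr$converged,
              ofv_convention = fr$ofv_convention,
              n_studies = fr$n_studies, n_obs = fr$n_obs,
              shrinkage = as.list(fr$shrinkage))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Empirical-Bayes estimates of the study-level parameters
#'
#' Per-study posterior modes of `(eta_alpha, eta_beta)` at the final
#' population estimates, mapped to study-level `(alpha_i, beta_i)` with
#' conditional-Hessian standard errors (delta method). The attribute
#' `"shrinkage"` carries `1 - SD(eta_hat)/omega` per effect.
#'
#' @param ts The fitted [trial_set()].
#' @param fr A converged `fit_result`.
#' @return Data frame, one row per study.
#' @export
empirical_bayes <- function(ts, fr) {
  if (!fr$converged) stop("fit did not converge")
  ld <- likelihood_data(ts)
  parts <- laplace_kernel(fr$estimates, ld)
  ebe <- data.frame(study_id = ld$arms$study_id,
                    eta_alpha = parts$eta[, 1], eta_beta = parts$eta[, 2],
                    se_eta_alpha = sqrt(pmax(parts$cond_var[, 1], 0)),
                    se_eta_beta = sqrt(pmax(parts$cond_var[, 3], 0)),
                    alpha_i = parts$alpha_typ_i * (1 + parts$eta[, 1]),
                    beta_i = parts$beta_typ_i * (1 + parts$eta[, 2]),
                    stringsAsFactors = FALSE)
  ebe$se_alpha_i <- abs(parts$alpha_typ_i) * ebe$se_eta_alpha
  ebe$se_beta_i <- abs(parts$beta_typ_i) * ebe$se_eta_beta
  shrink <- c(alpha = NA_real_, beta = NA_real_)
  if (fr$estimates$omega_alpha > 0)
    shrink[["alpha"]] <- 1 - stats::sd(ebe$eta_alpha) / fr$estimates$omega_alpha
  if (fr$estimates$omega_beta > 0)
    shrink[["beta"]] <- 1 - stats::sd(ebe$eta_beta) / fr$estimates$omega_beta
  attr(ebe, "shrinkage") <- shrink
  ebe
}

#' Structural-model selection by AIC
#'
#' Fits each candidate placebo form as a covariate-free model and ranks
#' converged candidates by AIC; candidates that fail to converge are listed
#' last with the failure reason (short-duration designs routinely defeat
#' the inverse-Bateman offset rate constant).
#'
#' @param ts A [trial_set()].
#' @param forms Character vector of candidate placebo forms (>= 2).
#' @param ... Passed to [fit_progression()].
#' @return Data frame ranked by AIC: `form`, `ofv`, `aic`, `n_par`,
#'   `converged`, `reason`; the winning fits are attached as attribute
#'   `"fits"`.
#' @export
select_structural <- function(ts, forms = c("emax", "sigmoid_emax",
                                            "exponential",
                                            "inverse_bateman"), ...) {
  stopifnot(length(forms) >= 2)
  rows <- vector("list", length(forms))
  fits <- vector("list", length(forms))
  for (k in seq_along(forms)) {
    fr <- tryCatch(fit_progression(ts, base_model_spec(forms[k]), ...),
                   error = function(e) NULL)
    ok <- !is.null(fr) && fr$converged
    rows[[k]] <- data.frame(
      form = forms[k], input_order = k,
      ofv = if (ok) fr$ofv else NA_real_,
      aic = if (ok) fr$aic else NA_real_,
      n_par = if (ok) fr$n_par else NA_integer_,
      converged = ok,
      reason = if (ok) "" else "fit failed or did not converge",
      stringsAsFactors = FALSE)
    fits[[k]] <- fr
  }
  tab <- do.call(rbind, rows)
  ord <- order(!tab$converged, tab$aic, tab$input_order)
  tab <- tab[ord, setdiff(names(tab), "input_order")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
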