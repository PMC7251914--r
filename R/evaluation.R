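# Model evaluation: nonparametric bootstrap over study arms, visual
# predictive check on the observed design, and goodness-of-fit residual
# diagnostics.

# run code under a temporary seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

resample_trial_set <- function(ts, idx) {
  arms <- ts$arms[idx, , drop = FALSE]
  sp <- split(seq_len(nrow(ts$observations)), ts$observations$study_id)
  rows <- sp[arms$study_id]
  obs <- ts$observations[unlist(rows, use.names = FALSE), , drop = FALSE]
  new_id <- sprintf("b%03d.%s", seq_along(idx), arms$study_id)
  obs$study_id <- rep(new_id, lengths(rows))
  arms$study_id <- new_id
  trial_set(arms, obs, covariate_refs = ts$covariate_refs)
}

#' Nonparametric bootstrap of the fitted model
#'
#' Resamples study arms (the random-effect unit) with replacement to the
#' original study count, refits each replicate (warm-started at the
#' original estimates, with one jittered fallback), and summarizes each
#' parameter by its bootstrap median and 2.5/97.5 percentiles. Replicate
#' failures are logged, not silently dropped; if more than half fail the
#' result is flagged unreliable.
#'
#' @param ts A [trial_set()].
#' @param spec A [model_spec()].
#' @param B Number of replicates (published analysis used 1000).
#' @param seed RNG seed for the resampling stream.
#' @param fit Optional original `fit_result` (refitted here when missing).
#' @param control Optimizer control for replicate fits.
#' @return Object of class `bootstrap_result`: `summary` (per-parameter
#'   median and percentile interval), `replicates` (matrix), `n_failed`,
#'   `reliable`, `seed`.
#' @export
bootstrap_model <- function(ts, spec = final_model_spec(), B = 1000,
                            seed = 1L, fit = NULL,
                            control = list(rel.tol = 1e-5)) {
  spec <- resolve_spec(spec, ts)
  if (is.null(fit)) fit <- fit_progression(ts, spec, control = control)
  N <- n_studies(ts)
  idx_mat <- with_seed(seed,
                       matrix(sample.int(N, N * B, replace = TRUE), nrow = B))
  reps <- vector("list", B)
  failed <- logical(B)
  for (b in seq_len(B)) {
    tsb <- resample_trial_set(ts, idx_mat[b, ])
    frb <- tryCatch(
      fit_progression(tsb, spec, starts = fit$par, compute_se = FALSE,
                      control = control),
      error = function(e) NULL)
    if (is.null(frb) || !frb$converged) {
      frb <- tryCatch(
        fit_progression(tsb, spec, starts = fit$par, n_restarts = 2,
                        compute_se = FALSE, control = control),
        error = function(e) NULL)
    }
    if (is.null(frb) || !frb$converged) failed[b] <- TRUE
    else reps[[b]] <- frb$natural
  }
  mat <- do.call(rbind, reps[!failed])
  qs <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  summary <- data.frame(parameter = colnames(mat),
                        boot_median = qs[2, ], pi_lower = qs[1, ],
                        pi_upper = qs[3, ], stringsAsFactors = FALSE)
  structure(list(summary = summary, replicates = mat,
                 B = B, n_failed = sum(failed),
                 reliable = mean(failed) <= 0.5, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates, %d failed%s\n", x$B, x$n_failed,
              if (x$reliable) "" else "  [UNRELIABLE: >50% failures]"))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the observed design (same studies,
#' visit times, sample sizes and covariates) from the fitted parameters,
#' including random-effect and residual draws, and compares the observed
#' 2.5/50/97.5 percent quantiles of the mean change per time bin with the
#' 95% simulation interval of each quantile.
#'
#' @param ts A [trial_set()].
#' @param fr A converged `fit_result`.
#' @param n_sim Number of simulated datasets (published check used 1000).
#' @param seed RNG seed.
#' @param bins `"nominal"` bins on exact scheduled weeks (aggregate data
#'   cluster on protocol visits); `"width"` uses intervals of `bin_width`
#'   weeks for irregular schedules.
#' @param bin_width Width in weeks when `bins = "width"`.
#' @return Object of class `vpc_result`: data frame `bands` with, per bin
#'   and per observed quantile, the simulated lower/upper envelope and an
#'   inside/outside flag.
#' @export
vpc <- function(ts, fr, n_sim = 1000, seed = 1L,
                bins = c("nominal", "width"), bin_width = 8) {
  bins <- match.arg(bins)
  if (!fr$converged) stop("fit did not converge")
  if (n_sim < 2) warning("n_sim < 2: simulation bands collapse to a single draw")
  p <- fr$estimates
  ld <- likelihood_data(ts)
  bin_id <- if (bins == "nominal") ld$t else bin_width * ceiling(ld$t / bin_width)
  ubins <- sort(unique(bin_id))
  fac <- covariate_factors(p, ld$arms)
  Ca <- rep(fac$alpha, length.out = ld$n_studies)
  Cb <- rep(fac$beta, length.out = ld$n_studies)
  unit <- placebo_unit(ld$t, et50 = p$et50, form = p$placebo_form,
                       hill = p$hill, k_onset = p$k_onset,
                       k_offset = p$k_offset)
  qfun <- function(y) {
    vapply(ubins, function(b)
      stats::quantile(y[bin_id == b], probs = c(0.025, 0.5, 0.975),
                      names = FALSE), numeric(3))
  }
  obs_q <- qfun(ld$y)                       # 3 x nbins
  L <- chol_omega(p$omega_alpha, p$omega_beta, p$rho)
  sims <- with_seed(seed, {
    out <- array(NA_real_, c(n_sim, 3, length(ubins)))
    for (s in seq_len(n_sim)) {
      eta <- matrix(stats::rnorm(2 * ld$n_studies), 2) # 2 x n_studies
      eta <- t(L %*% eta)                               # n_studies x 2
      alpha_i <- p$alpha * Ca * (1 + eta[, 1])
      beta_i <- p$beta * Cb * (1 + eta[, 2])
      ysim <- alpha_i[ld$study] * ld$t + beta_i[ld$study] * unit +
        stats::rnorm(ld$n_obs, 0, p$delta / sqrt(ld$n))
      out[s, , ] <- qfun(ysim)
    }
    out
  })
  rows <- list()
  qlab <- c("q2.5", "q50", "q97.5")
  for (j in seq_along(ubins)) for (q in 1:3) {
    env <- stats::quantile(sims[, q, j], probs = c(0.025, 0.975),
                           names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      bin = ubins[j], quantile = qlab[q], observed = obs_q[q, j],
      sim_lower = env[1], sim_median = stats::median(sims[, q, j]),
      sim_upper = env[2],
      inside = obs_q[q, j] >= env[1] && obs_q[q, j] <= env[2],
      n_in_bin = sum(bin_id == ubins[j]), stringsAsFactors = FALSE)
  }
  bands <- do.call(rbind, rows)
  structure(list(bands = bands, n_sim = n_sim, seed = seed, bins = bins),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d simulations, %d bins; %.0f%% of quantile points inside the 95%% band\n",
              x$n_sim, length(unique(x$bands$bin)),
              100 * mean(x$bands$inside)))
  invisible(x)
}

#' Plot a visual predictive check
#'
#' @param x A `vpc_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.vpc_result <- function(x, ...) {
  b <- x$bands
  med <- b[b$quantile == "q50", ]
  lo <- b[b$quantile == "q2.5", ]
  hi <- b[b$quantile == "q97.5", ]
  graphics::plot(med$bin, med$observed, type = "n",
                 ylim = range(c(b$observed, b$sim_lower, b$sim_upper)),
                 xlab = "time (weeks)", ylab = "mean change in ADAS-cog", ...)
  shade <- function(d, col)
    graphics::polygon(c(d$bin, rev(d$bin)), c(d$sim_lower, rev(d$sim_upper)),
                      col = col, border = NA)
  shade(lo, grDevices::adjustcolor("steelblue", 0.3))
  shade(med, grDevices::adjustcolor("grey50", 0.3))
  shade(hi, grDevices::adjustcolor("firebrick", 0.3))
  graphics::lines(med$bin, med$observed, lwd = 2)
  graphics::lines(lo$bin, lo$observed, lty = 2)
  graphics::lines(hi$bin, hi$observed, lty = 2)
  invisible(x)
}

#' Goodness-of-fit diagnostics
#'
#' Per-observation table: population prediction (`eta = 0`), individual
#' prediction (at the empirical-Bayes mode), weighted residual
#' `(y - PRED) * sqrt(n) / delta`, and a conditional weighted residual
#' computed from the first-order expansion about the conditional mode
#' (`y - F(eta_hat) + Z eta_hat`, whitened by the marginal covariance
#' `Z Omega Z' + diag(delta^2/n)` per study).
#'
#' @param ts A [trial_set()].
#' @param fr A converged `fit_result`.
#' @return Data frame with one row per observation: `study_id`, `time`,
#'   `n`, `observed`, `pred`, `ipred`, `wres`, `cwres`.
#' @export
gof_diagnostics <- function(ts, fr) {
  if (!fr$converged) stop("fit did not converge")
  p <- fr$estimates
  ld <- likelihood_data(ts)
  parts <- laplace_kernel(p, ld)
  unit <- placebo_unit(ld$t, et50 = p$et50, form = p$placebo_form,
                       hill = p$hill, k_onset = p$k_onset,
                       k_offset = p$k_offset)
  Z1 <- parts$alpha_typ_i[ld$study] * ld$t
  Z2 <- parts$beta_typ_i[ld$study] * unit
  pred <- Z1 + Z2
  ipred <- Z1 * (1 + parts$eta[ld$study, 1]) +
    Z2 * (1 + parts$eta[ld$study, 2])
  wres <- (ld$y - pred) * sqrt(ld$n) / p$delta
  Om <- chol_omega(p$omega_alpha, p$omega_beta, p$rho)
  Om <- Om %*% t(Om)
  cwres <- numeric(ld$n_obs)
  for (i in seq_len(ld$n_studies)) {
    sel <- which(ld$study == i)
    Z <- cbind(Z1[sel], Z2[sel])
    V <- Z %*% Om %*% t(Z) + diag(p$delta^2 / ld$n[sel],
                                  nrow = length(sel))
    # FOCE mean f(eta_hat) - Z eta_hat: reduces to the population
    # prediction f0 because the conditional model is linear in eta
    r <- ld$y[sel] - pred[sel]
    cwres[sel] <- drop(backsolve(chol(V), r, transpose = TRUE))
  }
  data.frame(study_id = ld$arms$study_id[ld$study], time = ld$t, n = ld$n,
             observed = ld$y, pred = pred, ipred = ipred, wres = wres,
             cwres = cwres, stringsAsFactors = FALSE)
}
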