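# Stepwise covariate search: forward inclusion by likelihood-ratio drop
# (> 3.84 OFV points, chi-square P < 0.05 at df = 1), then backward
# elimination (retention requires a > 6.64 rise on removal, P < 0.01),
# with a data-coverage gate that drops covariates reported in too few
# studies before any fitting happens.

#' Screening plan
#'
#' @param candidates Covariate-effect table ([covariate_effect()] rows):
#'   each row is one candidate (covariate, target parameter, form). Several
#'   forms of the same covariate may be listed; once one form is included,
#'   the remaining forms of that (parameter, covariate) pair leave the
#'   candidate pool.
#' @param forward_threshold OFV drop required for inclusion (default 3.84,
#'   strict inequality).
#' @param backward_threshold OFV rise required for retention (default 6.64,
#'   strict inequality).
#' @param coverage_floor Minimum fraction of studies reporting the
#'   covariate, in `(0, 1]` (default 0.70).
#' @return An object of class `screening_plan`.
#' @export
screening_plan <- function(candidates = default_candidates(),
                           forward_threshold = 3.84,
                           backward_threshold = 6.64,
                           coverage_floor = 0.70) {
  if (forward_threshold <= 0 || backward_threshold <= 0)
    stop("config error: thresholds must be > 0")
  if (coverage_floor <= 0 || coverage_floor > 1)
    stop("config error: coverage_floor must be in (0, 1]")
  structure(list(candidates = candidates,
                 forward_threshold = forward_threshold,
                 backward_threshold = backward_threshold,
                 coverage_floor = coverage_floor),
            class = "screening_plan")
}

#' @rdname screening_plan
#' @details `default_candidates()` mirrors the published search on the
#'   progression rate: baseline ADAS-cog as inverse-U and as power form
#'   (compared head-to-head by OFV drop), and baseline age as power form.
#' @export
default_candidates <- function() {
  rbind(covariate_effect("baseline_adas", "alpha", "inverse_u"),
        covariate_effect("baseline_adas", "alpha", "power"),
        covariate_effect("baseline_age", "alpha", "power"))
}

#' Coverage gate for candidate covariates
#'
#' Drops candidates whose covariate is missing in more than
#' `1 - coverage_floor` of the study arms (covariates absent from too many
#' studies cannot be screened reliably).
#'
#' @param ts A [trial_set()].
#' @param candidates Candidate table.
#' @param coverage_floor Fraction in `(0, 1]`.
#' @return List with `admitted` and `excluded` candidate tables; `excluded`
#'   carries a `reason` column.
#' @export
coverage_filter <- function(ts, candidates, coverage_floor = 0.70) {
  if (coverage_floor <= 0 || coverage_floor > 1)
    stop("config error: coverage_floor must be in (0, 1]")
  frac <- vapply(candidates$covariate, function(cv) {
    col <- ts$arms[[cv]]
    if (is.null(col)) 0 else mean(!is.na(col))
  }, numeric(1))
  keep <- frac >= coverage_floor
  excluded <- candidates[!keep, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("reported in %.0f%% of studies (< %.0f%%)",
                               100 * frac[!keep], 100 * coverage_floor)
  list(admitted = candidates[keep, , drop = FALSE], excluded = excluded)
}

# warm start for an augmented/reduced spec from a previous fit
warm_starts <- function(fr, spec2) {
  p <- fr$estimates
  th <- rep(0, length(spec2$covariate_model$theta_name))
  names(th) <- spec2$covariate_model$theta_name
  common <- intersect(names(th), names(p$theta))
  th[common] <- p$theta[common]
  p$theta <- th
  p$covariate_model <- spec2$covariate_model
  pack_params(p, spec2)
}

#' One forward-inclusion step
#'
#' Fits every single-candidate augmentation of the current spec
#' (warm-started at the current optimum) and includes the candidate with
#' the largest OFV drop strictly greater than the threshold. Equal drops
#' (within 1e-6) break by candidate order. Candidates whose
#' (parameter, covariate) pair is already in the spec are skipped; failed
#' augmentations are recorded and the search continues.
#'
#' @param ts A [trial_set()].
#' @param current_fit `fit_result` for the current spec.
#' @param candidates Admitted candidate table.
#' @param threshold Forward OFV-drop threshold (strict).
#' @param ... Passed to [fit_progression()].
#' @return List: `fit` (augmented fit or `NULL` when nothing passes),
#'   `included` (chosen candidate row or `NULL`), `table` (per-candidate
#'   OFV drops).
#' @export
forward_step <- function(ts, current_fit, candidates, threshold = 3.84, ...) {
  cur_cm <- current_fit$spec$covariate_model
  in_model <- if (is.null(cur_cm)) character() else
    paste(cur_cm$parameter, cur_cm$covariate)
  rows <- list(); fits <- list()
  for (k in seq_len(nrow(candidates))) {
    cand <- candidates[k, , drop = FALSE]
    if (paste(cand$parameter, cand$covariate) %in% in_model) next
    spec2 <- model_spec(current_fit$spec$placebo_form,
                        rbind(cur_cm, cand[, setdiff(names(cand), "reason")]),
                        estimate_iiv = current_fit$spec$estimate_iiv,
                        scale_max = current_fit$spec$scale_max)
    spec2 <- resolve_spec(spec2, ts)
    fr2 <- tryCatch(
      fit_progression(ts, spec2, starts = warm_starts(current_fit, spec2),
                      compute_se = FALSE, ...),
      error = function(e) NULL)
    ok <- !is.null(fr2) && fr2$converged
    rows[[length(rows) + 1]] <- data.frame(
      candidate = cand$theta_name, covariate = cand$covariate,
      parameter = cand$parameter, form = cand$form,
      ofv = if (ok) fr2$ofv else NA_real_,
      delta_ofv = if (ok) current_fit$ofv - fr2$ofv else NA_real_,
      failed = !ok, stringsAsFactors = FALSE)
    fits[[length(fits) + 1]] <- fr2
  }
  if (!length(rows)) {
    return(list(fit = NULL, included = NULL,
                table = data.frame(candidate = character(),
                                   delta_ofv = numeric())))
  }
  tab <- do.call(rbind, rows)
  pass <- which(!tab$failed & tab$delta_ofv > threshold)
  if (!length(pass)) return(list(fit = NULL, included = NULL, table = tab))
  # Within one (parameter, covariate) group, alternative functional forms
  # are not ranked by OFV drop alone: the earliest-listed form that clears
  # the gate is the group's champion. Listing the boundary-aware inverse-U
  # form ahead of the power form encodes the plausibility preference for
  # bounded-scale covariates; competing covariates (different groups) are
  # then ranked by their champion's OFV drop.
  grp <- paste(tab$parameter, tab$covariate)
  champions <- vapply(split(pass, grp[pass]), min, integer(1))
  mx <- max(tab$delta_ofv[champions])
  best <- champions[tab$delta_ofv[champions] >= mx - 1e-6]
  best <- min(best)                    # order-stable tie-break
  list(fit = fits[[best]], included = tab[best, ], table = tab)
}

#' Backward-elimination pass
#'
#' Removes, one at a time, the covariate whose deletion raises the OFV the
#' least, as long as that rise is <= the threshold; iterates until every
#' remaining covariate is necessary (> threshold rise on removal).
#'
#' @param ts A [trial_set()].
#' @param full_fit `fit_result` of the full model.
#' @param threshold Backward OFV-rise threshold (default 6.64, strict).
#' @param ... Passed to [fit_progression()].
#' @return List: `fit` (pruned fit), `removed` (character vector of dropped
#'   effect names), `table` (per-covariate OFV rises, final round).
#' @export
backward_step <- function(ts, full_fit, threshold = 6.64, ...) {
  fit <- full_fit
  removed <- character()
  tab <- data.frame()
  repeat {
    cm <- fit$spec$covariate_model
    if (is.null(cm) || nrow(cm) == 0) break
    rows <- list(); fits <- list()
    for (k in seq_len(nrow(cm))) {
      spec2 <- model_spec(fit$spec$placebo_form,
                          cm[-k, , drop = FALSE],
                          estimate_iiv = fit$spec$estimate_iiv,
                          scale_max = fit$spec$scale_max)
      fr2 <- tryCatch(
        fit_progression(ts, spec2, starts = warm_starts(fit, spec2),
                        compute_se = FALSE, ...),
        error = function(e) NULL)
      ok <- !is.null(fr2) && fr2$converged
      rows[[k]] <- data.frame(candidate = cm$theta_name[k],
                              ofv = if (ok) fr2$ofv else NA_real_,
                              rise = if (ok) fr2$ofv - fit$ofv else NA_real_,
                              failed = !ok, stringsAsFactors = FALSE)
      fits[[k]] <- fr2
    }
    tab <- do.call(rbind, rows)
    drop_k <- which(!tab$failed & tab$rise <= threshold)
    if (!length(drop_k)) break
    k <- drop_k[which.min(tab$rise[drop_k])]
    removed <- c(removed, tab$candidate[k])
    fit <- fits[[k]]
  }
  list(fit = fit, removed = removed, table = tab)
}

#' Stepwise covariate search
#'
#' Coverage gate, forward inclusion to exhaustion, then backward
#' elimination. Deterministic given the data and plan; the audit trail
#' records every fitted model's OFV and every decision.
#'
#' @param ts A validated [trial_set()].
#' @param plan A [screening_plan()].
#' @param base_spec Starting spec (default covariate-free Emax model).
#' @param ... Passed to [fit_progression()] (e.g. a looser `control`).
#' @return List of class `screening_result`: `fit` (final model fit,
#'   with standard errors), `spec`, `audit` (data frame of decisions),
#'   `excluded` (coverage-gate exclusions).
#' @export
stepwise_search <- function(ts, plan = screening_plan(),
                            base_spec = base_model_spec(), ...) {
  gate <- coverage_filter(ts, plan$candidates, plan$coverage_floor)
  audit <- list()
  note <- function(stage, action, candidate = NA_character_,
                   ofv = NA_real_, delta = NA_real_)
    audit[[length(audit) + 1]] <<- data.frame(
      stage = stage, action = action, candidate = candidate, ofv = ofv,
      delta_ofv = delta, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(gate$excluded)))
    note("coverage", "excluded", gate$excluded$theta_name[k])
  fit <- fit_progression(ts, resolve_spec(base_spec, ts),
                         compute_se = FALSE, ...)
  if (!fit$converged) stop("base model did not converge")
  note("base", "fitted", ofv = fit$ofv)
  repeat {
    step <- forward_step(ts, fit, gate$admitted,
                         threshold = plan$forward_threshold, ...)
    for (k in seq_len(nrow(step$table)))
      note("forward", "tested", step$table$candidate[k],
           step$table$ofv[k], step$table$delta_ofv[k])
    if (is.null(step$fit)) break
    fit <- step$fit
    note("forward", "included", step$included$candidate, fit$ofv,
         step$included$delta_ofv)
  }
  back <- backward_step(ts, fit, threshold = plan$backward_threshold, ...)
  for (rm_name in back$removed) note("backward", "removed", rm_name)
  fit <- back$fit
  note("final", "fitted", ofv = fit$ofv)
  # cold-start cross-check with standard errors on the final model only
  final <- fit_progression(ts, fit$spec, ...)
  if (final$converged && final$ofv <= fit$ofv + 1e-3) fit <- final
  structure(list(fit = fit, spec = fit$spec,
                 audit = do.call(rbind, audit), excluded = gate$excluded),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cm <- x$spec$covariate_model
  cat("Stepwise covariate search -> ",
      if (is.null(cm)) "no covariates retained"
      else paste(cm$theta_name, collapse = ", "), "\n", sep = "")
  cat(sprintf("  final OFV %.3f (%d decisions logged)\n", x$fit$ofv,
              nrow(x$audit)))
  invisible(x)
}
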