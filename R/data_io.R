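#' @keywords internal
ARM_COLUMNS <- c("study_id", "publication_year", "era", "add_on", "region",
                 "baseline_adas", "baseline_age", "randomized_n")
OBS_COLUMNS <- c("study_id", "time", "mean_change", "n", "imputation")
REGION_LEVELS <- c("International", "NorthAmerica", "EuropeOceania",
                   "EastAsia", "MiddleAsia", "SouthAmerica")

#' Construct a trial set
#'
#' A `trial_set` holds one placebo arm per study: an arm-level table of
#' covariates and a long observation table of mean changes from baseline in
#' ADAS-cog. Observations are normalized to ascending time within study;
#' `era` is derived from `publication_year` (`pre2008` / `post2008`) when
#' absent; region labels outside the six-way grouping map to `"Unlabeled"`
#' so subgrouping stays optional.
#'
#' @param arms Data frame, one row per study arm: `study_id`,
#'   `baseline_adas`, `baseline_age`, and optionally `publication_year`,
#'   `era`, `add_on`, `region`, `randomized_n`.
#' @param observations Data frame, one row per (study, time):
#'   `study_id`, `time` (weeks, > 0), `mean_change` (points), `n`
#'   (analyzed sample size), optional `imputation` (`"OC"`, `"LOCF"`,
#'   `"unknown"`).
#' @param covariate_refs Named vector of reference covariate values used by
#'   covariate functions (defaults: ADAS-cog 24.5, age 73.5).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(arms, observations,
                      covariate_refs = c(baseline_adas = 24.5,
                                         baseline_age = 73.5)) {
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  for (col in c("study_id", "baseline_adas", "baseline_age"))
    if (is.null(arms[[col]])) stop("arms table missing column: ", col)
  for (col in c("study_id", "time", "mean_change", "n"))
    if (is.null(observations[[col]])) stop("observations missing column: ", col)
  arms$study_id <- as.character(arms$study_id)
  observations$study_id <- as.character(observations$study_id)
  if (is.null(arms$publication_year)) arms$publication_year <- NA_integer_
  if (is.null(arms$era))
    arms$era <- ifelse(is.na(arms$publication_year), NA_character_,
                       ifelse(arms$publication_year < 2008,
                              "pre2008", "post2008"))
  arms$era[is.na(arms$era) & !is.na(arms$publication_year)] <-
    ifelse(arms$publication_year[is.na(arms$era) &
                                 !is.na(arms$publication_year)] < 2008,
           "pre2008", "post2008")
  if (is.null(arms$add_on)) arms$add_on <- NA
  if (is.null(arms$region)) arms$region <- "Unlabeled"
  arms$region[!(arms$region %in% REGION_LEVELS)] <- "Unlabeled"
  if (is.null(arms$randomized_n)) {
    mx <- tapply(observations$n, observations$study_id, max)
    arms$randomized_n <- as.integer(mx[arms$study_id])
  }
  if (is.null(observations$imputation)) observations$imputation <- "unknown"
  observations <- observations[order(observations$study_id,
                                     observations$time), , drop = FALSE]
  rownames(arms) <- rownames(observations) <- NULL
  structure(list(arms = arms[, ARM_COLUMNS],
                 observations = observations[, OBS_COLUMNS],
                 covariate_refs = covariate_refs),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d study arms, %d observations (%.0f-%.0f weeks)\n",
              nrow(x$arms), nrow(x$observations),
              min(x$observations$time), max(x$observations$time)))
  cat("  covariate refs:",
      paste(sprintf("%s=%.3g", names(x$covariate_refs), x$covariate_refs),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of study arms in a trial set
#' @param ts A `trial_set`.
#' @export
n_studies <- function(ts) nrow(ts$arms)

default_dialect <- function() {
  c(study_id = "study_id", time = "time_weeks", mean_change = "mean_change",
    n = "n", baseline_adas = "baseline_adas", baseline_age = "baseline_age",
    publication_year = "publication_year", era = "era", add_on = "add_on",
    region = "region", randomized_n = "randomized_n",
    imputation = "imputation")
}

#' Read a trial set from CSV
#'
#' Long format, one row per (study, time point); arm-level covariates are
#' repeated across a study's rows and must be constant within study.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param dialect Named character vector mapping canonical field names to
#'   file column names; defaults cover `study_id`, `time_weeks`,
#'   `mean_change`, `n`, `baseline_adas`, `baseline_age` plus the optional
#'   covariates.
#' @param covariate_refs Passed to [trial_set()].
#' @return A validated `trial_set`.
#' @export
read_trials <- function(path, dialect = default_dialect(),
                        covariate_refs = c(baseline_adas = 24.5,
                                           baseline_age = 73.5)) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- utils::modifyList(as.list(default_dialect()), as.list(dialect))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "time", "mean_change", "n",
                "baseline_adas", "baseline_age")
  for (fld in required)
    if (!(dialect[[fld]] %in% names(raw)))
      stop("missing required column: ", dialect[[fld]])
  get_col <- function(fld) {
    col <- dialect[[fld]]
    if (col %in% names(raw)) raw[[col]] else NULL
  }
  for (fld in c("time", "mean_change", "n")) {
    v <- suppressWarnings(as.numeric(get_col(fld)))
    bad <- which(is.na(v) & !is.na(get_col(fld)))
    if (length(bad))
      stop("non-numeric ", fld, " at row(s): ", paste(bad, collapse = ", "))
    raw[[dialect[[fld]]]] <- v
  }
  obs <- data.frame(study_id = get_col("study_id"), time = get_col("time"),
                    mean_change = get_col("mean_change"), n = get_col("n"),
                    stringsAsFactors = FALSE)
  imp <- get_col("imputation")
  obs$imputation <- if (is.null(imp)) "unknown" else imp
  arm_fields <- c("study_id", "publication_year", "era", "add_on", "region",
                  "baseline_adas", "baseline_age", "randomized_n")
  arms <- lapply(arm_fields, get_col)
  names(arms) <- arm_fields
  arms <- as.data.frame(Filter(Negate(is.null), arms),
                        stringsAsFactors = FALSE)
  arms <- arms[!duplicated(arms$study_id), , drop = FALSE]
  trial_set(arms, obs, covariate_refs = covariate_refs)
}

#' Write a trial set to CSV
#'
#' Inverse of [read_trials()]: emits the long-format dialect with arm
#' covariates repeated on each observation row.
#'
#' @param ts A `trial_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ts, path) {
  merged <- merge(ts$observations, ts$arms, by = "study_id", sort = FALSE)
  merged <- merged[order(merged$study_id, merged$time), ]
  names(merged)[names(merged) == "time"] <- "time_weeks"
  utils::write.csv(merged, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trial set
#'
#' Checks the data-quality rules used at inclusion and modelling time; each
#' violation is reported as data (one row), never raised. Rules:
#' `min-sample-size` (placebo-arm size must exceed 10), `adas-range`
#' (baseline ADAS-cog within the open 0-70 scale), `missing-covariate`
#' (baseline ADAS-cog and age are required by the final model),
#' `time-positive`, `obs-n` (n >= 1), `finite-change`, `duplicate-id`.
#'
#' @param ts A `trial_set`.
#' @return Data frame with columns `study_id`, `rule`, `message`; zero rows
#'   when the set is fully valid.
#' @export
validate_trials <- function(ts) {
  v <- list()
  add <- function(study_id, rule, message)
    v[[length(v) + 1]] <<- data.frame(study_id = study_id, rule = rule,
                                      message = message,
                                      stringsAsFactors = FALSE)
  a <- ts$arms
  dup <- unique(a$study_id[duplicated(a$study_id)])
  for (id in dup) add(id, "duplicate-id", "study_id not unique")
  for (k in seq_len(nrow(a))) {
    id <- a$study_id[k]
    if (!is.na(a$randomized_n[k]) && a$randomized_n[k] <= 10)
      add(id, "min-sample-size", "placebo arm size must be > 10")
    if (is.na(a$baseline_adas[k]) || is.na(a$baseline_age[k]))
      add(id, "missing-covariate",
          "baseline_adas and baseline_age are required")
    else if (a$baseline_adas[k] <= 0 || a$baseline_adas[k] >= 70)
      add(id, "adas-range", "baseline ADAS-cog outside (0, 70)")
  }
  o <- ts$observations
  bad_t <- unique(o$study_id[o$time <= 0])
  for (id in bad_t) add(id, "time-positive", "observation time must be > 0")
  bad_n <- unique(o$study_id[o$n < 1])
  for (id in bad_n) add(id, "obs-n", "per-time sample size must be >= 1")
  bad_y <- unique(o$study_id[!is.finite(o$mean_change)])
  for (id in bad_y) add(id, "finite-change", "mean change must be finite")
  orphans <- setdiff(unique(o$study_id), a$study_id)
  for (id in orphans) add(id, "orphan-observation", "no matching study arm")
  if (any(ts$covariate_refs <= 0))
    add(NA_character_, "covariate-refs", "covariate_refs must be positive")
  if (length(v)) do.call(rbind, v)
  else data.frame(study_id = character(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Restrict a trial set to the modelling window
#'
#' Long-term observations can bias the linear progression slope, so only
#' data within the first `max_weeks` (default two years) are modelled.
#' Arms left without observations are dropped; the counts are attached as
#' attributes `n_dropped_obs` / `n_dropped_arms`.
#'
#' @param ts A `trial_set`.
#' @param max_weeks Window length in weeks (> 0), default 104.
#' @return A filtered `trial_set`.
#' @export
filter_modeling_window <- function(ts, max_weeks = 104) {
  stopifnot(max_weeks > 0)
  keep <- ts$observations$time <= max_weeks
  obs <- ts$observations[keep, , drop = FALSE]
  live <- ts$arms$study_id %in% unique(obs$study_id)
  out <- trial_set(ts$arms[live, , drop = FALSE], obs,
                   covariate_refs = ts$covariate_refs)
  attr(out, "n_dropped_obs") <- sum(!keep)
  attr(out, "n_dropped_arms") <- sum(!live)
  out
}
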