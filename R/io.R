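TRIAL_COLUMNS <- c("subject_id", "phase", "session_index", "trial_index",
                   "rewarded_side", "positive_stimulus", "chosen_stimulus",
                   "correct", "initiated", "n_blank_touches",
                   "response_latency", "reward_latency", "reward_ul")

SESSION_COLUMNS <- c("subject_id", "phase", "session_index", "n_trials",
                     "n_correct", "accuracy", "duration_min", "complete",
                     "sum_response_latency", "sum_reward_latency",
                     "n_rewarded")

#' Write trial-level and session-level logs as CSV
#'
#' Writes the documented trial-log format: comma-separated, UTF-8, `"."`
#' decimal separator, `NA` for missing, one row per trial
#' (`trials.csv`-style) and one row per session (`sessions.csv`-style).
#' Round-trips losslessly through [read_trial_logs()].
#'
#' @param x an `animal_run`, a `cohort` (with `keep_trials = TRUE`), or a
#'   list with `trials` and `sessions` data frames.
#' @param trials_path,sessions_path output files.
#' @return Invisibly, the two paths.
#' @export
write_trial_logs <- function(x, trials_path, sessions_path) {
  if (is.null(x$trials)) stop("no trial-level log present (keep_trials?)")
  tr <- x$trials[, TRIAL_COLUMNS]
  se <- x$sessions[, SESSION_COLUMNS]
  write.csv(tr, trials_path, row.names = FALSE, na = "NA",
            fileEncoding = "UTF-8", quote = FALSE)
  write.csv(se, sessions_path, row.names = FALSE, na = "NA",
            fileEncoding = "UTF-8", quote = FALSE)
  invisible(c(trials = trials_path, sessions = sessions_path))
}

#' Read and validate trial-level logs
#'
#' Reads the CSV trial-log format back, with schema validation: required
#' columns, non-negative latencies and trial counts, and unique (subject,
#' phase, session, trial) keys. Violations are reported with the offending
#' file line numbers. Rows are returned ordered by subject, phase, session
#' and trial.
#'
#' @param trials_path trial-level CSV.
#' @param sessions_path optional session-level CSV.
#' @return A list of class `trial_logs` with `trials` and `sessions`
#'   (`NULL` when no session file is given).
#' @export
read_trial_logs <- function(trials_path, sessions_path = NULL) {
  tr <- read.csv(trials_path, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing_cols)) {
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("response_latency", "reward_latency")) {
    if (!is.numeric(tr[[col]])) {
      stop("column ", col, " is not numeric")
    }
    bad <- which(!is.na(tr[[col]]) & tr[[col]] < 0)
    if (length(bad)) {
      stop("negative ", col, " at line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", trials_path)
    }
  }
  if (!is.logical(tr$correct)) stop("column correct is not logical")
  key <- paste(tr$subject_id, tr$phase, tr$session_index, tr$trial_index)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicated (subject, phase, session, trial) keys at line(s) ",
         paste(dup + 1L, collapse = ", "), " of ", trials_path)
  }
  tr <- tr[order(tr$subject_id, match(tr$phase, PHASES), tr$session_index,
                 tr$trial_index), , drop = FALSE]
  rownames(tr) <- NULL
  se <- NULL
  if (!is.null(sessions_path)) {
    se <- read.csv(sessions_path, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
    missing_cols <- setdiff(SESSION_COLUMNS, names(se))
    if (length(missing_cols)) {
      stop("session log lacks columns: ",
           paste(missing_cols, collapse = ", "))
    }
    if (any(se$n_trials < 0)) stop("negative trial counts in session log")
    se <- se[order(se$subject_id, match(se$phase, PHASES),
                   se$session_index), , drop = FALSE]
    rownames(se) <- NULL
  }
  structure(list(trials = tr, sessions = se), class = "trial_logs")
}

#' Write a cohort manifest as JSON
#'
#' Serializes a simulated cohort's provenance: the master seed, and per
#' subject the group, sex, age, counterbalanced positive image, derived
#' seed, truncation flag and every true generating parameter. Together
#' with the package version this suffices to re-simulate any subject in
#' isolation.
#'
#' @param cohort a `cohort` from [make_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- list(
    master_seed = cohort$manifest$master_seed,
    n_young = cohort$spec$n_young, n_aged = cohort$spec$n_aged,
    p_stim_bias = cohort$spec$p_stim_bias,
    stim_bias_size = cohort$spec$stim_bias_size,
    animals = cohort$manifest$animals
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Load the packaged per-animal summary table
#'
#' Loads the fixture transcribed verbatim (to the printed precision) from
#' the published per-animal performance table of the touchscreen mouse
#' lemur aging study: 30 subjects, their sex, age, training days, positive
#' image, first-session image bias, PD and PDR sessions/trials to
#' criterion, latencies, and the three perseveration measures. Integrity is
#' checked on every load: 30 rows, 20 young (10 m / 10 f) and 10 aged
#' (4 m / 6 f) by the 5-year age threshold, exactly 6 bias-flagged
#' subjects, and the internal count invariants; any mismatch (fixture
#' tampering) is an error.
#'
#' @param path fixture CSV; defaults to the copy shipped with the package.
#' @return Data frame with one row per animal, plus derived `age_group` and
#'   `bias_flag` columns.
#' @examples
#' t1 <- load_table1()
#' subset(t1, subject_id == "WIL")$trials_to_50 # 1680
#' @export
load_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1.csv", package = "touchPDR",
                        mustWork = TRUE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                 fileEncoding = "UTF-8")
  df$age_group <- ifelse(df$age_years < 5, "young", "aged")
  df$bias_flag <- !is.na(df$bias_image)
  fail <- function(...) stop("fixture integrity check failed: ", ...)
  if (nrow(df) != 30L) fail("expected 30 rows, got ", nrow(df))
  if (sum(df$age_group == "young") != 20L ||
      sum(df$age_group == "aged") != 10L) fail("age-group counts")
  sx <- table(df$sex, df$age_group)
  if (sx["m", "young"] != 10L || sx["f", "young"] != 10L ||
      sx["m", "aged"] != 4L || sx["f", "aged"] != 6L) fail("sex counts")
  if (sum(df$bias_flag) != 6L) fail("expected 6 bias-flagged rows")
  if (!all(df$bias_image[df$bias_flag] %in% c("marble", "fan"))) {
    fail("bias images")
  }
  with(df, {
    if (any(pd_trials < pd_sessions) || any(pdr_trials < pdr_sessions)) {
      fail("trials < sessions")
    }
    if (any(persev_errors_50 > trials_to_50)) {
      fail("perseverative errors exceed trials to the 50% criterion")
    }
    if (any(df[sapply(df, is.numeric)] < 0, na.rm = TRUE)) {
      fail("negative values")
    }
  })
  df
}
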