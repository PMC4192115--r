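#' Scoring configuration
#'
#' Thresholds and conventions for per-animal scoring.
#'
#' @param accuracy_criterion,criterion_window task criterion: accuracy at or
#'   above `accuracy_criterion` in `criterion_window` consecutive sessions.
#' @param bias_alpha significance level of the first-session binomial
#'   stimulus-bias screen (two-sided).
#' @param chance_p chance success probability of the binomial tests.
#' @param fifty_criterion,fifty_window the reversal "end of perseverance"
#'   criterion: accuracy at or above `fifty_criterion` in `fifty_window`
#'   consecutive *complete* sessions.
#' @param complete_trials trial count defining a complete session.
#' @param persev_mode `"all"` counts perseverative errors in every session
#'   flagged by the per-session binomial test; `"contiguous"` restricts to
#'   the initial unbroken run of flagged sessions.
#' @param latency_mode `"pooled"` averages latencies over all trials of a
#'   phase; `"session_mean"` averages per-session means.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(accuracy_criterion = 0.80, criterion_window = 2L,
                           bias_alpha = 0.05, chance_p = 0.5,
                           fifty_criterion = 0.50, fifty_window = 2L,
                           complete_trials = 30L,
                           persev_mode = c("all", "contiguous"),
                           latency_mode = c("pooled", "session_mean")) {
  stopifnot(accuracy_criterion > 0, accuracy_criterion <= 1,
            criterion_window >= 1, bias_alpha > 0, bias_alpha < 1,
            chance_p > 0, chance_p < 1,
            fifty_criterion > 0, fifty_criterion <= 1, fifty_window >= 1)
  structure(list(accuracy_criterion = accuracy_criterion,
                 criterion_window = as.integer(criterion_window),
                 bias_alpha = bias_alpha, chance_p = chance_p,
                 fifty_criterion = fifty_criterion,
                 fifty_window = as.integer(fifty_window),
                 complete_trials = as.integer(complete_trials),
                 persev_mode = match.arg(persev_mode),
                 latency_mode = match.arg(latency_mode)),
            class = "scoring_config")
}

#' Exact two-sided binomial stimulus-bias test
#'
#' Tests whether `k` choices of a stimulus in `n` trials deviate from chance
#' `p0`, using the exact two-sided binomial test (all outcomes with
#' probability at most that of the observed outcome are summed, the
#' convention of [stats::binom.test()]). Used to screen the first PD session
#' for a spontaneous preference or aversion for the positive stimulus, and
#' per reversal session to flag a response bias for the formerly positive
#' stimulus. At `n = 30`, `p0 = 0.5`, the smallest flagged upper count is
#' 21 (and by symmetry 9 for the lower tail).
#'
#' @param k number of choices of the focal stimulus.
#' @param n number of trials (>= 1).
#' @param p0 chance probability.
#' @param alpha significance level for the `biased` flag.
#' @return List with `k`, `n`, `p` (exact two-sided), `biased`, and
#'   `direction` (`"toward"`, `"away"`, `"none"`).
#' @examples
#' binomial_bias_test(15, 30)$p # 1, symmetric
#' binomial_bias_test(21, 30)$biased # TRUE
#' @export
binomial_bias_test <- function(k, n, p0 = 0.5, alpha = 0.05) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  p <- binom.test(k, n, p = p0)$p.value
  list(k = as.integer(k), n = as.integer(n), p = p,
       biased = p < alpha,
       direction = if (k > n * p0) "toward" else if (k < n * p0) "away" else "none")
}

#' Sessions and trials to the task criterion
#'
#' Locates the first pair (more generally, window) of consecutive sessions
#' whose accuracies all reach the criterion, and returns the number of
#' sessions, trials and errors accumulated up to and including the last
#' criterion session. Incomplete sessions count as sessions and contribute
#' their trials, and may themselves serve as criterion sessions (the task
#' criterion caps, but does not require, 30 trials per session).
#'
#' @param session_accuracies per-session accuracy, in session order.
#' @param session_trial_counts per-session completed-trial counts.
#' @param session_error_counts per-session error counts; by default
#'   recovered as `round(trials * (1 - accuracy))`.
#' @param config a [scoring_config()].
#' @return List with `reached` (logical), `n_sessions`, `n_trials`,
#'   `n_errors` (all `NA` when the criterion is never met).
#' @examples
#' criterion_point(c(0.9, 0.9), c(30, 30)) # reached at session 2, 60 trials
#' @export
criterion_point <- function(session_accuracies, session_trial_counts,
                            session_error_counts = NULL,
                            config = scoring_config()) {
  m <- length(session_accuracies)
  if (m == 0L) stop("empty session history")
  if (length(session_trial_counts) != m) stop("parallel lists required")
  if (is.null(session_error_counts)) {
    session_error_counts <- round(session_trial_counts *
                                    (1 - session_accuracies))
  }
  w <- config$criterion_window
  ok <- session_accuracies >= config$accuracy_criterion
  if (m >= w) {
    for (i in w:m) {
      if (all(ok[(i - w + 1L):i])) {
        return(list(reached = TRUE, n_sessions = i,
                    n_trials = sum(session_trial_counts[1:i]),
                    n_errors = sum(session_error_counts[1:i])))
      }
    }
  }
  list(reached = FALSE, n_sessions = NA_integer_, n_trials = NA_integer_,
       n_errors = NA_integer_)
}

# Coerce reversal-session input (list of session_log or a data frame) to a
# per-session table with n_trials / n_errors / complete.
as_pdr_sessions <- function(x, config) {
  if (is.data.frame(x)) {
    df <- x
    if (is.null(df$n_errors)) df$n_errors <- df$n_trials - df$n_correct
  } else if (is.list(x) && length(x) > 0 &&
             inherits(x[[1]], "session_log")) {
    df <- data.frame(
      n_trials = vapply(x, `[[`, integer(1), "n_trials"),
      n_errors = vapply(x, function(s) s$n_trials - s$n_correct, integer(1))
    )
  } else {
    stop("expected a data frame or a list of session_log objects")
  }
  if (nrow(df) == 0L) stop("empty session list")
  df$complete <- df$n_trials >= config$complete_trials
  df
}

#' Perseverative errors under the binomial criterion
#'
#' Applies the per-session binomial test to the number of touches of the
#' formerly positive stimulus (which, in reversal, are exactly the errors)
#' and flags sessions with a significant response bias toward it. The
#' perseveration phase comprises all flagged sessions (or only the initial
#' contiguous run when `persev_mode = "contiguous"`), and the perseverative
#' error count is the total number of errors within flagged sessions.
#'
#' @param pdr_sessions reversal sessions in order: a list of `session_log`
#'   objects or a data frame with columns `n_trials` and `n_errors` (or
#'   `n_correct`).
#' @param config a [scoring_config()].
#' @return List with `flagged_sessions` (indices) and
#'   `persev_errors_binomial`.
#' @examples
#' perseveration_binomial(data.frame(n_trials = 30, n_errors = 25))
#' @export
perseveration_binomial <- function(pdr_sessions, config = scoring_config()) {
  df <- as_pdr_sessions(pdr_sessions, config)
  flagged <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$n_trials[i] == 0L) next
    b <- binomial_bias_test(df$n_errors[i], df$n_trials[i],
                            p0 = config$chance_p, alpha = config$bias_alpha)
    flagged[i] <- b$biased && b$direction == "toward"
  }
  idx <- which(flagged)
  if (config$persev_mode == "contiguous" && length(idx) > 0L) {
    run_end <- which(c(diff(idx) != 1L, TRUE))[1]
    if (idx[1] != 1L) idx <- integer(0) else idx <- idx[seq_len(run_end)]
  }
  list(flagged_sessions = idx,
       persev_errors_binomial = sum(df$n_errors[idx]))
}

#' Trials and errors to the 50 percent reversal criterion
#'
#' Finds the first pair of consecutive *complete* reversal sessions whose
#' accuracies both reach 50 percent (chance), taken to mark the definite end
#' of perseverance, and returns the trials and errors accumulated over all
#' sessions up to and including the second session of the pair. Incomplete
#' sessions cannot serve as criterion sessions but their trials and errors
#' still accumulate.
#'
#' @inheritParams perseveration_binomial
#' @return List with `reached`, `trials_to_50`, `persev_errors_50`.
#' @examples
#' fifty_percent_point(data.frame(n_trials = rep(30, 4),
#'                                n_errors = c(24, 18, 15, 12)))
#' @export
fifty_percent_point <- function(pdr_sessions, config = scoring_config()) {
  df <- as_pdr_sessions(pdr_sessions, config)
  acc <- ifelse(df$n_trials > 0, 1 - df$n_errors / df$n_trials, 0)
  ok <- df$complete & acc >= config$fifty_criterion
  w <- config$fifty_window
  if (nrow(df) >= w) {
    for (i in w:nrow(df)) {
      if (all(ok[(i - w + 1L):i])) {
        return(list(reached = TRUE,
                    trials_to_50 = sum(df$n_trials[1:i]),
                    persev_errors_50 = sum(df$n_errors[1:i])))
      }
    }
  }
  list(reached = FALSE, trials_to_50 = NA_integer_,
       persev_errors_50 = NA_integer_)
}

#' Mean response and reward-collection latencies of a phase
#'
#' Trial-level pooled means over all sessions of the phase (the default):
#' the response-latency mean over every completed trial, and the
#' reward-collection mean over rewarded (correct) trials only.
#' `latency_mode = "session_mean"` in the config averages per-session means
#' instead.
#'
#' @param x an `animal_run` (from [simulate_animal()]), or a trials data
#'   frame, or a sessions data frame carrying latency sums.
#' @param phase phase label to pool over.
#' @param config a [scoring_config()].
#' @return List with `response_latency` and `reward_latency` (the latter
#'   `NA` when the phase has no rewarded trial).
#' @export
latency_summary <- function(x, phase, config = scoring_config()) {
  if (inherits(x, "animal_run")) {
    x <- if (!is.null(x$trials)) x$trials else x$sessions
  }
  stopifnot(is.data.frame(x))
  if ("trial_index" %in% names(x)) {
    tr <- x[x$phase == phase, , drop = FALSE]
    if (nrow(tr) == 0L) stop("no trials of phase ", phase)
    if (config$latency_mode == "pooled") {
      resp <- mean(tr$response_latency)
      rew <- if (any(!is.na(tr$reward_latency))) {
        mean(tr$reward_latency, na.rm = TRUE)
      } else NA_real_
    } else {
      by_resp <- tapply(tr$response_latency, tr$session_index, mean)
      by_rew <- tapply(tr$reward_latency, tr$session_index,
                       function(v) mean(v, na.rm = TRUE))
      resp <- mean(by_resp)
      rew <- mean(by_rew, na.rm = TRUE)
      if (is.nan(rew)) rew <- NA_real_
    }
  } else {
    se <- x[x$phase == phase & x$n_trials > 0, , drop = FALSE]
    if (nrow(se) == 0L) stop("no sessions of phase ", phase)
    if (config$latency_mode == "pooled") {
      resp <- sum(se$sum_response_latency) / sum(se$n_trials)
      rew <- if (sum(se$n_rewarded) > 0) {
        sum(se$sum_reward_latency) / sum(se$n_rewarded)
      } else NA_real_
    } else {
      resp <- mean(se$sum_response_latency / se$n_trials)
      has <- se$n_rewarded > 0
      rew <- if (any(has)) {
        mean(se$sum_reward_latency[has] / se$n_rewarded[has])
      } else NA_real_
    }
  }
  list(response_latency = resp, reward_latency = rew)
}

#' Per-animal summary of a full protocol run
#'
#' Assembles the one-row-per-animal summary used throughout the group
#' analyses: total training days; first-PD-session stimulus-bias screen;
#' sessions, trials, and latencies to the PD and PDR criteria; and both
#' reversal perseveration measures. Phases whose criterion was never
#' reached (truncated runs) yield `NA` fields and `FALSE` reached flags.
#' The bias screen is evaluated purely by the binomial rule, so a
#' near-perfect first PD session is itself flagged as a preference for the
#' positive stimulus.
#'
#' @param run an `animal_run` from [simulate_animal()].
#' @param config a [scoring_config()].
#' @return One-row data frame with the per-animal summary columns
#'   (`subject_id`, `sex`, `age_years`, `age_group`, `training_days`,
#'   `positive_image`, `bias_image`, `bias_flag`, `pd_sessions`,
#'   `pd_trials`, latencies, `pdr_sessions`, `pdr_trials`,
#'   `persev_errors_binomial`, `persev_errors_50`, `trials_to_50`,
#'   reached flags).
#' @export
summarize_animal <- function(run, config = scoring_config()) {
  stopifnot(inherits(run, "animal_run"))
  se <- run$sessions
  training_days <- sum(se$phase %in% c("STEP1", "STEP2", "STEP3",
                                       "STEP4", "STEP5"))
  out <- data.frame(
    subject_id = run$subject_id,
    sex = run$sex %||% NA_character_,
    age_years = run$age_years %||% NA_real_,
    age_group = NA_character_,
    training_days = training_days,
    positive_image = run$positive_image,
    bias_image = NA_character_, bias_flag = NA,
    pd_sessions = NA_integer_, pd_trials = NA_integer_,
    pd_response_latency = NA_real_, pd_reward_latency = NA_real_,
    pdr_sessions = NA_integer_, pdr_trials = NA_integer_,
    pdr_response_latency = NA_real_, pdr_reward_latency = NA_real_,
    persev_errors_binomial = NA_integer_, persev_errors_50 = NA_integer_,
    trials_to_50 = NA_integer_,
    pd_reached = FALSE, pdr_reached = FALSE, fifty_reached = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.na(out$age_years)) {
    out$age_group <- if (out$age_years < 5) "young" else "aged"
  }
  pd <- se[se$phase == "PD", , drop = FALSE]
  if (nrow(pd) > 0L) {
    b <- binomial_bias_test(pd$n_correct[1], pd$n_trials[1],
                            p0 = config$chance_p, alpha = config$bias_alpha)
    out$bias_flag <- b$biased
    if (b$biased) {
      neg <- setdiff(run$stimuli %||% c("marble", "fan"),
                     run$positive_image)
      other <- if (length(neg)) neg[1] else NA_character_
      out$bias_image <- if (b$direction == "toward") run$positive_image else other
    }
    cp <- criterion_point(pd$n_correct / pd$n_trials, pd$n_trials,
                          pd$n_trials - pd$n_correct, config)
    out$pd_reached <- cp$reached
    out$pd_sessions <- cp$n_sessions
    out$pd_trials <- cp$n_trials
    lat <- latency_summary(run, "PD", config)
    out$pd_response_latency <- lat$response_latency
    out$pd_reward_latency <- lat$reward_latency
  }
  pdr <- se[se$phase == "PDR", , drop = FALSE]
  if (nrow(pdr) > 0L) {
    cp <- criterion_point(pdr$n_correct / pdr$n_trials, pdr$n_trials,
                          pdr$n_trials - pdr$n_correct, config)
    out$pdr_reached <- cp$reached
    out$pdr_sessions <- cp$n_sessions
    out$pdr_trials <- cp$n_trials
    lat <- latency_summary(run, "PDR", config)
    out$pdr_response_latency <- lat$response_latency
    out$pdr_reward_latency <- lat$reward_latency
    ps <- data.frame(n_trials = pdr$n_trials,
                     n_errors = pdr$n_trials - pdr$n_correct)
    out$persev_errors_binomial <-
      perseveration_binomial(ps, config)$persev_errors_binomial
    fp <- fifty_percent_point(ps, config)
    out$fifty_reached <- fp$reached
    out$trials_to_50 <- fp$trials_to_50
    out$persev_errors_50 <- fp$persev_errors_50
  }
  out
}
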