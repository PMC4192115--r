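#' Default parameter distributions for young and aged subjects
#'
#' Population distributions over [agent_params()] from which cohort members
#' are drawn. Each entry is `c(mean, sd)` of a (clamped) normal draw, except
#' the fixed log-normal shape parameters and the age range. The aged
#' distribution has learning rates about half the young ones, which is what
#' produces slower acquisition, slower reversal and stronger perseveration
#' in the aged group, and slightly slower latencies; everything else is
#' shared. See the package vignette for the reasoning behind the values.
#'
#' @return A named list describing the distribution.
#' @export
young_param_dist <- function() {
  list(alpha_pos = c(0.004, 0.0015), alpha_neg = c(0.004, 0.0015),
       beta = c(6, 1.5), side_bias = c(0, 0.25), lapse = c(0.04, 0.02),
       latency_mu = c(log(4), 0.35), latency_sigma = 0.6,
       reward_latency_mu = c(log(1.5), 0.3), reward_latency_sigma = 0.5,
       age_range = c(1.1, 4.1))
}

#' @rdname young_param_dist
#' @export
aged_param_dist <- function() {
  list(alpha_pos = c(0.002, 0.0008), alpha_neg = c(0.002, 0.0008),
       beta = c(5.5, 1.5), side_bias = c(0, 0.25), lapse = c(0.04, 0.02),
       latency_mu = c(log(5.5), 0.45), latency_sigma = 0.6,
       reward_latency_mu = c(log(1.9), 0.35), reward_latency_sigma = 0.5,
       age_range = c(6.9, 9.5))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_norm <- function(ms) rnorm(1, ms[1], ms[2])

# One parameter draw from a population distribution.
draw_agent_params <- function(dist, p_stim_bias, stim_bias_size,
                              stimuli = c("marble", "fan")) {
  biased <- runif(1) < p_stim_bias
  agent_params(
    alpha_pos = clamp(draw_norm(dist$alpha_pos), 8e-4, 0.08),
    alpha_neg = clamp(draw_norm(dist$alpha_neg), 8e-4, 0.08),
    beta = clamp(draw_norm(dist$beta), 2, 12),
    side_bias = clamp(draw_norm(dist$side_bias), -0.8, 0.8),
    stim_bias = if (biased) stim_bias_size else 0,
    stim_bias_image = if (biased) sample(stimuli, 1) else NA_character_,
    lapse = clamp(draw_norm(dist$lapse), 0.005, 0.15),
    latency_mu = draw_norm(dist$latency_mu),
    latency_sigma = dist$latency_sigma,
    reward_latency_mu = draw_norm(dist$reward_latency_mu),
    reward_latency_sigma = dist$reward_latency_sigma,
    engage0 = runif(1)
  )
}

#' Simulate one animal through the complete protocol
#'
#' Runs a learning agent through habituation, the four interactive training
#' steps, PD and PDR, advancing via [training_advance()] during training and
#' via the two-consecutive-sessions accuracy criterion
#' ([criterion_point()]) in PD/PDR. The reversal starts with the
#' stimulus-reward contingency flipped and the agent's learned values
#' carried over. An agent that never reaches a phase criterion within
#' `session_cap` sessions is truncated (flagged, not an error).
#'
#' @param params an [agent_params()].
#' @param positive_image the PD positive stimulus (counterbalance across a
#'   cohort); the PDR positive stimulus is the other one.
#' @param stimuli the discrimination pair.
#' @param subject_id,sex,age_years metadata stamped on the logs.
#' @param session_cap maximum sessions per phase.
#' @param scoring a [scoring_config()] supplying the PD/PDR criterion.
#' @param keep_trials keep the trial-level log (set `FALSE` for large
#'   simulation studies; session-level summaries always remain).
#' @param keep_events keep per-session event timelines.
#' @param seed optional seed for the whole run.
#'
#' @return A list of class `animal_run`: `sessions` (one row per session),
#'   `trials` (data frame or `NULL`), `params`, `positive_image`,
#'   `truncated` (named logical per phase), metadata and `seed`.
#' @examples
#' run <- simulate_animal(agent_params(alpha_pos = 0.02, alpha_neg = 0.02),
#'                        seed = 1)
#' table(run$sessions$phase)
#' @export
simulate_animal <- function(params, positive_image = "marble",
                            stimuli = c("marble", "fan"),
                            subject_id = "sim", sex = NA_character_,
                            age_years = NA_real_, session_cap = 100L,
                            scoring = scoring_config(), keep_trials = TRUE,
                            keep_events = FALSE, seed = NULL) {
  stopifnot(inherits(params, "agent_params"),
            positive_image %in% stimuli, length(stimuli) == 2L)
  if (!is.null(seed)) set.seed(seed)
  agent <- rl_agent(params, stimuli)
  spec <- schedule_spec()
  sess_rows <- list()
  trial_tabs <- list()
  truncated <- stats::setNames(logical(6),
                               c("STEP2", "STEP3", "STEP4", "STEP5",
                                 "PD", "PDR"))
  add_session <- function(log) {
    sess_rows[[length(sess_rows) + 1L]] <<- data.frame(
      subject_id = subject_id, phase = log$phase,
      session_index = log$session_index, n_trials = log$n_trials,
      n_correct = log$n_correct,
      accuracy = if (log$n_trials > 0) log$n_correct / log$n_trials else NA_real_,
      duration_min = log$duration_min, complete = log$complete,
      sum_response_latency = log$sum_response_latency,
      sum_reward_latency = log$sum_reward_latency,
      n_rewarded = log$n_rewarded, stringsAsFactors = FALSE)
    if (keep_trials && nrow(log$trials) > 0L) {
      trial_tabs[[length(trial_tabs) + 1L]] <<- log$trials
    }
  }
  # STEP1: one 20-minute habituation session, no trials
  sess_rows[[1]] <- data.frame(
    subject_id = subject_id, phase = "STEP1", session_index = 1L,
    n_trials = 0L, n_correct = 0L, accuracy = NA_real_, duration_min = 20,
    complete = TRUE, sum_response_latency = 0, sum_reward_latency = 0,
    n_rewarded = 0L, stringsAsFactors = FALSE)

  for (phase in c("STEP2", "STEP3", "STEP4", "STEP5")) {
    cfg <- task_config(phase)
    hist <- data.frame(n_trials = integer(0), duration_min = numeric(0),
                       accuracy = numeric(0))
    si <- 0L
    repeat {
      si <- si + 1L
      sched <- if (cfg$scheduled) generate_side_sequence(spec) else NULL
      log <- run_session(cfg, agent, sched, subject_id = subject_id,
                         session_index = si, keep_events = keep_events)
      add_session(log)
      hist <- rbind(hist, data.frame(
        n_trials = log$n_trials, duration_min = log$duration_min,
        accuracy = if (log$n_trials > 0) log$n_correct / log$n_trials else 0))
      if (training_advance(phase, hist, cfg) == "advance") break
      if (si >= session_cap) { truncated[[phase]] <- TRUE; break }
    }
  }

  negative_image <- setdiff(stimuli, positive_image)[1]
  for (phase in c("PD", "PDR")) {
    cfg <- task_config(phase)
    pos <- if (phase == "PD") positive_image else negative_image
    neg <- if (phase == "PD") negative_image else positive_image
    acc <- numeric(0); cnt <- integer(0); err <- integer(0)
    si <- 0L
    repeat {
      si <- si + 1L
      sched <- generate_side_sequence(spec)
      log <- run_session(cfg, agent, sched, positive_stimulus = pos,
                         negative_stimulus = neg, subject_id = subject_id,
                         session_index = si, keep_events = keep_events)
      add_session(log)
      acc <- c(acc, if (log$n_trials > 0) log$n_correct / log$n_trials else 0)
      cnt <- c(cnt, log$n_trials)
      err <- c(err, log$n_trials - log$n_correct)
      if (criterion_point(acc, cnt, err, scoring)$reached) break
      if (si >= session_cap) { truncated[[phase]] <- TRUE; break }
    }
  }

  structure(list(
    subject_id = subject_id, sex = sex, age_years = age_years,
    positive_image = positive_image, stimuli = stimuli, params = params,
    sessions = do.call(rbind, sess_rows),
    trials = if (keep_trials && length(trial_tabs)) {
      do.call(rbind, trial_tabs)
    },
    truncated = truncated, seed = seed
  ), class = "animal_run")
}

#' Cohort specification
#'
#' Describes a simulated young/aged cohort: group sizes, the population
#' parameter distributions, the stimulus-bias mixture and the master seed.
#' Defaults mirror the design of the touchscreen aging study the package
#' models: 20 young and 10 aged subjects, a roughly one-in-five chance of a
#' spontaneous image bias, and aged learning rates about half the young
#' ones.
#'
#' @param n_young,n_aged group sizes (>= 0).
#' @param young,aged population distributions (see [young_param_dist()]).
#' @param p_stim_bias probability that a subject carries an initial image
#'   bias.
#' @param stim_bias_size value offset of a carried image bias.
#' @param seed master seed; every derived per-animal seed is a function of
#'   it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 20L, n_aged = 10L,
                        young = young_param_dist(),
                        aged = aged_param_dist(),
                        p_stim_bias = 0.2, stim_bias_size = 0.4,
                        seed = 1L) {
  stopifnot(n_young >= 0, n_aged >= 0,
            p_stim_bias >= 0, p_stim_bias <= 1)
  structure(list(n_young = as.integer(n_young), n_aged = as.integer(n_aged),
                 young = young, aged = aged, p_stim_bias = p_stim_bias,
                 stim_bias_size = stim_bias_size, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a complete young/aged cohort
#'
#' Draws subjects from the cohort specification, simulates each through the
#' full protocol ([simulate_animal()]) and scores it
#' ([summarize_animal()]). Sexes alternate within each group and the PD
#' positive image is counterbalanced across consecutive subjects. The run
#' is fully reproducible from the spec's master seed, and the manifest
#' records every subject's true parameters and derived seed.
#'
#' @param spec a [cohort_spec()].
#' @param keep_trials retain trial-level logs for every subject (memory
#'   heavy; defaults to session-level logs only).
#' @param scoring a [scoring_config()].
#' @return A list of class `cohort`: `summaries` (one row per animal),
#'   `sessions`, `trials` (or `NULL`), `manifest` (parameters, seeds,
#'   truncation flags) and the `spec`.
#' @examples
#' co <- make_cohort(cohort_spec(n_young = 2, n_aged = 1, seed = 42))
#' co$summaries[, c("subject_id", "age_group", "pd_trials", "pdr_trials")]
#' @export
make_cohort <- function(spec = cohort_spec(), keep_trials = FALSE,
                        scoring = scoring_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_young + spec$n_aged
  groups <- rep(c("young", "aged"), c(spec$n_young, spec$n_aged))
  ids <- c(sprintf("Y%02d", seq_len(spec$n_young)),
           sprintf("A%02d", seq_len(spec$n_aged)))
  stimuli <- c("marble", "fan")
  if (n == 0L) {
    return(structure(list(summaries = data.frame(), sessions = data.frame(),
                          trials = NULL,
                          manifest = list(spec = spec, animals = data.frame()),
                          spec = spec), class = "cohort"))
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  params <- vector("list", n)
  ages <- numeric(n); sexes <- character(n); pos_img <- character(n)
  for (i in seq_len(n)) {
    dist <- if (groups[i] == "young") spec$young else spec$aged
    params[[i]] <- draw_agent_params(dist, spec$p_stim_bias,
                                     spec$stim_bias_size, stimuli)
    ages[i] <- runif(1, dist$age_range[1], dist$age_range[2])
    within <- sum(groups[seq_len(i)] == groups[i])
    sexes[i] <- if (within %% 2L == 1L) "m" else "f"
    pos_img[i] <- stimuli[(i - 1L) %% 2L + 1L]
  }
  summaries <- vector("list", n)
  sessions <- vector("list", n)
  trials <- if (keep_trials) vector("list", n)
  trunc_any <- logical(n)
  for (i in seq_len(n)) {
    run <- simulate_animal(params[[i]], positive_image = pos_img[i],
                           stimuli = stimuli, subject_id = ids[i],
                           sex = sexes[i], age_years = ages[i],
                           scoring = scoring, keep_trials = keep_trials,
                           seed = seeds[i])
    summaries[[i]] <- summarize_animal(run, scoring)
    sessions[[i]] <- run$sessions
    if (keep_trials) trials[[i]] <- run$trials
    trunc_any[i] <- any(run$truncated)
  }
  par_df <- do.call(rbind, lapply(params, function(p) {
    as.data.frame(p[c("alpha_pos", "alpha_neg", "beta", "side_bias",
                      "stim_bias", "stim_bias_image", "lapse", "latency_mu",
                      "latency_sigma", "reward_latency_mu",
                      "reward_latency_sigma", "engage0")],
                  stringsAsFactors = FALSE)
  }))
  manifest <- list(
    master_seed = spec$seed,
    animals = cbind(data.frame(subject_id = ids, group = groups, sex = sexes,
                               age_years = ages, positive_image = pos_img,
                               seed = seeds, truncated = trunc_any,
                               stringsAsFactors = FALSE),
                    par_df))
  structure(list(summaries = do.call(rbind, summaries),
                 sessions = do.call(rbind, sessions),
                 trials = if (keep_trials) do.call(rbind, trials),
                 manifest = manifest, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Simulated touchscreen cohort:", x$spec$n_young, "young /",
      x$spec$n_aged, "aged (master seed", x$spec$seed, ")\n")
  if (nrow(x$summaries)) {
    cat("  PD trials to criterion, young median:",
        median(x$summaries$pd_trials[x$summaries$age_group == "young"],
               na.rm = TRUE),
        "; aged median:",
        median(x$summaries$pd_trials[x$summaries$age_group == "aged"],
               na.rm = TRUE), "\n")
    cat("  truncated runs:", sum(x$manifest$animals$truncated), "\n")
  }
  invisible(x)
}
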