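PHASES <- c("STEP1", "STEP2", "STEP3", "STEP4", "STEP5", "PD", "PDR")

#' Per-phase task configuration
#'
#' Returns the protocol parameters of one phase of the staged touchscreen
#' protocol. The training ladder is: STEP1 habituation (one 20-minute free
#' session); STEP2 initial image training (two identical images, touch is
#' rewarded with 75 ul, otherwise an automatic 25 ul reward after the 30 s
#' stimulus timeout); STEP3 "must touch" (one image vs. a blank window, the
#' trial only ends on an image touch); STEP4 adds trial initiation by a
#' reward-tray entry; STEP5 signals incorrect (blank) touches with a 500 ms
#' 2000 Hz tone, ends the trial and lengthens the inter-trial interval to
#' 15 s. PD/PDR use the same contingencies as STEP5 with a two-stimulus
#' discrimination.
#'
#' @param phase one of `"STEP1"`, ..., `"STEP5"`, `"PD"`, `"PDR"`.
#' @param session_cap_trials,session_cap_minutes session caps; a session ends
#'   at whichever is reached first.
#' @param accuracy_criterion,criterion_window the advancement criterion for
#'   STEP5/PD/PDR: accuracy at or above `accuracy_criterion` in
#'   `criterion_window` consecutive sessions.
#'
#' @return A list of class `task_config`.
#' @examples
#' task_config("PD")$iti_incorrect # 15 s after an error
#' @export
task_config <- function(phase, session_cap_trials = 30L,
                        session_cap_minutes = 30,
                        accuracy_criterion = 0.80, criterion_window = 2L) {
  phase <- match.arg(phase, PHASES)
  stopifnot(accuracy_criterion > 0, accuracy_criterion <= 1,
            criterion_window >= 1, session_cap_minutes > 0,
            session_cap_trials >= 1)
  structure(list(
    phase = phase,
    iti_correct = 10,
    iti_incorrect = if (phase %in% c("STEP5", "PD", "PDR")) 15 else 10,
    stimulus_timeout = if (phase == "STEP2") 30 else NA_real_,
    session_cap_trials = as.integer(session_cap_trials),
    session_cap_minutes = session_cap_minutes,
    accuracy_criterion = accuracy_criterion,
    criterion_window = as.integer(criterion_window),
    reward_touch_ul = if (phase == "STEP2") 75 else 25,
    reward_auto_ul = if (phase == "STEP2") 25 else NA_real_,
    tone_hz = 2000, tone_ms = 500,
    # STEP2 has two completion routes: 30 trials within 20 minutes in a
    # single session (active screen interaction), or 30 trials within the
    # 30-minute cap in 3 consecutive sessions (passive reward collection).
    step2_fast_minutes = 20,
    step2_slow_sessions = 3L,
    requires_initiation = phase %in% c("STEP4", "STEP5", "PD", "PDR"),
    scheduled = phase %in% c("STEP3", "STEP4", "STEP5", "PD", "PDR")
  ), class = "task_config")
}

#' The default training picture pool
#'
#' Thirty-eight distinct training pictures; each can be drawn at most once
#' per session.
#' @return Character vector of picture identifiers.
#' @export
default_stimulus_pool <- function() sprintf("train%02d", 1:38)

#' Run one simulated session
#'
#' Plays one daily session of the given phase against an agent and returns
#' the complete trial log together with a simulated session clock. The agent
#' is a list with an `act(info)` function and an optional `learn(info,
#' outcome)` function (see Details); scripted agents for testing are built
#' with [scripted_agent()], learning agents with [rl_agent()].
#'
#' The simulated clock accumulates, per trial: the trial-initiation latency
#' (STEP4 onward), the response latency (or the 30 s stimulus timeout in
#' STEP2), the reward-collection latency on rewarded trials, and the
#' inter-trial interval (10 s, or 15 s after an incorrect response in
#' STEP5/PD/PDR, where errors are also marked by a tone event). The session
#' ends when `session_cap_trials` trials are completed or when the response
#' of a trial would fall beyond `session_cap_minutes`; such a partial trial
#' is discarded and the session duration is the cap.
#'
#' `info` passed to the agent holds `phase`, `trial_index`, `rewarded_side`,
#' `left_stimulus`, `right_stimulus` and `positive_stimulus`. `act()` must
#' return a list with, depending on the phase: STEP2 `touch` (logical),
#' `response_latency`, `reward_latency`; STEP3/STEP4 `blank_touches`,
#' `response_latency` (total time until the image touch), `reward_latency`;
#' STEP5 `choice` (`"image"` or `"blank"`); PD/PDR `choice` (a stimulus
#' name); choice phases also use `response_latency`, `reward_latency` and,
#' from STEP4 on, `initiation_latency`. `learn()`, when present, receives
#' the outcome (`chosen_stimulus`, `correct`, `reward`).
#'
#' @param config a [task_config()].
#' @param agent the agent (list with `act`, optionally `learn`).
#' @param schedule side sequence from [generate_side_sequence()]; required
#'   for STEP3 onward and at least `session_cap_trials` long.
#' @param positive_stimulus,negative_stimulus the discrimination pair
#'   (PD/PDR). For a reversal session pass the reversed roles.
#' @param stimulus_pool training picture pool for STEP2--STEP5.
#' @param subject_id,session_index identifiers stamped on the log.
#' @param keep_events if `TRUE`, an event timeline (stimulus onsets, touches,
#'   tones, rewards, ITIs) is retained; the session duration equals the time
#'   of its final event.
#'
#' @return A list of class `session_log` with elements `trials` (data frame,
#'   one row per completed trial), `events` (data frame or `NULL`),
#'   `n_trials`, `n_correct`, `duration_min`, `complete`, and latency sums.
#' @examples
#' cfg <- task_config("PD")
#' sched <- generate_side_sequence(schedule_spec(), seed = 1)
#' ag <- scripted_agent(choices = rep("positive", 30))
#' s <- run_session(cfg, ag, sched)
#' s$n_correct / s$n_trials # 1
#' @export
run_session <- function(config, agent, schedule = NULL,
                        positive_stimulus = "marble",
                        negative_stimulus = "fan",
                        stimulus_pool = default_stimulus_pool(),
                        subject_id = "sim", session_index = 1L,
                        keep_events = TRUE) {
  stopifnot(inherits(config, "task_config"), is.function(agent$act))
  phase <- config$phase
  if (phase == "STEP1") stop("STEP1 has no trial loop; record it directly")
  cap_n <- config$session_cap_trials
  cap_s <- config$session_cap_minutes * 60

  if (config$scheduled) {
    if (is.null(schedule)) stop("phase ", phase, " requires a side schedule")
    if (length(schedule) < cap_n) {
      stop("schedule has ", length(schedule), " entries; ", cap_n, " needed")
    }
  }
  if (phase %in% c("STEP2", "STEP3", "STEP4", "STEP5")) {
    if (length(stimulus_pool) < cap_n) {
      stop("stimulus pool smaller than the session cap")
    }
    session_images <- sample(stimulus_pool, cap_n)
  }

  rewarded_side <- chosen <- pos_stim <- character(cap_n)
  correct <- logical(cap_n)
  resp_lat <- rew_lat <- numeric(cap_n)
  blank_touches <- integer(cap_n)
  reward_ul <- numeric(cap_n)
  initiated <- rep(if (config$requires_initiation) TRUE else NA, cap_n)

  ev_trial <- integer(0); ev_time <- numeric(0); ev_name <- character(0)
  add_event <- function(i, t, name) {
    if (keep_events) {
      ev_trial[[length(ev_trial) + 1L]] <<- i
      ev_time[[length(ev_time) + 1L]] <<- t
      ev_name[[length(ev_name) + 1L]] <<- name
    }
  }

  clock <- 0
  n_done <- 0L
  complete <- TRUE
  for (i in seq_len(cap_n)) {
    if (clock >= cap_s) { complete <- FALSE; break }
    if (phase %in% c("PD", "PDR")) {
      side <- schedule[[i]]
      left_stim <- if (side == "left") positive_stimulus else negative_stimulus
      right_stim <- if (side == "left") negative_stimulus else positive_stimulus
      pos <- positive_stimulus
    } else if (phase == "STEP2") {
      side <- NA_character_
      left_stim <- right_stim <- pos <- session_images[[i]]
    } else {
      side <- schedule[[i]]
      pos <- session_images[[i]]
      left_stim <- if (side == "left") pos else "blank"
      right_stim <- if (side == "left") "blank" else pos
    }
    info <- list(phase = phase, trial_index = i, rewarded_side = side,
                 left_stimulus = left_stim, right_stimulus = right_stim,
                 positive_stimulus = pos)
    res <- agent$act(info)

    if (config$requires_initiation) {
      clock <- clock + max(0, res$initiation_latency %||% 0)
    }
    onset <- clock
    add_event(i, onset, "stimulus_onset")

    if (phase == "STEP2") {
      touched <- isTRUE(res$touch)
      rl <- if (touched) res$response_latency else config$stimulus_timeout
      t_resp <- onset + rl
      if (t_resp > cap_s) { complete <- FALSE; break }
      add_event(i, t_resp, if (touched) "touch" else "timeout_auto_reward")
      clock <- t_resp + res$reward_latency
      add_event(i, clock, "reward_collected")
      n_done <- i
      chosen[i] <- if (touched) pos else "NONE"
      correct[i] <- touched
      resp_lat[i] <- rl
      rew_lat[i] <- res$reward_latency
      reward_ul[i] <- if (touched) config$reward_touch_ul else config$reward_auto_ul
      rewarded_side[i] <- NA_character_
      pos_stim[i] <- pos
      iti <- config$iti_correct
    } else if (phase %in% c("STEP3", "STEP4")) {
      nb <- as.integer(res$blank_touches %||% 0L)
      t_resp <- onset + res$response_latency
      if (t_resp > cap_s) { complete <- FALSE; break }
      if (nb > 0L) add_event(i, t_resp, paste0("blank_touches_", nb))
      add_event(i, t_resp, "touch_image")
      clock <- t_resp + res$reward_latency
      add_event(i, clock, "reward_collected")
      n_done <- i
      chosen[i] <- pos
      correct[i] <- nb == 0L
      blank_touches[i] <- nb
      resp_lat[i] <- res$response_latency
      rew_lat[i] <- res$reward_latency
      reward_ul[i] <- config$reward_touch_ul
      rewarded_side[i] <- side
      pos_stim[i] <- pos
      iti <- config$iti_correct
    } else { # STEP5 / PD / PDR
      ch <- res$choice
      valid <- if (phase == "STEP5") c(pos, "blank") else c(left_stim, right_stim)
      if (phase == "STEP5" && identical(ch, "image")) ch <- pos
      if (!ch %in% valid) {
        stop("agent chose '", ch, "', not on screen (",
             paste(valid, collapse = ", "), ")")
      }
      t_resp <- onset + res$response_latency
      if (t_resp > cap_s) { complete <- FALSE; break }
      ok <- identical(ch, pos)
      add_event(i, t_resp, "touch")
      if (ok) {
        clock <- t_resp + res$reward_latency
        add_event(i, clock, "reward_collected")
      } else {
        add_event(i, t_resp, "tone")
        clock <- t_resp
      }
      n_done <- i
      chosen[i] <- ch
      correct[i] <- ok
      resp_lat[i] <- res$response_latency
      rew_lat[i] <- if (ok) res$reward_latency else NA_real_
      reward_ul[i] <- if (ok) config$reward_touch_ul else 0
      rewarded_side[i] <- side
      pos_stim[i] <- pos
      iti <- if (ok) config$iti_correct else config$iti_incorrect
      if (is.function(agent$learn)) {
        agent$learn(info, list(chosen_stimulus = ch, correct = ok,
                               reward = as.numeric(ok)))
      }
    }
    if (phase %in% c("STEP2", "STEP3", "STEP4") && is.function(agent$learn)) {
      agent$learn(info, list(chosen_stimulus = chosen[i],
                             correct = correct[i], reward = 1))
    }
    add_event(i, clock, sprintf("iti_%g", iti))
    clock <- clock + iti
  }

  duration_min <- if (complete) clock / 60 else config$session_cap_minutes
  add_event(n_done, duration_min * 60, "session_end")

  idx <- seq_len(n_done)
  trials <- data.frame(
    subject_id = rep(subject_id, n_done),
    phase = rep(phase, n_done),
    session_index = rep(as.integer(session_index), n_done),
    trial_index = idx,
    rewarded_side = rewarded_side[idx],
    positive_stimulus = pos_stim[idx],
    chosen_stimulus = chosen[idx],
    correct = correct[idx],
    initiated = initiated[idx],
    n_blank_touches = blank_touches[idx],
    response_latency = resp_lat[idx],
    reward_latency = rew_lat[idx],
    reward_ul = reward_ul[idx],
    stringsAsFactors = FALSE
  )
  structure(list(
    trials = trials,
    events = if (keep_events) {
      data.frame(trial_index = ev_trial, time_s = ev_time, event = ev_name,
                 stringsAsFactors = FALSE)
    },
    subject_id = subject_id, phase = phase,
    session_index = as.integer(session_index),
    n_trials = n_done,
    n_correct = sum(correct[idx]),
    duration_min = duration_min,
    complete = n_done == cap_n,
    sum_response_latency = sum(resp_lat[idx]),
    sum_reward_latency = sum(rew_lat[idx], na.rm = TRUE),
    n_rewarded = sum(!is.na(rew_lat[idx]))
  ), class = "session_log")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training-step advancement decision
#'
#' Decides, from the history of sessions of the current training step,
#' whether the animal advances to the next step or repeats. Rules:
#' STEP1 advances after one session. STEP2 advances when one session holds
#' 30 trials within 20 minutes (active-interaction route) or when 3
#' consecutive sessions each hold 30 trials within 30 minutes
#' (passive-collection route). STEP3 and STEP4 advance when the last session
#' holds 30 trials in under 30 minutes. STEP5 advances when the last two
#' sessions each hold 30 trials within 30 minutes at accuracy of at least
#' 80 percent.
#'
#' @param phase the current training step (`"STEP1"` ... `"STEP5"`).
#' @param history data frame with one row per session of this step, columns
#'   `n_trials`, `duration_min`, `accuracy`, in session order.
#' @param config the step's [task_config()].
#'
#' @return `"advance"` or `"repeat"`.
#' @examples
#' h <- data.frame(n_trials = 30, duration_min = 18, accuracy = NA)
#' training_advance("STEP2", h) # "advance" (30 trials within 20 minutes)
#' @export
training_advance <- function(phase, history, config = task_config(phase)) {
  phase <- match.arg(phase, PHASES[1:5])
  if (is.null(history) || nrow(history) == 0L) {
    stop("empty session history")
  }
  n <- nrow(history)
  full <- history$n_trials >= config$session_cap_trials
  within_cap <- history$duration_min <= config$session_cap_minutes
  last <- n
  dec <- switch(phase,
    STEP1 = TRUE,
    STEP2 = {
      fast <- any(full & history$duration_min <= config$step2_fast_minutes)
      k <- config$step2_slow_sessions
      slow <- n >= k && all((full & within_cap)[(n - k + 1L):n])
      fast || slow
    },
    STEP3 = ,
    STEP4 = full[last] && history$duration_min[last] < config$session_cap_minutes,
    STEP5 = {
      w <- config$criterion_window
      n >= w && all((full & within_cap &
                       history$accuracy >= config$accuracy_criterion)[(n - w + 1L):n])
    }
  )
  if (dec) "advance" else "repeat"
}

#' Scripted agent for testing and worked examples
#'
#' Deterministic agent whose behavior is given directly: per-trial choices
#' and fixed latencies. Choices are symbolic: for PD/PDR use `"positive"` /
#' `"negative"`, for STEP5 `"image"` / `"blank"`; values are recycled over
#' trials. For STEP2 set `touch` (recycled); `touch = FALSE` emulates the
#' passive animal that waits out the 30 s stimulus timeout for the automatic
#' reward.
#'
#' @param choices symbolic choice vector, recycled.
#' @param touch logical vector for STEP2, recycled.
#' @param blank_touches integer vector for STEP3/STEP4, recycled.
#' @param response_latency,reward_latency,initiation_latency fixed latencies
#'   in seconds.
#' @return An agent list usable with [run_session()].
#' @export
scripted_agent <- function(choices = "positive", touch = TRUE,
                           blank_touches = 0L, response_latency = 1,
                           reward_latency = 1, initiation_latency = 0) {
  act <- function(info) {
    i <- info$trial_index
    pick <- function(v) v[[(i - 1L) %% length(v) + 1L]]
    ch <- switch(pick(choices),
      positive = info$positive_stimulus,
      negative = setdiff(c(info$left_stimulus, info$right_stimulus),
                         info$positive_stimulus)[1],
      image = info$positive_stimulus,
      blank = "blank",
      pick(choices)
    )
    list(choice = ch, touch = pick(touch),
         blank_touches = pick(blank_touches),
         response_latency = response_latency,
         reward_latency = reward_latency,
         initiation_latency = initiation_latency)
  }
  list(act = act, learn = NULL)
}
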