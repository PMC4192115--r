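#' Parameters of a simulated subject
#'
#' The behavioral model behind the cohort simulator is a two-learning-rate
#' delta rule with logistic (softmax) choice: after choosing stimulus `c`
#' and receiving reward `r` (0/1), `V_c <- V_c + alpha * (r - V_c)` with
#' `alpha = alpha_pos` on rewarded and `alpha_neg` on unrewarded outcomes;
#' the probability of choosing stimulus A over B is a lapse-mixed logistic,
#' `P(A) = lapse/2 + (1 - lapse) * plogis(beta * (V_A - V_B) +
#' side_bias * s)` with `s = +1` when A is on the left. `alpha_neg = 0`
#' makes learned values immune to errors (pure perseverance).
#'
#' Latencies are log-normal: response latency `exp(N(latency_mu,
#' latency_sigma))`; reward-collection latency (drawn only on rewarded
#' trials) and the tray-entry trial-initiation latency both use
#' `reward_latency_mu/sigma`, since both are visits to the reward tray.
#'
#' `stim_bias` is an initial value offset carried by `stim_bias_image`
#' before the first PD session, producing a spontaneous preference or
#' aversion detectable by the first-session binomial screen. `alpha_train`
#' is the learning rate of the (perceptually trivial) image-versus-blank
#' training discrimination; it is common to both age groups. `engage0` is
#' the initial propensity to interact with the screen in STEP2.
#'
#' @param alpha_pos,alpha_neg learning rates, `alpha_pos` in (0, 1],
#'   `alpha_neg` in \[0, 1\].
#' @param beta choice inverse temperature (> 0).
#' @param side_bias additive left-side bias on the logit scale.
#' @param stim_bias,stim_bias_image initial value offset and the image
#'   carrying it (`NA` for none).
#' @param lapse probability of a uniformly random choice, in \[0, 0.5).
#' @param latency_mu,latency_sigma log-normal response-latency parameters.
#' @param reward_latency_mu,reward_latency_sigma log-normal parameters for
#'   reward collection and trial initiation.
#' @param alpha_train training-step learning rate.
#' @param engage0 initial STEP2 screen-engagement value, in \[0, 1\].
#'
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha_pos = 0.006, alpha_neg = 0.006, beta = 6,
                         side_bias = 0, stim_bias = 0,
                         stim_bias_image = NA_character_, lapse = 0.03,
                         latency_mu = log(4), latency_sigma = 0.6,
                         reward_latency_mu = log(1.5),
                         reward_latency_sigma = 0.5,
                         alpha_train = 0.25, engage0 = 0.5) {
  stopifnot(alpha_pos > 0, alpha_pos <= 1,
            alpha_neg >= 0, alpha_neg <= 1,
            beta > 0, lapse >= 0, lapse < 0.5,
            alpha_train > 0, alpha_train <= 1,
            engage0 >= 0, engage0 <= 1,
            latency_sigma > 0, reward_latency_sigma > 0)
  structure(as.list(environment()), class = "agent_params")
}

#' Logistic choice between two stimuli
#'
#' Pure choice rule of the simulated subject: with probability `lapse` the
#' choice is uniform, otherwise the first stimulus is chosen with
#' probability `plogis(beta * (V_A - V_B) + side_bias * s)` where `s` is +1
#' if the first stimulus is on the left and -1 otherwise.
#'
#' @param values named numeric of length 2, learned values with the first
#'   element as stimulus A.
#' @param side_of_a `"left"` or `"right"`, the side stimulus A occupies.
#' @param params an [agent_params()].
#'
#' @return List with `p_a` (probability of choosing A), `choice` (a name of
#'   `values`) and `response_latency` (log-normal draw).
#' @examples
#' set.seed(1)
#' agent_choose(c(marble = 0.5, fan = 0.5), "left", agent_params())$p_a
#' @export
agent_choose <- function(values, side_of_a = "left", params = agent_params()) {
  stopifnot(length(values) == 2L)
  s <- if (identical(side_of_a, "left")) 1 else -1
  p_a <- params$lapse / 2 + (1 - params$lapse) *
    plogis(params$beta * (values[[1]] - values[[2]]) + params$side_bias * s)
  pick <- if (runif(1) < p_a) 1L else 2L
  list(p_a = unname(p_a), choice = names(values)[pick],
       response_latency = rlnorm(1, params$latency_mu, params$latency_sigma))
}

#' Delta-rule value update
#'
#' Updates the value of the chosen stimulus toward the obtained reward with
#' learning rate `alpha_pos` (rewarded) or `alpha_neg` (unrewarded); the
#' unchosen value is unchanged.
#'
#' @param values named numeric of learned values.
#' @param chosen name of the chosen stimulus (must be in `values`).
#' @param reward 0 or 1.
#' @param params an [agent_params()].
#' @return The updated `values`.
#' @examples
#' agent_update(c(a = 0.5, b = 0), "a", 1, agent_params(alpha_pos = 0.2))
#' @export
agent_update <- function(values, chosen, reward, params) {
  if (!chosen %in% names(values)) stop("chosen stimulus not among values")
  alpha <- if (reward > 0) params$alpha_pos else params$alpha_neg
  values[[chosen]] <- values[[chosen]] + alpha * (reward - values[[chosen]])
  values
}

#' Learning agent for the full protocol
#'
#' Builds a stateful agent implementing the delta-rule/logistic model of
#' [agent_params()] across all phases. Internal state: a screen-engagement
#' value (STEP2), an image value for the image-versus-blank training
#' discrimination (STEP3--STEP5), and one value per discrimination stimulus
#' (PD/PDR). Values persist across sessions and across the PD-to-PDR
#' reversal (no reset), which is what produces below-chance accuracy in the
#' first reversal session. `stim_bias` is applied once to
#' `stim_bias_image`'s initial value.
#'
#' In STEP3/STEP4 (trial ends only on an image touch) the number of blank
#' touches preceding the image touch is geometric in the image-choice
#' probability, and the response latency is the sum of one log-normal draw
#' per touch.
#'
#' @param params an [agent_params()].
#' @param stimuli the discrimination pair.
#' @return An agent list (`act`, `learn`, `state`) for [run_session()].
#' @export
rl_agent <- function(params, stimuli = c("marble", "fan")) {
  state <- new.env(parent = emptyenv())
  state$v_engage <- params$engage0
  state$v_image <- 0
  state$values <- stats::setNames(numeric(2), stimuli)
  if (!is.na(params$stim_bias_image) && params$stim_bias != 0) {
    state$values[[params$stim_bias_image]] <- params$stim_bias
  }
  lat <- function() rlnorm(1, params$latency_mu, params$latency_sigma)
  tray <- function() rlnorm(1, params$reward_latency_mu,
                            params$reward_latency_sigma)
  mix <- function(p) params$lapse / 2 + (1 - params$lapse) * p

  act <- function(info) {
    phase <- info$phase
    if (phase == "STEP2") {
      p_touch <- plogis(6 * (state$v_engage - 0.4))
      touched <- runif(1) < p_touch
      return(list(touch = touched, response_latency = lat(),
                  reward_latency = tray()))
    }
    s <- if (identical(info$rewarded_side, "left")) 1 else -1
    p_img <- mix(plogis(params$beta * (state$v_image - 0) +
                          params$side_bias * s))
    if (phase %in% c("STEP3", "STEP4")) {
      nb <- min(rgeom(1, p_img), 10L)
      return(list(blank_touches = nb,
                  response_latency = sum(rlnorm(nb + 1L, params$latency_mu,
                                                params$latency_sigma)),
                  reward_latency = tray(), initiation_latency = tray()))
    }
    if (phase == "STEP5") {
      return(list(choice = if (runif(1) < p_img) "image" else "blank",
                  response_latency = lat(), reward_latency = tray(),
                  initiation_latency = tray()))
    }
    # PD / PDR: choose between the two displayed stimuli
    vl <- state$values[[info$left_stimulus]]
    vr <- state$values[[info$right_stimulus]]
    p_left <- mix(plogis(params$beta * (vl - vr) + params$side_bias))
    ch <- if (runif(1) < p_left) info$left_stimulus else info$right_stimulus
    list(choice = ch, response_latency = lat(), reward_latency = tray(),
         initiation_latency = tray())
  }

  learn <- function(info, outcome) {
    phase <- info$phase
    if (phase == "STEP2") {
      if (outcome$chosen_stimulus != "NONE") {
        state$v_engage <- state$v_engage +
          params$alpha_train * (1 - state$v_engage)
      }
    } else if (phase %in% c("STEP3", "STEP4", "STEP5")) {
      if (outcome$correct || phase %in% c("STEP3", "STEP4")) {
        # the trial ends on an image touch (always rewarded)
        state$v_image <- state$v_image +
          params$alpha_train * (1 - state$v_image)
      }
    } else {
      state$values <- agent_update(state$values, outcome$chosen_stimulus,
                                   outcome$reward, params)
    }
    invisible(NULL)
  }
  list(act = act, learn = learn, state = state)
}
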