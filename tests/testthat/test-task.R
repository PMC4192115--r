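pd_schedule <- function(seed = 1) generate_side_sequence(seed = seed)

test_that("an always-correct PD session matches the hand-computed clock", {
  cfg <- task_config("PD")
  ag <- scripted_agent(choices = "positive", response_latency = 1,
                       reward_latency = 1, initiation_latency = 0)
  set.seed(1)
  s <- run_session(cfg, ag, pd_schedule())
  expect_equal(s$n_trials, 30L)
  expect_equal(s$n_correct, 30L)
  # 30 trials x (1 s response + 1 s reward collection + 10 s ITI)
  expect_equal(s$duration_min, 30 * 12 / 60)
  expect_true(s$complete)
  # replaying the event log reproduces the duration
  expect_equal(max(s$events$time_s) / 60, s$duration_min)
  # completed sessions carry the scheduled side balance
  expect_equal(sum(s$trials$rewarded_side == "left"), 15L)
  expect_lte(max_side_run(s$trials$rewarded_side), 3L)
})

test_that("incorrect PD trials get a tone event and the 15 s ITI", {
  cfg <- task_config("PD")
  ag <- scripted_agent(choices = c("positive", "negative"))
  set.seed(1)
  s <- run_session(cfg, ag, pd_schedule())
  expect_equal(s$n_correct / s$n_trials, 0.5)
  expect_equal(sum(s$events$event == "tone"), 15L)
  expect_equal(sum(s$events$event == "iti_15"), 15L)
  expect_equal(sum(s$events$event == "iti_10"), 15L)
  bad <- s$trials[!s$trials$correct, ]
  expect_true(all(is.na(bad$reward_latency)))
  expect_true(all(!is.na(s$trials$reward_latency[s$trials$correct])))
  # duration: 15 correct cycles of 12 s + 15 incorrect cycles of 1 + 15 s
  expect_equal(s$duration_min, (15 * 12 + 15 * 16) / 60)
})

test_that("a never-touching STEP2 session follows the stated timeline", {
  cfg <- task_config("STEP2")
  ag <- scripted_agent(touch = FALSE, reward_latency = 2)
  set.seed(1)
  s <- run_session(cfg, ag)
  expect_equal(s$n_trials, 30L)
  expect_true(all(s$trials$chosen_stimulus == "NONE"))
  expect_true(all(s$trials$reward_ul == 25))
  # hand-simulated: each cycle is 30 s timeout + 2 s collection + 10 s ITI
  cycle <- 42
  expect_equal(s$duration_min, 30 * cycle / 60)
  onsets <- s$events$time_s[s$events$event == "stimulus_onset"]
  expect_equal(onsets, (0:29) * cycle)
  autos <- s$events$time_s[s$events$event == "timeout_auto_reward"]
  expect_equal(autos, (0:29) * cycle + 30)
  rewards <- s$events$time_s[s$events$event == "reward_collected"]
  expect_equal(rewards, (0:29) * cycle + 32)
})

test_that("the 30-minute cap ends the session and discards the partial trial", {
  cfg <- task_config("PD")
  ag <- scripted_agent(choices = "positive", response_latency = 120,
                       reward_latency = 1)
  set.seed(1)
  s <- run_session(cfg, ag, pd_schedule())
  # cycle 131 s; trial k responds at (k-1)*131 + 120 <= 1800 for k <= 13
  expect_equal(s$n_trials, 13L)
  expect_false(s$complete)
  expect_equal(s$duration_min, 30)
})

test_that("run_session validates schedule and agent output", {
  cfg <- task_config("PD")
  ag <- scripted_agent()
  expect_error(run_session(cfg, ag, rep("left", 10)), "schedule has")
  expect_error(run_session(cfg, ag, NULL), "requires a side schedule")
  rogue <- list(act = function(info) {
    list(choice = "bogus", response_latency = 1, reward_latency = 1,
         initiation_latency = 0)
  })
  expect_error(run_session(cfg, rogue, pd_schedule()), "not on screen")
})

test_that("training advancement follows the per-step rules", {
  h <- function(n, d, a = NA_real_) {
    data.frame(n_trials = n, duration_min = d, accuracy = a)
  }
  empty <- data.frame(n_trials = integer(0), duration_min = numeric(0),
                      accuracy = numeric(0))
  expect_error(training_advance("STEP2", empty), "empty session history")
  # STEP2, active route: 30 trials within 20 minutes
  expect_equal(training_advance("STEP2", h(30, 18)), "advance")
  expect_equal(training_advance("STEP2", h(30, 25)), "repeat")
  # STEP2, passive route: 3 consecutive 30-trial sessions within 30 minutes
  expect_equal(training_advance("STEP2", h(c(30, 30), c(21, 21))), "repeat")
  expect_equal(training_advance("STEP2", h(c(30, 30, 30), c(21, 21, 21))),
               "advance")
  expect_equal(training_advance("STEP2", h(c(30, 12, 30, 30),
                                           c(21, 30, 21, 21))), "repeat")
  # STEP3/STEP4: last session with 30 trials in under 30 minutes
  expect_equal(training_advance("STEP3", h(c(20, 30), c(30, 29))), "advance")
  expect_equal(training_advance("STEP4", h(30, 30)), "repeat") # not < 30
  # STEP5: the consecutive-window accuracy rule
  accs <- c(0.83, 0.77, 0.83, 0.87)
  for (k in 1:3) {
    expect_equal(training_advance(
      "STEP5", h(rep(30, k), rep(20, k), accs[1:k])), "repeat")
  }
  expect_equal(training_advance("STEP5", h(rep(30, 4), rep(20, 4), accs)),
               "advance")
})
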