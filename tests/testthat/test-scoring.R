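test_that("binomial screen matches the exhaustive-summation oracle", {
  b <- binomial_bias_test(15, 30)
  expect_equal(b$p, 1)
  expect_false(b$biased)
  expect_equal(b$direction, "none")
  b <- binomial_bias_test(30, 30)
  expect_equal(b$p, 2 * 2^-30)
  expect_true(b$biased)
  expect_equal(b$direction, "toward")
  for (k in 0:30) {
    expect_equal(binomial_bias_test(k, 30)$p,
                 oracle_binom_two_sided(k, 30), tolerance = 1e-12,
                 info = paste("k =", k))
  }
  flagged <- vapply(0:30, function(k) binomial_bias_test(k, 30)$biased,
                    logical(1))
  expect_equal(which(flagged) - 1L, c(0:9, 21:30))
  expect_error(binomial_bias_test(31, 30), "k <= n")
})

test_that("criterion point finds the first qualifying window", {
  cp <- criterion_point(c(0.9, 0.9), c(30, 30))
  expect_equal(cp[c("n_sessions", "n_trials", "n_errors")],
               list(n_sessions = 2, n_trials = 60, n_errors = 6))
  # the window must be consecutive
  cp <- criterion_point(c(0.85, 0.7, 0.8, 0.83), rep(30, 4))
  expect_equal(cp$n_sessions, 4)
  expect_equal(cp$n_trials, 120)
  expect_false(criterion_point(c(0.7, 0.9, 0.7), rep(30, 3))$reached)
  expect_error(criterion_point(numeric(0), integer(0)), "empty")
  # invariant to sessions appended after the criterion pair
  base <- criterion_point(c(0.5, 0.85, 0.9), c(30, 30, 28))
  longer <- criterion_point(c(0.5, 0.85, 0.9, 0.2), c(30, 30, 28, 30))
  expect_equal(base, longer)
})

test_that("binomial-criterion perseveration sums errors in flagged sessions", {
  one <- perseveration_binomial(data.frame(n_trials = 30, n_errors = 25))
  expect_equal(one$flagged_sessions, 1L)
  expect_equal(one$persev_errors_binomial, 25)
  multi <- perseveration_binomial(
    data.frame(n_trials = 30, n_errors = c(28, 24, 16, 12)))
  expect_equal(multi$flagged_sessions, 1:2)
  expect_equal(multi$persev_errors_binomial, 52)
  none <- perseveration_binomial(
    data.frame(n_trials = 30, n_errors = rep(15, 4)))
  expect_equal(none$persev_errors_binomial, 0)
  expect_length(none$flagged_sessions, 0)
  expect_error(perseveration_binomial(data.frame()), "empty|expected")
})

test_that("contiguous mode keeps only the initial flagged run", {
  counts <- data.frame(n_trials = 30, n_errors = c(25, 24, 15, 25))
  all_mode <- perseveration_binomial(counts)
  expect_equal(all_mode$flagged_sessions, c(1L, 2L, 4L))
  expect_equal(all_mode$persev_errors_binomial, 74)
  contig <- perseveration_binomial(
    counts, scoring_config(persev_mode = "contiguous"))
  expect_equal(contig$flagged_sessions, 1:2)
  expect_equal(contig$persev_errors_binomial, 49)
})

test_that("the 50% criterion needs two complete qualifying sessions", {
  fp <- fifty_percent_point(
    data.frame(n_trials = 30, n_errors = c(24, 18, 15, 12)))
  expect_true(fp$reached)
  expect_equal(fp$trials_to_50, 120)
  expect_equal(fp$persev_errors_50, 69)
  # an incomplete session cannot serve as a criterion session, but its
  # trials and errors still accumulate
  mixed <- fifty_percent_point(
    data.frame(n_trials = c(30, 30, 20, 30, 30),
               n_errors = c(24, 18, 8, 15, 12)))
  expect_equal(mixed$trials_to_50, 140)
  expect_equal(mixed$persev_errors_50, 77)
  expect_false(fifty_percent_point(
    data.frame(n_trials = 30, n_errors = c(24, 14, 18)))$reached)
  # a 56-complete-session reversal consistent with the slowest fixture row
  slow <- data.frame(n_trials = rep(30, 56),
                     n_errors = c(rep(18, 54), 15, 15))
  expect_equal(fifty_percent_point(slow)$trials_to_50, 1680)
})

test_that("latency means pool at the trial level by default", {
  tr <- data.frame(
    subject_id = "x", phase = "PD",
    session_index = c(1, 1, 1, 2), trial_index = c(1:3, 1),
    response_latency = c(1, 2, 3, 5),
    reward_latency = c(1, NA, 3, 5),
    correct = c(TRUE, FALSE, TRUE, TRUE)
  )
  lat <- latency_summary(tr, "PD")
  expect_equal(lat$response_latency, 2.75) # pooled, not mean of means
  expect_equal(lat$reward_latency, 3)      # rewarded trials only
  sm <- latency_summary(tr, "PD", scoring_config(latency_mode = "session_mean"))
  expect_equal(sm$response_latency, (2 + 5) / 2)
  expect_error(latency_summary(tr, "PDR"), "no trials")
})

test_that("per-animal summaries respect their invariants and are pure", {
  run <- simulate_animal(agent_params(alpha_pos = 0.01, alpha_neg = 0.01),
                         seed = 11, keep_trials = TRUE)
  s1 <- summarize_animal(run)
  s2 <- summarize_animal(run)
  expect_identical(s1, s2)
  expect_true(s1$pd_reached && s1$pdr_reached)
  expect_gte(s1$pd_trials, s1$pd_sessions)
  expect_gte(s1$pdr_trials, s1$pdr_sessions)
  expect_lte(s1$persev_errors_50, s1$trials_to_50)
  expect_lte(s1$trials_to_50, s1$pdr_trials)
  expect_true(all(is.finite(c(s1$pd_response_latency, s1$pd_reward_latency,
                              s1$pdr_response_latency,
                              s1$pdr_reward_latency))))
  # flagged perseverative sessions all precede the reversal criterion point
  pdr <- run$sessions[run$sessions$phase == "PDR", ]
  pb <- perseveration_binomial(
    data.frame(n_trials = pdr$n_trials,
               n_errors = pdr$n_trials - pdr$n_correct))
  if (length(pb$flagged_sessions)) {
    expect_lte(max(pb$flagged_sessions), s1$pdr_sessions)
  }
  # criterion scoring agrees with an independent flat re-scan of the trials
  for (ph in c("PD", "PDR")) {
    tab <- oracle_session_table(run$trials, ph)
    cp <- criterion_point(tab$n_correct / tab$n_trials, tab$n_trials)
    expect_equal(cp$n_sessions,
                 if (ph == "PD") s1$pd_sessions else s1$pdr_sessions)
    expect_equal(cp$n_trials,
                 if (ph == "PD") s1$pd_trials else s1$pdr_trials)
  }
  # pooled latency equals the flat mean over the raw trial rows
  pd_tr <- run$trials[run$trials$phase == "PD", ]
  expect_equal(s1$pd_response_latency, mean(pd_tr$response_latency))
  expect_equal(s1$pd_reward_latency,
               mean(pd_tr$reward_latency, na.rm = TRUE))
})
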