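test_that("the delta-rule update follows its closed form", {
  p <- agent_params(alpha_pos = 0.2, alpha_neg = 0.1)
  v <- agent_update(c(a = 0.5, b = 0.3), "a", 1, p)
  expect_equal(v[["a"]], 0.6)
  expect_equal(v[["b"]], 0.3) # unchosen value untouched
  # alpha_neg = 0: errors never move the value (pure perseverance)
  p0 <- agent_params(alpha_neg = 0)
  v <- c(a = 0.8, b = 0)
  for (i in 1:5) v <- agent_update(v, "a", 0, p0)
  expect_equal(v[["a"]], 0.8)
  # repeated reward: V_t = 1 - (1 - alpha)^t * (1 - V_0)
  p3 <- agent_params(alpha_pos = 0.3)
  v <- c(a = 0.1, b = 0)
  for (t in 1:8) {
    v <- agent_update(v, "a", 1, p3)
    expect_equal(v[["a"]], 1 - 0.7^t * 0.9)
  }
  expect_error(agent_update(c(a = 0, b = 0), "c", 1, p), "not among")
})

test_that("the logistic choice rule is symmetric and saturates", {
  p <- agent_params(lapse = 0, side_bias = 0)
  expect_equal(agent_choose(c(a = 0.4, b = 0.4), "left", p)$p_a, 0.5)
  phuge <- agent_params(beta = 500, lapse = 0)
  expect_gt(agent_choose(c(a = 0.6, b = 0.4), "left", phuge)$p_a, 0.999)
  # lapse bounds the attainable probability
  plapse <- agent_params(beta = 500, lapse = 0.2)
  expect_equal(agent_choose(c(a = 1, b = 0), "left", plapse)$p_a, 0.9)
  # side bias pushes toward the left stimulus
  pside <- agent_params(lapse = 0, side_bias = 1)
  expect_gt(agent_choose(c(a = 0, b = 0), "left", pside)$p_a, 0.5)
  expect_lt(agent_choose(c(a = 0, b = 0), "right", pside)$p_a, 0.5)
})

test_that("empirical choice frequency matches the closed form", {
  p <- agent_params(beta = 1, lapse = 0, side_bias = 0)
  set.seed(42)
  n <- 20000
  hits <- sum(vapply(seq_len(n), function(i) {
    agent_choose(c(a = 1, b = 0), "left", p)$choice == "a"
  }, logical(1)))
  expected <- plogis(1)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(hits / n - expected), 4 * se)
})

test_that("a capable agent learns PD and perseverates at reversal", {
  # learning fast enough to converge in a handful of sessions, but slow
  # enough that the carried-over values dominate the whole first reversal
  # session (very fast learners relearn within the session and can average
  # above chance over its 30 trials)
  p <- agent_params(alpha_pos = 0.05, alpha_neg = 0.05, beta = 8,
                    lapse = 0.01)
  reached <- below <- logical(10)
  for (i in seq_len(10)) {
    run <- simulate_animal(p, seed = 100 + i, keep_trials = FALSE)
    s <- summarize_animal(run)
    reached[i] <- s$pd_reached
    pdr1 <- run$sessions[run$sessions$phase == "PDR", ][1, ]
    below[i] <- pdr1$accuracy < 0.5
  }
  expect_true(all(reached))
  expect_gte(sum(below), 9L)
})

test_that("a maximal-lapse agent stays at chance and gets truncated", {
  p <- agent_params(alpha_pos = 0.5, alpha_neg = 0.5, beta = 8,
                    lapse = 0.49)
  run <- simulate_animal(p, session_cap = 12L, seed = 7,
                         keep_trials = FALSE)
  s <- summarize_animal(run)
  expect_true(any(run$truncated))
  # at lapse 0.49 the attainable true accuracy is capped near 0.755,
  # below the 80% criterion, so the discrimination phases cannot be
  # passed reliably
  pd <- run$sessions[run$sessions$phase == "PD", ]
  if (nrow(pd) > 0) {
    expect_lt(mean(pd$accuracy), 0.80)
    expect_false(isTRUE(s$pd_reached) && isTRUE(s$pdr_reached) &&
                   !any(run$truncated))
  }
})

test_that("a strong stimulus bias is caught by the first-session screen", {
  p <- agent_params(stim_bias = 1.5, stim_bias_image = "marble", beta = 6,
                    alpha_pos = 0.004, alpha_neg = 0.004)
  run <- simulate_animal(p, positive_image = "marble", seed = 5,
                         keep_trials = FALSE)
  s <- summarize_animal(run)
  expect_true(s$bias_flag)
  expect_equal(s$bias_image, "marble")
})
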