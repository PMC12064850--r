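# MID task engine: ITI distribution, scheduling, deadline titration,
# outcome adjudication, simulated agents, and behavioral scoring.

test_that("ITI sampler respects bounds and calibrated mean", {
  set.seed(42)
  x <- sample_iti(20000)
  expect_true(all(x >= 2 & x <= 11))
  expect_lt(abs(mean(x) - 5), 0.1)
  # rate frozen from solving the closed-form truncated-mean equation
  expect_equal(iti_rate(5, 2, 11), 0.2387917555, tolerance = 1e-8)
  expect_error(iti_rate(1.5, 2, 11), "lo_s < mean_s")
  expect_error(iti_rate(7, 2, 11), "not reachable")
})

test_that("schedule balances conditions, randomizes, and is deterministic", {
  s <- generate_schedule(4, 64, seed = 3)
  expect_equal(nrow(s), 256L)
  expect_equal(sum(s$condition == "reward"), 128L)
  for (run in 0:3)
    expect_equal(sum(s$condition == "reward" & s$run_index == run), 32L)
  expect_true(all(s$target_number %in% c(1L, 4L, 6L, 9L)))
  expect_true(all(s$iti1_s >= 2 & s$iti1_s <= 11))
  # onsets strictly increasing within each trial
  expect_true(all(s$item_onset_s < s$number_onset_s))
  expect_true(all(s$number_onset_s < s$outcome_onset_s))
  expect_identical(s, generate_schedule(4, 64, seed = 3))
  s2 <- generate_schedule(1, 2, seed = 1)
  expect_setequal(s2$condition, c("reward", "neutral"))
  expect_error(generate_schedule(1, 3), "even")
})

test_that("deadline titration is the interpolated 70th percentile", {
  expect_equal(titrate_deadline(numeric(0), 0.6), 0.6)
  expect_equal(titrate_deadline(seq(0.3, 1.2, by = 0.1)), 0.93)
  expect_error(titrate_deadline(c(0.5, -0.1)), "positive")
})

test_that("an i.i.d. agent beats its titrated deadline ~70% of the time", {
  set.seed(7)
  n <- 4000
  rts <- rlnorm(n, log(0.45), 0.25)
  beat <- logical(n - 1)
  for (i in 2:n)
    beat[i - 1] <- rts[i] <= titrate_deadline(rts[seq_len(i - 1)])
  expect_lt(abs(mean(beat) - 0.70), 0.05)
})

test_that("outcome adjudication matches the +2/-1/0 rule", {
  expect_equal(adjudicate_outcome("reward", TRUE, TRUE, 0.40, 0.50), 2L)
  expect_equal(adjudicate_outcome("reward", TRUE, FALSE, 0.40, 0.50), -1L)
  expect_equal(adjudicate_outcome("reward", FALSE, TRUE, 0.40, 0.50), -1L)
  expect_equal(adjudicate_outcome("reward", TRUE, TRUE, 0.60, 0.50), -1L)
  expect_equal(adjudicate_outcome("neutral", FALSE, FALSE, 2.0, 0.5), 0L)
  expect_error(adjudicate_outcome("reward", NA, TRUE, 0.4, 0.5), "missing")
})

test_that("ceiling and floor agents hit the outcome table edges", {
  s <- generate_schedule(1, 16, seed = 2)
  # constant RTs: the titrated deadline then always equals the RT itself,
  # so every number response is in time
  ceiling_p <- agent_params(p_item_reward = 1, p_item_neutral = 1,
                            p_number = 1, rt_number_meanlog = log(0.3),
                            rt_number_sdlog = 0)
  b <- simulate_agent(s, ceiling_p, seed = 1)
  expect_true(all(b$outcome_points[b$condition == "reward"] == 2L))
  expect_true(all(b$outcome_points[b$condition == "neutral"] == 0L))
  floor_p <- agent_params(p_item_reward = 0)
  b2 <- simulate_agent(s, floor_p, seed = 1)
  expect_true(all(b2$outcome_points[b2$condition == "reward"] == -1L))
})

test_that("simulated RT ordering follows the agent parameters", {
  s <- generate_schedule(2, 64, seed = 5)
  p <- agent_params(rt_item_meanlog = c(reward = log(0.6),
                                        neutral = log(0.9)))
  b <- simulate_agent(s, p, seed = 6)
  expect_lt(mean(b$item_rt_s[b$condition == "reward"]),
            mean(b$item_rt_s[b$condition == "neutral"]))
})

test_that("memory test has the right size and limiting behavior", {
  s <- generate_schedule(4, 64, seed = 8)
  b <- simulate_agent(s, seed = 9)
  m <- simulate_memory_test(b, seed = 10)
  expect_equal(nrow(m), 384L)                       # 256 old + 128 lures
  expect_equal(sum(m$truth == "old"), 256L)
  expect_equal(sum(m$truth == "new"), 128L)
  expect_true(all(m$confidence >= 0 & m$confidence <= 100))
  expect_true(all(m$encoding_condition[m$truth == "new"] == "none"))
  # infinitely strong encoding -> hit rate 1
  b_inf <- b
  b_inf$encoding_strength <- 50
  m_inf <- simulate_memory_test(b_inf, seed = 11)
  expect_equal(mean(m_inf$response[m_inf$truth == "old"] == "old"), 1)
})

test_that("a reward encoding boost raises the reward hit rate", {
  p <- agent_params(encode_reward_boost = 1.5)
  wins <- 0L
  for (seed in 1:20) {
    s <- generate_schedule(1, 64, seed = seed)
    b <- simulate_agent(s, p, seed = seed + 100)
    m <- simulate_memory_test(b, params = p, seed = seed + 200)
    hr <- function(cond)
      mean(m$response[m$truth == "old" &
                      m$encoding_condition == cond] == "old")
    wins <- wins + (hr("reward") > hr("neutral"))
  }
  expect_gt(binom.test(wins, 20, 0.5, alternative = "greater")$p.value < 0.05,
            0)
  expect_gte(wins, 15L)
})

test_that("signal-detection scoring counts and filters correctly", {
  toy <- data.frame(
    truth = rep(c("old", "new"), c(10, 10)),
    response = c(rep("old", 7), rep("new", 3), rep("old", 2), rep("new", 8)),
    confidence = 80,
    encoding_condition = rep(c("reward", "none"), c(10, 10)),
    encoding_item_correct = c(rep(TRUE, 10), rep(NA, 10)))
  s <- score_sdt(toy)
  expect_equal(s$p_hit, 0.7)
  expect_equal(s$p_fa, 0.2)
  expect_equal(s$recognition, 0.5)
  expect_equal(s$n_hits + s$n_misses, 10L)
  expect_equal(s$n_fa + s$n_cr, 10L)
  # perfect memory
  perf <- toy
  perf$response <- ifelse(perf$truth == "old", "old", "new")
  sp <- score_sdt(perf)
  expect_equal(sp$recognition, 1)
  # confidence 67 kept, 66 dropped under the high-confidence filter
  hc <- toy
  hc$confidence <- c(rep(67, 5), rep(66, 5), rep(67, 10))
  shc <- score_sdt(hc, restrict_high_confidence = TRUE)
  expect_equal(shc$n_hits + shc$n_misses, 5L)
  # misclassified encoding items excluded from condition-restricted scoring
  mc <- toy
  mc$encoding_item_correct[1:3] <- FALSE
  smc <- score_sdt(mc, restrict_to_condition = "reward")
  expect_equal(smc$n_hits + smc$n_misses, 7L)
  expect_error(score_sdt(toy[toy$truth == "old", ]), "lures")
})

test_that("outlier rule flags only strict >3 SD deviations", {
  vals <- c(rep(0.9, 19), 0.1)
  ids <- paste0("p", 1:20)
  expect_equal(detect_outliers(vals, ids, rep("reward", 20)), "p20")
  expect_equal(detect_outliers(rep(0.8, 10), paste0("p", 1:10),
                               rep("reward", 10)), character(0))
  # a value at exactly 3 SD is not an outlier (strict inequality)
  base <- c(rep(0, 10), rep(1, 10))
  a <- uniroot(function(a) {
    x <- c(base, a); (a - mean(x)) / sd(x) - 3
  }, c(1, 100), tol = 1e-12)$root - 1e-9
  x <- c(base, a)
  expect_lte((a - mean(x)) / sd(x), 3 + 1e-12)
  expect_equal(detect_outliers(x, paste0("p", 1:21), rep("a", 21)),
               character(0))
})

test_that("behavioral summary reproduces a hand-computed paired t", {
  rec <- do.call(rbind, lapply(1:5, function(p) {
    data.frame(participant = p, condition = rep(c("reward", "neutral"), 4),
               item_response_correct = TRUE, number_response_correct = TRUE,
               item_rt_s = rep(c(0.5 + 0.02 * p, 0.6 + 0.01 * p), 4),
               number_rt_s = 0.4)
  }))
  out <- summarize_behavior(rec)
  d <- (0.5 + 0.02 * (1:5)) - (0.6 + 0.01 * (1:5))
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  t_pkg <- out$tests$t[out$tests$measure == "item_rt_s"]
  expect_equal(t_pkg, t_hand, tolerance = 1e-10)
  # identical accuracies -> t = 0 (degenerate all-zero differences)
  expect_equal(out$tests$t[out$tests$measure == "item_accuracy"], 0)
})

test_that("runs with >50% misclassified items are excluded", {
  rec <- data.frame(run_index = rep(0:1, each = 10),
                    item_response_correct = c(rep(TRUE, 10),
                                              rep(c(FALSE, TRUE), c(6, 4))))
  ex <- exclude_bad_runs(rec)
  expect_equal(ex$dropped_runs, 1L)
  expect_true(all(ex$kept$run_index == 0L))
  # exactly 50% is kept (strict inequality)
  rec2 <- data.frame(run_index = 0L,
                     item_response_correct = rep(c(TRUE, FALSE), 5))
  expect_length(exclude_bad_runs(rec2)$dropped_runs, 0L)
})
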