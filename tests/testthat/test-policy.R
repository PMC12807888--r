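test_that("policy initialization applies uniform priors by default", {
  p <- init_policy(2, seed = 1)
  expect_equal(p$alpha, c(1, 1))
  expect_equal(p$beta, c(1, 1))
  expect_identical(p$turn_counter, 0L)
  expect_true(is.na(p$last_reward))
  expect_equal(p$style_names, c("neutral", "enthusiastic"))

  p1 <- init_policy(1)
  expect_length(p1$alpha, 1)
  expect_equal(sample_and_select(p1)$chosen, 1)  # degenerate bandit

  p3 <- init_policy(2, priors = list(c(3, 1), c(1, 3)))
  expect_equal(p3$alpha, c(3, 1))
  expect_equal(p3$beta, c(1, 3))

  expect_error(init_policy(0), "positive")
  expect_error(init_policy(2, priors = list(c(0.5, 1), c(1, 1))), ">= 1")
})

test_that("replayed update sequences match hand-counted bookkeeping", {
  set.seed(7)
  for (rep in 1:5) {
    n_turns <- sample(10:40, 1)
    played <- sample(1:2, n_turns, replace = TRUE)
    rewards <- round(runif(n_turns, -0.64, 0.76), 3)
    rewards[sample(n_turns, 2)] <- rewards[1]  # force some exact ties
    p <- init_policy(2, seed = rep)
    for (t in seq_len(n_turns))
      p <- policy_observe(p, played[t], rewards[t])$state
    oracle <- count_updates(played, rewards, 2)
    expect_equal(p$alpha, 1 + oracle$successes)
    expect_equal(p$beta, 1 + oracle$failures)
    # conservation: total count growth equals number of updated turns
    expect_equal(sum(p$alpha + p$beta) - 4, n_turns - 1)
  }
})

test_that("zero delta counts as a success and turn 1 never updates", {
  p <- init_policy(2, seed = 2)
  expect_warning(p2 <- update_from_delta(p, 1, 0.5), "turn")
  expect_equal(p2$alpha, c(1, 1))  # no-op before a previous reward exists

  p <- policy_observe(p, 1, 0.2)$state      # turn 1: record only
  expect_equal(p$alpha, c(1, 1))
  res <- policy_observe(p, 2, 0.2)$state    # turn 2: delta = 0 -> success
  expect_equal(res$alpha, c(1, 2))
  expect_equal(res$beta, c(1, 1))

  res2 <- policy_observe(res, 1, 0.1)$state # delta < 0 -> failure
  expect_equal(res2$beta, c(2, 1))
  expect_equal(res2$alpha, c(1, 2))
})

test_that("symmetric priors select each arm half the time", {
  p <- init_policy(2, seed = 123)
  picks <- integer(10000)
  for (i in seq_along(picks)) {
    s <- sample_and_select(p)
    picks[i] <- s$chosen
    p <- s$state
  }
  expect_lt(abs(mean(picks == 1) - 0.5), 0.02)
})

test_that("near-degenerate posteriors select the confident arm", {
  p <- init_policy(2, priors = list(c(100, 1), c(1, 100)), seed = 9)
  picks <- integer(10000)
  for (i in seq_along(picks)) {
    s <- sample_and_select(p)
    picks[i] <- s$chosen
    p <- s$state
  }
  expect_gte(mean(picks == 1), 0.99)
})

test_that("selection is deterministic from identical states", {
  p <- init_policy(2, seed = 77)
  a <- sample_and_select(p)
  b <- sample_and_select(p)
  expect_identical(a$chosen, b$chosen)
  expect_identical(a$thetas, b$thetas)
  # and the advanced states keep agreeing
  expect_identical(sample_and_select(a$state)$thetas,
                   sample_and_select(b$state)$thetas)
})

test_that("posterior mean follows the Beta closed form and the LLN", {
  expect_equal(posterior_mean(1, 1), 0.5)
  expect_equal(posterior_mean(3, 1), 0.75)
  p <- init_policy(2, seed = 5)
  p$turn_counter <- 2L  # make updates eligible
  set.seed(11)
  for (i in 1:1000)
    p <- update_from_delta(p, 1, ifelse(runif(1) < 0.7, 1, -1))
  expect_lt(abs(posterior_mean(p)[["neutral"]] - 0.7), 0.05)
})

test_that("baseline selectors implement their contracts", {
  # empirical rates 0.8 vs 0.2 from scripted updates
  p <- init_policy(2, seed = 3)
  p$turn_counter <- 2L
  for (i in 1:10) {
    p <- update_from_delta(p, 1, ifelse(i <= 8, 1, -1))
    p <- update_from_delta(p, 2, ifelse(i <= 2, 1, -1))
  }
  for (i in 1:50) {
    s <- baseline_select(p, "epsilon_greedy", epsilon = 0)
    expect_equal(s$chosen, 1)  # pure greedy always takes the better arm
    p <- s$state
  }

  # pure exploration is uniform
  q <- init_policy(2, seed = 21)
  picks <- integer(10000)
  for (i in seq_along(picks)) {
    s <- baseline_select(q, "epsilon_greedy", epsilon = 1)
    picks[i] <- s$chosen
    q <- s$state
  }
  expect_lt(abs(mean(picks == 1) - 0.5), 0.02)

  # UCB plays a never-updated arm first
  r <- init_policy(2, seed = 4)
  r$turn_counter <- 2L
  r <- update_from_delta(r, 1, 1)
  expect_equal(baseline_select(r, "ucb")$chosen, 2)

  expect_error(baseline_select(p, "epsilon_greedy", epsilon = 2), "epsilon")
  expect_error(baseline_select(p, "ucb", c_ucb = -1), "positive")
})

test_that("policy state round-trips through JSON", {
  p <- init_policy(2, priors = list(c(2, 1), c(1.5, 3)), seed = 42)
  p <- policy_observe(p, 1, 0.3)$state
  p <- policy_observe(p, 2, 0.1)$state
  path <- withr::local_tempfile(fileext = ".json")
  policy_to_json(p, path)
  q <- policy_from_json(path)
  expect_equal(q$alpha, p$alpha)
  expect_equal(q$beta, p$beta)
  expect_equal(q$prior_alpha, p$prior_alpha)
  expect_identical(q$turn_counter, p$turn_counter)
  expect_equal(q$last_reward, p$last_reward)
  expect_identical(q$rng, p$rng)
  # restored state continues identically
  expect_identical(sample_and_select(q)$thetas, sample_and_select(p)$thetas)
})
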