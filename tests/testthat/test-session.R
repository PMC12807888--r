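test_that("a full-script session logs 32 turns and 31 updates", {
  u <- user_profile(trait = 10)
  lg <- run_session(u, config = session_config(seed = 2))
  expect_equal(nrow(lg$turns), 32)
  expect_equal(sum(lg$turns$update != "none"), 31)
  expect_true(is.na(lg$turns$delta[1]))
  expect_true(all(!is.na(lg$turns$delta[-1])))
  # final posteriors equal priors plus counted successes/failures
  oracle <- count_updates(lg$turns$chosen, lg$turns$reward, 2)
  expect_equal(lg$final_state$alpha, 1 + oracle$successes)
  expect_equal(lg$final_state$beta, 1 + oracle$failures)
})

test_that("a one-turn session applies no update", {
  lg <- run_session(user_profile(), config = session_config(n_turns = 1,
                                                            seed = 3))
  expect_equal(nrow(lg$turns), 1)
  expect_equal(lg$turns$update, "none")
  expect_equal(lg$final_state$alpha, c(1, 1))
  expect_equal(lg$final_state$beta, c(1, 1))
})

test_that("count-growth and replay invariants hold on generated logs", {
  for (seed in c(5, 6, 7)) {
    n_turns <- c(8, 32, 50)[match(seed, c(5, 6, 7))]
    lg <- run_session(user_profile(trait = seed * 4),
                      make_default_script(50),
                      session_config(n_turns = n_turns, seed = seed,
                                     frames_per_turn = 12))
    expect_equal(nrow(lg$turns), n_turns)
    growth <- sum(lg$final_state$alpha + lg$final_state$beta) - 4
    expect_equal(growth, sum(lg$turns$update != "none"))
    expect_equal(growth, n_turns - 1)
    # rewards recomputable from logged frames, exactly
    expect_identical(replay_rewards(lg), lg$turns$reward)
    # alpha/beta snapshots non-decreasing
    for (col in grep("^(alpha|beta)_", names(lg$turns), value = TRUE))
      expect_true(all(diff(lg$turns[[col]]) >= 0))
  }
})

test_that("sessions are reproducible and seed-sensitive", {
  cfg <- session_config(seed = 99)
  u <- user_profile(trait = 20)
  a <- run_session(u, config = cfg)
  b <- run_session(u, config = cfg)
  expect_identical(a$turns, b$turns)
  expect_identical(a$frames, b$frames)
  c2 <- run_session(u, config = session_config(seed = 100))
  expect_false(identical(a$turns$reward, c2$turns$reward))
})

test_that("file-based emotion streams drive a session", {
  set.seed(123)
  stream <- data.frame(turn = rep(1:6, each = 10), frame = rep(0:9, 6),
                       emotion = sample(EMOTION_LABELS, 60, replace = TRUE))
  lg <- run_session(stream, make_default_script(6),
                    session_config(n_turns = 6, seed = 1))
  expect_equal(lg$turns$reward,
               unname(tapply(default_valences[stream$emotion], stream$turn,
                             mean)),
               ignore_attr = TRUE)
  # exhausted stream errors, citing the turn
  expect_error(run_session(stream, make_default_script(8),
                           session_config(n_turns = 8, seed = 1)),
               "turn 7")
  # lenient mode records the missing turns without updating
  lg2 <- run_session(stream, make_default_script(8),
                     session_config(n_turns = 8, seed = 1, strict = FALSE))
  expect_true(all(is.na(lg2$turns$reward[7:8])))
  expect_equal(sum(lg2$turns$update != "none"), 5)
})

test_that("the uniform baseline plays both styles evenly", {
  counts <- 0
  n_sessions <- 60
  u <- bernoulli_user(c(0.9, 0.1))
  for (k in seq_len(n_sessions)) {
    lg <- run_session(u, config = session_config(seed = 2000 + k,
                                                 policy = "uniform"))
    counts <- counts + sum(lg$turns$chosen == 1)
  }
  # 60 sessions x 32 turns: binomial(1920, 0.5), +-3 sd band
  expect_lt(abs(counts / (n_sessions * 32) - 0.5), 3 * 0.5 / sqrt(1920))
})

test_that("cohort runs are order-stable and deterministic", {
  coh <- make_cohort(6, seed = 4)
  cfg <- session_config(n_turns = 10, seed = 42)
  logs1 <- run_cohort(coh, make_default_script(10), cfg)
  logs2 <- run_cohort(coh, make_default_script(10), cfg)
  expect_length(logs1, 6)
  expect_identical(vapply(logs1, `[[`, numeric(1), "user_id"),
                   as.numeric(1:6))
  expect_identical(lapply(logs1, `[[`, "turns"),
                   lapply(logs2, `[[`, "turns"))
  summ <- cohort_summary(logs1)
  expect_equal(nrow(summ), 6)
  expect_true(all(c("alpha_neutral", "alpha_enthusiastic", "dominant")
                  %in% names(summ)))
})

test_that("dominant-style classification honors the count margin", {
  expect_equal(classify_dominant_style(c(neutral = 10, enthusiastic = 3)),
               "neutral")
  expect_equal(classify_dominant_style(c(neutral = 7, enthusiastic = 7),
                                       margin = 0.5),
               "no clear preference")
  expect_equal(classify_dominant_style(c(neutral = 8, enthusiastic = 7),
                                       margin = 2),
               "no clear preference")
  expect_equal(classify_dominant_style(c(neutral = 8, enthusiastic = 7),
                                       margin = 1),
               "neutral")
  expect_error(classify_dominant_style(c(a = 1, b = 2), margin = -1), ">= 0")
})

test_that("session logs round-trip through JSONL", {
  lg <- run_session(user_profile(trait = 25),
                    config = session_config(n_turns = 8, seed = 31,
                                            frames_per_turn = 5))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(lg, path)
  back <- read_session_log(path)
  expect_equal(nrow(back$turns), 8)
  expect_equal(back$turns$reward, lg$turns$reward)
  expect_equal(back$turns$style, lg$turns$style)
  expect_identical(back$frames, lg$frames)
  expect_equal(back$final_state$alpha, lg$final_state$alpha)
  expect_equal(back$final_state$beta, lg$final_state$beta)
  expect_identical(replay_rewards(back), back$turns$reward)
})
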