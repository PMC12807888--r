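#' Session configuration
#'
#' Bundles the knobs of one adaptive interaction session: the number
#' of turns (bounded by the script length), frames collected per turn,
#' the selection policy and its parameters, the master seed, and the
#' handling of empty turns (no face detected). The policy and the
#' simulated user consume independent random sub-streams derived from
#' the master seed, so logs are reproducible regardless of call order.
#'
#' @param n_turns number of interaction turns; defaults to the script
#'   length at run time.
#' @param frames_per_turn frames observed per turn (default 30).
#' @param policy one of `"thompson"`, `"epsilon_greedy"`, `"ucb"`,
#'   `"uniform"`.
#' @param n_styles number of styles.
#' @param style_names optional style names.
#' @param priors optional per-arm `(alpha, beta)` priors (>= 1).
#' @param epsilon,c_ucb baseline-policy parameters.
#' @param seed master seed.
#' @param strict if `TRUE` an empty turn is an error; if `FALSE` the
#'   turn is logged with a missing reward and no policy update.
#' @param map a [valence_map()].
#' @return a `session_config` object.
#' @export
session_config <- function(n_turns = NULL, frames_per_turn = 30L,
                           policy = c("thompson", "epsilon_greedy",
                                      "ucb", "uniform"),
                           n_styles = 2L, style_names = NULL, priors = NULL,
                           epsilon = 0.1, c_ucb = sqrt(2), seed = 1L,
                           strict = TRUE, map = valence_map()) {
  policy <- match.arg(policy)
  structure(list(n_turns = n_turns, frames_per_turn = as.integer(frames_per_turn),
                 policy = policy, n_styles = as.integer(n_styles),
                 style_names = style_names, priors = priors,
                 epsilon = epsilon, c_ucb = c_ucb, seed = as.integer(seed),
                 strict = isTRUE(strict), map = map),
            class = "session_config")
}

# wrap a raw emotion stream (data.frame turn,frame,emotion) as a user
stream_user <- function(stream) {
  codes <- match(canonical_emotion(stream$emotion), EMOTION_LABELS)
  structure(list(by_turn = split(codes, stream$turn)), class = "stream_user")
}

#' Run one adaptive interaction session
#'
#' Executes the full per-turn loop over a script, a Thompson Sampling
#' (or baseline) policy and a user: sample and select a style, deliver
#' the item, observe the turn's emotion frames, compute the
#' mean-valence reward, and — from the second turn onward — update the
#' played arm with the sign of the reward change. Every turn is
#' logged, including the sampled thetas and post-update posterior
#' snapshots, so the session can be replayed and audited.
#'
#' @param user a [user_profile()], a [bernoulli_user()], or an emotion
#'   stream data.frame (`turn`, `frame`, `emotion`) read with
#'   [read_emotion_stream()].
#' @param script script data.frame (default [make_default_script()]).
#' @param config a [session_config()].
#' @param policy optional pre-initialized `policy_state`; by default a
#'   fresh policy is initialized from the config.
#' @return a `session_log`: list with `config`, `turns` (one row per
#'   turn), `frames` (per-turn emotion labels, `NULL` for reward-level
#'   users) and `final_state`.
#' @export
run_session <- function(user, script = make_default_script(),
                        config = session_config(), policy = NULL) {
  stopifnot(inherits(config, "session_config"))
  script <- validate_script(script)
  n_turns <- if (is.null(config$n_turns)) nrow(script)
             else as.integer(config$n_turns)
  if (n_turns < 1L) stop("n_turns must be >= 1", call. = FALSE)
  if (n_turns > nrow(script))
    stop("n_turns (", n_turns, ") exceeds script length (", nrow(script), ")",
         call. = FALSE)
  if (is.data.frame(user)) user <- stream_user(user)
  if (is.null(policy))
    policy <- init_policy(config$n_styles, priors = config$priors,
                          style_names = config$style_names,
                          seed = derive_seed(config$seed, 1L))
  n_arms <- length(policy$alpha)
  vmap <- unclass(config$map)[EMOTION_LABELS]
  sim_rng <- rng_init(derive_seed(config$seed, 2L))

  chosen <- integer(n_turns)
  reward <- numeric(n_turns)
  delta <- rep(NA_real_, n_turns)
  update <- character(n_turns)
  thetas <- matrix(NA_real_, n_turns, n_arms)
  alpha_snap <- matrix(NA_real_, n_turns, n_arms)
  beta_snap <- matrix(NA_real_, n_turns, n_arms)
  response <- rep(NA_integer_, n_turns)
  frames <- vector("list", n_turns)

  with_preserved_rng({
    for (t in seq_len(n_turns)) {
      # --- selection (policy sub-stream) ---
      assign(".Random.seed", policy$rng, envir = globalenv())
      if (config$policy == "thompson") {
        sel <- .sample_select(policy$alpha, policy$beta)
        a <- sel$chosen
        thetas[t, ] <- sel$thetas
      } else {
        a <- switch(config$policy,
          uniform = sample.int(n_arms, 1L),
          epsilon_greedy = {
            if (stats::runif(1) < config$epsilon) sample.int(n_arms, 1L)
            else which.max(.empirical_rates(policy))
          },
          ucb = {
            upd <- (policy$alpha - policy$prior_alpha) +
                   (policy$beta - policy$prior_beta)
            if (any(upd == 0)) which(upd == 0)[1L]
            else which.max(.empirical_rates(policy) +
                           config$c_ucb * sqrt(log(sum(upd)) / upd))
          })
      }
      policy$rng <- get(".Random.seed", envir = globalenv())
      chosen[t] <- a

      # --- user response (simulator sub-stream) ---
      assign(".Random.seed", sim_rng, envir = globalenv())
      if (inherits(user, "stream_user")) {
        codes <- user$by_turn[[as.character(t)]]
        if (is.null(codes) || length(codes) == 0L) {
          if (config$strict)
            stop("user stream exhausted: no frames for turn ", t,
                 call. = FALSE)
          obs <- list(frames = integer(0), reward = NA_real_)
        } else obs <- list(frames = codes, reward = mean(vmap[codes]))
      } else {
        obs <- user_turn(user, a, config$frames_per_turn, policy$last_reward)
      }
      if (inherits(user, "user_profile"))
        response[t] <- sample.int(5L, 1L)  # logged, never used by the policy
      sim_rng <- get(".Random.seed", envir = globalenv())

      if (length(obs$frames)) frames[[t]] <- EMOTION_LABELS[obs$frames]
      r <- obs$reward
      reward[t] <- r

      # --- bookkeeping + update (only from turn 2 onward) ---
      policy$turn_counter <- t
      policy$plays[a] <- policy$plays[a] + 1L
      upd <- "none"
      if (!is.na(r)) {
        if (t >= 2L && !is.na(policy$last_reward)) {
          d <- r - policy$last_reward
          delta[t] <- d
          if (d >= 0) { policy$alpha[a] <- policy$alpha[a] + 1; upd <- "success" }
          else        { policy$beta[a]  <- policy$beta[a]  + 1; upd <- "failure" }
        }
        policy$last_reward <- r
      }
      update[t] <- upd
      alpha_snap[t, ] <- policy$alpha
      beta_snap[t, ] <- policy$beta
    }
  })

  turns <- data.frame(turn = seq_len(n_turns),
                      item_id = script$id[seq_len(n_turns)],
                      chosen = chosen,
                      style = policy$style_names[chosen],
                      reward = reward, delta = delta, update = update,
                      response = response,
                      stringsAsFactors = FALSE)
  colnames(thetas) <- paste0("theta_", policy$style_names)
  colnames(alpha_snap) <- paste0("alpha_", policy$style_names)
  colnames(beta_snap) <- paste0("beta_", policy$style_names)
  turns <- cbind(turns, thetas, alpha_snap, beta_snap)
  structure(list(config = config,
                 user_id = if (inherits(user, "user_profile")) user$user_id else NA,
                 trait = if (inherits(user, "user_profile")) user$trait else NA,
                 turns = turns, frames = frames, final_state = policy),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("session log: %d turn(s), %d update(s)\n",
              nrow(x$turns), sum(x$turns$update != "none")))
  print(x$final_state)
  invisible(x)
}

#' Run one session per cohort member
#'
#' Each user gets an independent session with a sub-seed derived from
#' the master seed in `config`; results are returned in cohort order.
#'
#' @param cohort list of users from [make_cohort()].
#' @param script script data.frame.
#' @param config a [session_config()]; its `seed` acts as the cohort
#'   master seed.
#' @return list of `session_log` objects.
#' @export
run_cohort <- function(cohort, script = make_default_script(),
                       config = session_config()) {
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  lapply(seq_along(cohort), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 1000L + i)
    run_session(cohort[[i]], script, cfg)
  })
}

#' Classify a session's dominant style
#'
#' A style dominates when its final alpha (success count) exceeds
#' every other style's by at least `margin`; otherwise the session
#' shows no clear preference (comparable alpha values).
#'
#' @param state a `policy_state`, a `session_log`, or a named numeric
#'   vector of final alpha values.
#' @param margin non-negative count margin (default 2).
#' @return style name, or `"no clear preference"`.
#' @examples
#' classify_dominant_style(c(neutral = 10, enthusiastic = 3))
#' @export
classify_dominant_style <- function(state, margin = 2) {
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  if (inherits(state, "session_log")) state <- state$final_state
  if (inherits(state, "policy_state")) {
    alpha <- state$alpha; names(alpha) <- state$style_names
  } else alpha <- state
  ord <- order(alpha, decreasing = TRUE)
  if (length(alpha) > 1 && alpha[ord[1]] - alpha[ord[2]] < margin)
    return("no clear preference")
  names(alpha)[ord[1]]
}

#' Per-user cohort summary
#'
#' @param logs list of `session_log` objects.
#' @param margin dominance margin for [classify_dominant_style()].
#' @return data.frame with one row per user: trait, final alpha/beta
#'   per style, and the dominant style.
#' @export
cohort_summary <- function(logs, margin = 2) {
  do.call(rbind, lapply(logs, function(lg) {
    st <- lg$final_state
    row <- data.frame(user_id = lg$user_id, trait = lg$trait,
                      stringsAsFactors = FALSE)
    for (i in seq_along(st$alpha)) {
      row[[paste0("alpha_", st$style_names[i])]] <- st$alpha[i]
      row[[paste0("beta_", st$style_names[i])]] <- st$beta[i]
    }
    row$dominant <- classify_dominant_style(st, margin)
    row
  }))
}

#' Write / read a session log as JSONL
#'
#' One JSON object per turn record (including the turn's frame
#' labels), followed by a footer object with the config echo and the
#' final policy state. A round-trip preserves turn records, frames and
#' final posteriors.
#'
#' @param log a `session_log`.
#' @param path file path (conventionally `.jsonl`).
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  lines <- vapply(seq_len(nrow(log$turns)), function(t) {
    rec <- as.list(log$turns[t, ])
    rec$frames <- log$frames[[t]]
    # digits = I(17): enough significant digits for doubles to
    # round-trip bit-exactly, so replay checks survive serialization
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                                  null = "null", na = "null"))
  }, character(1))
  footer <- list(final = jsonlite::fromJSON(policy_to_json(log$final_state),
                                            simplifyVector = FALSE),
                 user_id = log$user_id, trait = log$trait,
                 n_turns = nrow(log$turns))
  writeLines(c(lines,
               as.character(jsonlite::toJSON(footer, auto_unbox = TRUE,
                                             digits = NA, na = "null"))),
             path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  n <- length(lines) - 1L
  recs <- lapply(lines[seq_len(n)], jsonlite::fromJSON)
  frames <- lapply(recs, function(r) {
    f <- r$frames
    if (is.null(f) || length(f) == 0L) NULL else as.character(f)
  })
  turns <- do.call(rbind, lapply(recs, function(r) {
    r$frames <- NULL
    r[vapply(r, is.null, logical(1))] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  footer <- jsonlite::fromJSON(lines[length(lines)], simplifyVector = FALSE)
  final <- policy_from_json(jsonlite::toJSON(footer$final, auto_unbox = TRUE,
                                             digits = NA))
  structure(list(config = NULL,
                 user_id = footer$user_id, trait = footer$trait,
                 turns = turns, frames = frames, final_state = final),
            class = "session_log")
}

#' Recompute logged rewards from logged frames
#'
#' Replay check: recomputes each turn's mean-valence reward from the
#' frame labels stored in the log. For turns with frames the result
#' must equal the logged reward exactly.
#'
#' @param log a `session_log`.
#' @param map a [valence_map()] (must match the one used in the run).
#' @return numeric vector of recomputed rewards (`NA` where the log
#'   has no frames).
#' @export
replay_rewards <- function(log, map = valence_map()) {
  v <- unclass(map)[EMOTION_LABELS]
  vapply(log$frames, function(f) {
    if (is.null(f)) NA_real_ else mean(v[match(f, EMOTION_LABELS)])
  }, numeric(1))
}
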