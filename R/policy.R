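#' Initialize a Thompson Sampling policy over communicative styles
#'
#' Each style (arm) carries a Beta posterior `Beta(alpha_i, beta_i)`
#' over its probability of "success", where a success is a turn whose
#' mean-valence reward did not decrease relative to the previous turn.
#' All arms start from uniform priors `(1, 1)` unless overridden.
#'
#' @param n_styles number of styles (arms), at least 1.
#' @param priors optional per-arm priors: a list of `(alpha, beta)`
#'   pairs or a 2-column matrix with `n_styles` rows. All prior values
#'   must be >= 1 (real-valued priors are allowed; updates are always
#'   +1 increments).
#' @param style_names character names for the arms; defaults to
#'   `c("neutral", "enthusiastic")` for two arms, `style1..styleN`
#'   otherwise.
#' @param seed integer seed for the policy's private random stream.
#' @return a `policy_state` object.
#' @examples
#' p <- init_policy(2, seed = 7)
#' p$alpha  # c(1, 1)
#' @export
init_policy <- function(n_styles = 2L, priors = NULL, style_names = NULL,
                        seed = 1L) {
  n_styles <- as.integer(n_styles)
  if (is.na(n_styles) || n_styles < 1L)
    stop("n_styles must be a positive integer", call. = FALSE)
  if (is.null(style_names)) {
    style_names <- if (n_styles == 2L) c("neutral", "enthusiastic")
                   else paste0("style", seq_len(n_styles))
  }
  if (length(style_names) != n_styles || anyDuplicated(style_names))
    stop("style_names must be ", n_styles, " distinct names", call. = FALSE)
  if (is.null(priors)) {
    a <- rep(1, n_styles); b <- rep(1, n_styles)
  } else {
    if (is.list(priors)) priors <- do.call(rbind, lapply(priors, as.numeric))
    priors <- as.matrix(priors)
    if (nrow(priors) != n_styles || ncol(priors) != 2L)
      stop("priors must supply one (alpha, beta) pair per style",
           call. = FALSE)
    if (any(priors < 1))
      stop("prior alpha and beta must all be >= 1", call. = FALSE)
    a <- priors[, 1]; b <- priors[, 2]
  }
  structure(list(
    style_names = style_names,
    alpha = a, beta = b,
    prior_alpha = a, prior_beta = b,
    plays = integer(n_styles),
    turn_counter = 0L,
    last_reward = NA_real_,  # absent until the first reward is observed
    seed = as.integer(seed),
    rng = rng_init(seed)
  ), class = "policy_state")
}

#' @export
print.policy_state <- function(x, ...) {
  cat("Thompson Sampling policy over", length(x$alpha), "style(s)\n")
  for (i in seq_along(x$alpha))
    cat(sprintf("  %-14s alpha = %g, beta = %g (posterior mean %.3f)\n",
                x$style_names[i], x$alpha[i], x$beta[i],
                x$alpha[i] / (x$alpha[i] + x$beta[i])))
  cat("turns observed:", x$turn_counter, "\n")
  invisible(x)
}

# fast path: assumes the caller has already installed the policy's RNG
.sample_select <- function(alpha, beta) {
  thetas <- stats::rbeta(length(alpha), alpha, beta)
  list(chosen = which.max(thetas), thetas = thetas)
}

#' Thompson Sampling selection step
#'
#' Draws `theta_i ~ Beta(alpha_i, beta_i)` independently for every arm
#' (in fixed arm-index order from the policy's seeded stream) and
#' selects the arm with the highest sample; floating-point ties break
#' to the lowest index. The policy's random stream advances
#' deterministically.
#'
#' @param state a `policy_state`.
#' @return list with `chosen` (arm index), `style` (arm name),
#'   `thetas` (the per-arm samples) and `state` (with advanced RNG).
#' @export
sample_and_select <- function(state) {
  stopifnot(inherits(state, "policy_state"))
  res <- rng_eval(state$rng, function() .sample_select(state$alpha, state$beta))
  state$rng <- res$rng
  list(chosen = res$value$chosen,
       style = state$style_names[res$value$chosen],
       thetas = res$value$thetas,
       state = state)
}

#' Success/failure update from a reward change
#'
#' Applies the Beta-Bernoulli bookkeeping for the arm played this
#' turn: a non-negative reward change `delta` increments the arm's
#' `alpha` (success); a negative `delta` increments its `beta`
#' (failure). No other arm is touched. Updates only apply from the
#' second observed turn onward (at the first turn there is no previous
#' reward); an update requested at turn 1 is a no-op with a warning.
#'
#' @param state a `policy_state` whose `turn_counter` reflects the
#'   turns observed so far.
#' @param played index (or name) of the arm selected this turn.
#' @param delta the reward change `R_t - R_{t-1}`.
#' @return the updated `policy_state`.
#' @export
update_from_delta <- function(state, played, delta) {
  stopifnot(inherits(state, "policy_state"))
  if (is.character(played)) played <- match(played, state$style_names)
  played <- as.integer(played)
  if (is.na(played) || played < 1L || played > length(state$alpha))
    stop("unknown arm: ", played, call. = FALSE)
  if (state$turn_counter < 2L) {
    warning("no update at turn ", state$turn_counter,
            ": a previous reward is required", call. = FALSE)
    return(state)
  }
  if (is.na(delta)) return(state)  # lenient missing-reward turn
  if (delta >= 0) state$alpha[played] <- state$alpha[played] + 1
  else            state$beta[played]  <- state$beta[played] + 1
  state
}

#' Observe a turn's reward and update the policy
#'
#' Convenience step combining the per-turn bookkeeping: increments the
#' turn counter, computes `delta = reward - last_reward` (from the
#' second turn onward), applies [update_from_delta()], and stores the
#' reward for the next turn. A missing reward (`NA`, lenient
#' empty-turn mode) leaves the posteriors and the stored last reward
#' untouched.
#'
#' @inheritParams update_from_delta
#' @param reward the turn's mean-valence reward (may be `NA`).
#' @return list with `state`, `delta` (NA at turn 1) and `update`
#'   (one of `"success"`, `"failure"`, `"none"`).
#' @export
policy_observe <- function(state, played, reward) {
  stopifnot(inherits(state, "policy_state"))
  if (is.character(played)) played <- match(played, state$style_names)
  state$turn_counter <- state$turn_counter + 1L
  state$plays[played] <- state$plays[played] + 1L
  delta <- NA_real_
  update <- "none"
  if (!is.na(reward)) {
    if (state$turn_counter >= 2L && !is.na(state$last_reward)) {
      delta <- reward - state$last_reward
      state <- update_from_delta(state, played, delta)
      update <- if (delta >= 0) "success" else "failure"
    }
    state$last_reward <- reward
  }
  list(state = state, delta = delta, update = update)
}

#' Posterior mean of an arm's success probability
#'
#' @param x a `policy_state` (returns the per-arm vector) or a numeric
#'   alpha value.
#' @param beta numeric beta value when `x` is numeric.
#' @return numeric vector of posterior means `alpha / (alpha + beta)`.
#' @examples
#' posterior_mean(3, 1)  # 0.75
#' @export
posterior_mean <- function(x, beta = NULL) {
  if (inherits(x, "policy_state")) {
    out <- x$alpha / (x$alpha + x$beta)
    names(out) <- x$style_names
    return(out)
  }
  x / (x + beta)
}

# empirical success rate per arm from the update counts; arms with no
# updates fall back to 0.5 (uninformative)
.empirical_rates <- function(state) {
  succ <- state$alpha - state$prior_alpha
  fail <- state$beta - state$prior_beta
  n <- succ + fail
  ifelse(n > 0, succ / n, 0.5)
}

#' Baseline (non-Thompson) selection rules
#'
#' Reference policies for benchmarking the Thompson Sampling selector:
#' epsilon-greedy (with probability `1 - epsilon` play the arm with
#' the highest empirical success rate, otherwise a uniform arm), UCB
#' (argmax of empirical rate plus `c * sqrt(log(total updates) / arm
#' updates)`, with never-updated arms tried first), and uniform random
#' selection. Empirical rates are computed from the success/failure
#' counts accumulated through [update_from_delta()].
#'
#' @param state a `policy_state`.
#' @param method one of `"epsilon_greedy"`, `"ucb"`, `"uniform"`.
#' @param epsilon exploration rate in `[0, 1]` for epsilon-greedy.
#' @param c_ucb positive exploration constant for UCB.
#' @return list with `chosen`, `style` and `state` (advanced RNG).
#' @export
baseline_select <- function(state,
                            method = c("epsilon_greedy", "ucb", "uniform"),
                            epsilon = 0.1, c_ucb = sqrt(2)) {
  stopifnot(inherits(state, "policy_state"))
  method <- match.arg(method)
  if (method == "epsilon_greedy" && (epsilon < 0 || epsilon > 1))
    stop("epsilon must lie in [0, 1]", call. = FALSE)
  if (method == "ucb" && c_ucb <= 0)
    stop("UCB exploration constant must be positive", call. = FALSE)
  n <- length(state$alpha)
  res <- rng_eval(state$rng, function() {
    switch(method,
      uniform = sample.int(n, 1L),
      epsilon_greedy = {
        if (stats::runif(1) < epsilon) sample.int(n, 1L)
        else which.max(.empirical_rates(state))
      },
      ucb = {
        updates <- (state$alpha - state$prior_alpha) +
                   (state$beta - state$prior_beta)
        if (any(updates == 0)) which(updates == 0)[1L]
        else which.max(.empirical_rates(state) +
                       c_ucb * sqrt(log(sum(updates)) / updates))
      })
  })
  state$rng <- res$rng
  list(chosen = res$value, style = state$style_names[res$value], state = state)
}

#' Serialize / restore a policy state as JSON
#'
#' The JSON form is
#' `{"arms":[{"name":..,"alpha":..,"beta":..}],"turn":..,"last_reward":..,"seed":..}`
#' plus internal fields (priors, play counts, RNG stream) so that a
#' round-trip restores the state exactly.
#'
#' @param state a `policy_state`.
#' @param path optional file path; if omitted the JSON string is
#'   returned.
#' @export
policy_to_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "policy_state"))
  obj <- list(
    arms = lapply(seq_along(state$alpha), function(i)
      list(name = state$style_names[i],
           alpha = state$alpha[i], beta = state$beta[i],
           prior_alpha = state$prior_alpha[i],
           prior_beta = state$prior_beta[i],
           plays = state$plays[i])),
    turn = state$turn_counter,
    last_reward = if (is.na(state$last_reward)) NULL else state$last_reward,
    seed = state$seed,
    rng = state$rng
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname policy_to_json
#' @param json JSON string or file path produced by [policy_to_json()].
#' @export
policy_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyDataFrame = TRUE)
  arms <- obj$arms
  state <- structure(list(
    style_names = as.character(arms$name),
    alpha = as.numeric(arms$alpha), beta = as.numeric(arms$beta),
    prior_alpha = as.numeric(arms$prior_alpha),
    prior_beta = as.numeric(arms$prior_beta),
    plays = as.integer(arms$plays),
    turn_counter = as.integer(obj$turn),
    last_reward = if (is.null(obj$last_reward)) NA_real_
                  else as.numeric(obj$last_reward),
    seed = as.integer(obj$seed),
    rng = as.integer(obj$rng)
  ), class = "policy_state")
  state
}
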