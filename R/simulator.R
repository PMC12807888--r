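#' Synthetic affective user
#'
#' A simulated user is defined by a per-style categorical emission
#' distribution over the seven emotion labels: during a turn delivered
#' in style `s`, every frame's label is drawn i.i.d. from
#' `emission[s, ]`. The construction couples the emissions to a
#' personality-like trait through an exponential tilting of a common
#' baseline distribution `b`:
#'
#' `pi_s(e) proportional to b(e) * exp(kappa_s * V(e))`
#'
#' where `V` is the valence map and `kappa_s` is the style's affective
#' gain for this user. The gain gap `kappa_neutral - kappa_enthusiastic`
#' follows a logistic link in the standardized trait, so users with a
#' higher trait value show a larger expected-valence advantage for the
#' *neutral* style (and vice versa). `preference_strength` scales the
#' gap (0 gives a null user whose styles share one emission
#' distribution); `noise_level` mixes the emissions toward the uniform
#' distribution with weight `noise_level / (1 + noise_level)`,
#' flattening style differences.
#'
#' @param user_id identifier.
#' @param trait trait score on the `trait_range` scale (default scale
#'   0-32, emulating an EPQ Psychoticism score).
#' @param preference_strength effect size (>= 0) separating the two
#'   styles' affective gains at the extremes of the trait scale.
#' @param noise_level uniform-mixing weight parameter (>= 0).
#' @param link_slope slope of the logistic trait link (per standardized
#'   trait unit).
#' @param baseline_gain common affective gain added to both styles.
#' @param trait_range numeric length-2 range of the trait scale.
#' @param base baseline emission distribution (named over
#'   [EMOTION_LABELS]); the default is a Neutral-dominated mix typical
#'   of a seated questionnaire interaction.
#' @param map a [valence_map()].
#' @param styles style names, default `c("neutral", "enthusiastic")`.
#' @param emission optional explicit emission matrix
#'   (`length(styles)` rows, 7 columns named by [EMOTION_LABELS]); if
#'   supplied it overrides the trait-linked construction.
#' @return a `user_profile` object.
#' @export
user_profile <- function(user_id = 1L, trait = 16, preference_strength = 1,
                         noise_level = 0.5, link_slope = 1.5,
                         baseline_gain = 0, trait_range = c(0, 32),
                         base = c(Angry = 0.06, Disgust = 0.04, Fear = 0.06,
                                  Happy = 0.15, Sad = 0.08, Surprise = 0.06,
                                  Neutral = 0.55),
                         map = valence_map(),
                         styles = c("neutral", "enthusiastic"),
                         emission = NULL) {
  if (preference_strength < 0) stop("preference_strength must be >= 0",
                                    call. = FALSE)
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  v <- unclass(map)[EMOTION_LABELS]
  if (is.null(emission)) {
    base <- base[EMOTION_LABELS]
    if (anyNA(base) || any(base < 0) || abs(sum(base) - 1) > 1e-9)
      stop("base must be a distribution over the 7 emotion labels",
           call. = FALSE)
    mid <- mean(trait_range); half <- diff(range(trait_range)) / 2
    z <- (trait - mid) / (half / 2)  # standardized trait
    gap <- preference_strength * (2 * stats::plogis(link_slope * z) - 1)
    kappa <- c(baseline_gain + gap / 2, baseline_gain - gap / 2)
    names(kappa) <- styles
    w <- noise_level / (1 + noise_level)
    emission <- t(vapply(kappa, function(k) {
      p <- base * exp(k * v)
      p <- p / sum(p)
      (1 - w) * p + w / length(p)
    }, numeric(7)))
    colnames(emission) <- EMOTION_LABELS
  } else {
    emission <- as.matrix(emission)
    if (nrow(emission) != length(styles) || ncol(emission) != 7L)
      stop("emission must be a (styles x 7) matrix", call. = FALSE)
    if (is.null(colnames(emission))) colnames(emission) <- EMOTION_LABELS
    emission <- emission[, EMOTION_LABELS, drop = FALSE]
    rownames(emission) <- styles
    if (any(emission < 0) || any(abs(rowSums(emission) - 1) > 1e-9))
      stop("each emission row must be a probability distribution",
           call. = FALSE)
  }
  rownames(emission) <- styles
  structure(list(user_id = user_id, trait = trait,
                 preference_strength = preference_strength,
                 noise_level = noise_level,
                 styles = styles, emission = emission,
                 valence = v),
            class = "user_profile")
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("synthetic user %s: trait = %.2f\n", x$user_id, x$trait))
  for (s in x$styles)
    cat(sprintf("  %-14s expected valence = %+.4f\n", s,
                expected_valence(x, s)))
  invisible(x)
}

#' Expected per-frame valence of a user under a style
#'
#' Closed-form mean `sum_e pi(style, e) * V(e)`; by the law of large
#' numbers this is also the expected per-turn reward, whatever the
#' number of frames.
#'
#' @param profile a [user_profile()].
#' @param style style name or index.
#' @param map optional valence map overriding the profile's.
#' @return expected valence (valence units).
#' @export
expected_valence <- function(profile, style, map = NULL) {
  stopifnot(inherits(profile, "user_profile"))
  v <- if (is.null(map)) profile$valence else unclass(map)[EMOTION_LABELS]
  p <- profile$emission[style, ]
  sum(p * v)
}

#' Draw one turn's emotion frames for a synthetic user
#'
#' Frame labels are drawn i.i.d. from the user's emission distribution
#' for the delivered style.
#'
#' @inheritParams expected_valence
#' @param n_frames number of frames (>= 1).
#' @param seed optional seed; if `NULL` the current RNG stream is
#'   consumed (set a seed beforehand for reproducibility).
#' @return data.frame with columns `frame` (0-based) and `emotion`.
#' @export
emit_turn_frames <- function(profile, style, n_frames, seed = NULL) {
  stopifnot(inherits(profile, "user_profile"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("n_frames must be a positive integer", call. = FALSE)
  draw <- function() sample.int(7L, n_frames, replace = TRUE,
                                prob = profile$emission[style, ])
  codes <- if (is.null(seed)) draw()
           else with_preserved_rng({ set.seed(seed); draw() })
  data.frame(frame = seq_len(n_frames) - 1L,
             emotion = EMOTION_LABELS[codes],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws `n_users` users whose traits are sampled uniformly over the
#' trait scale and whose style preferences follow the logistic
#' trait link of [user_profile()]. By construction the
#' neutral-minus-enthusiastic expected-valence gap is monotone
#' increasing in the trait.
#'
#' @param n_users number of users (>= 1).
#' @param seed master seed for the cohort draw.
#' @param trait_range trait scale, default `c(0, 32)`.
#' @param ... further arguments passed to [user_profile()]
#'   (`preference_strength`, `noise_level`, `link_slope`, ...).
#' @return list of `user_profile` objects with `user_id` 1..n.
#' @export
make_cohort <- function(n_users = 20L, seed = 1L, trait_range = c(0, 32),
                        ...) {
  n_users <- as.integer(n_users)
  if (is.na(n_users) || n_users < 1L)
    stop("n_users must be a positive integer", call. = FALSE)
  traits <- with_preserved_rng({
    set.seed(as.integer(seed))
    stats::runif(n_users, trait_range[1], trait_range[2])
  })
  lapply(seq_len(n_users), function(i)
    user_profile(user_id = i, trait = traits[i], trait_range = trait_range,
                 ...))
}

#' Direct Bernoulli-success user
#'
#' A reward-level user abstraction for bandit diagnostics: instead of
#' emitting emotion frames, the user produces a reward sequence whose
#' turn-to-turn change is non-negative with exactly the per-style
#' probability `success_probs[style]`. On a success the reward moves
#' up by a random fraction of the remaining headroom to the valence
#' ceiling; on a failure it moves down likewise, so rewards stay
#' strictly inside the valence range and the sign of the change
#' matches the Bernoulli draw with probability one.
#'
#' @param success_probs named or positional numeric vector in `[0, 1]`,
#'   one probability per style.
#' @param step_frac fraction (in `(0, 1)`) of the available headroom
#'   used as the maximal step size.
#' @param r0 initial reward (strictly inside `bounds`).
#' @param bounds reward range; defaults to the range of the default
#'   valence map.
#' @return a `bernoulli_user` object.
#' @export
bernoulli_user <- function(success_probs, step_frac = 0.2, r0 = 0,
                           bounds = range(valence_map())) {
  if (any(success_probs < 0 | success_probs > 1))
    stop("success probabilities must lie in [0, 1]", call. = FALSE)
  if (step_frac <= 0 || step_frac >= 1)
    stop("step_frac must lie in (0, 1)", call. = FALSE)
  if (r0 <= bounds[1] || r0 >= bounds[2])
    stop("r0 must lie strictly inside bounds", call. = FALSE)
  structure(list(success_probs = as.numeric(success_probs),
                 step_frac = step_frac, r0 = r0, bounds = bounds),
            class = "bernoulli_user")
}

# ---- internal session-facing interface -------------------------------
# user_turn() consumes the currently-active RNG stream and returns the
# turn's frames (emotion codes, or NULL for reward-level users) and
# reward.

user_turn <- function(user, style_index, n_frames, prev_reward) {
  UseMethod("user_turn")
}

#' @export
user_turn.user_profile <- function(user, style_index, n_frames,
                                   prev_reward) {
  codes <- sample.int(7L, n_frames, replace = TRUE,
                      prob = user$emission[style_index, ])
  list(frames = codes, reward = mean(user$valence[codes]))
}

#' @export
user_turn.bernoulli_user <- function(user, style_index, n_frames,
                                     prev_reward) {
  r <- if (is.na(prev_reward)) user$r0 else prev_reward
  success <- stats::runif(1) < user$success_probs[style_index]
  u <- stats::runif(1)
  reward <- if (success) r + u * user$step_frac * (user$bounds[2] - r)
            else         r - u * user$step_frac * (r - user$bounds[1])
  list(frames = NULL, reward = reward)
}

#' Write / read a synthetic cohort as JSON
#'
#' Serializes each user's identifier, trait, generator parameters and
#' the realized per-style emission matrix. A round-trip preserves the
#' emission distributions exactly (each row remains a valid simplex
#' point).
#'
#' @param cohort list of [user_profile()] objects.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  obj <- lapply(cohort, function(u) {
    list(user_id = u$user_id, trait = u$trait,
         preference_strength = u$preference_strength,
         noise_level = u$noise_level,
         styles = u$styles,
         emission = apply(u$emission, 1L, as.list, simplify = FALSE))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj, function(u) {
    em <- do.call(rbind, lapply(u$emission, function(row)
      unlist(row)[EMOTION_LABELS]))
    user_profile(user_id = u$user_id, trait = u$trait,
                 preference_strength = u$preference_strength,
                 noise_level = u$noise_level,
                 styles = unlist(u$styles), emission = em)
  })
}
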