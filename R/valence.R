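#' Canonical facial-emotion labels
#'
#' The seven basic-emotion categories recognized by the upstream
#' frame-level classifier. All label handling in the package is reduced
#' to this set; matching is case-insensitive and the noun forms
#' "Happiness", "Sadness" and "Anger" are accepted as synonyms of
#' "Happy", "Sad" and "Angry".
#'
#' @format Character vector of length 7.
#' @export
EMOTION_LABELS <- c("Angry", "Disgust", "Fear", "Happy", "Sad",
                    "Surprise", "Neutral")

# synonym -> canonical, all lower case
.emotion_synonyms <- c(
  happiness = "Happy",
  sadness   = "Sad",
  anger     = "Angry"
)

#' Normalize emotion labels to the canonical 7-class set
#'
#' @param x character vector of emotion labels.
#' @return character vector of canonical labels (elements of
#'   [EMOTION_LABELS]).
#' @examples
#' canonical_emotion(c("happy", "Happiness", "FEAR"))
#' @export
canonical_emotion <- function(x) {
  if (!is.character(x)) stop("emotion labels must be character", call. = FALSE)
  low <- tolower(trimws(x))
  syn <- .emotion_synonyms[low]
  canon <- ifelse(is.na(syn), EMOTION_LABELS[match(low, tolower(EMOTION_LABELS))], syn)
  bad <- is.na(canon)
  if (any(bad)) {
    stop("unknown emotion label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  unname(canon)
}

#' Valence lookup table for the seven basic emotions
#'
#' Builds the emotion-to-valence map used by the reward computation.
#' The default scores are the calibration used throughout the package:
#' Happy +0.76, Surprise +0.40, Neutral 0.00, Angry -0.43,
#' Disgust -0.60, Sad -0.63, Fear -0.64. A custom map must assign a
#' score to every one of the seven labels; partial maps are rejected.
#'
#' @param scores optional named numeric vector of valence scores, one
#'   per emotion label (names matched through [canonical_emotion()]).
#'   Scores must lie in `[-1, 1]`.
#' @return named numeric vector of length 7, class `"valence_map"`.
#' @examples
#' vm <- valence_map()
#' vm["Happy"]
#' @export
valence_map <- function(scores = NULL) {
  default <- c(Happy = 0.76, Surprise = 0.40, Neutral = 0.00,
               Angry = -0.43, Disgust = -0.60, Sad = -0.63, Fear = -0.64)
  if (is.null(scores)) {
    out <- default[EMOTION_LABELS]
  } else {
    if (is.null(names(scores)) || !is.numeric(scores))
      stop("scores must be a named numeric vector", call. = FALSE)
    names(scores) <- canonical_emotion(names(scores))
    if (anyDuplicated(names(scores)))
      stop("duplicate emotion label in valence scores", call. = FALSE)
    missing <- setdiff(EMOTION_LABELS, names(scores))
    if (length(missing))
      stop("valence map is missing label(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (any(scores < -1 | scores > 1))
      stop("valence scores must lie in [-1, 1]", call. = FALSE)
    out <- scores[EMOTION_LABELS]
  }
  structure(out, class = c("valence_map", "numeric"))
}

#' Look up the valence score of an emotion label
#'
#' @param label emotion label (any accepted spelling).
#' @param map a [valence_map()].
#' @return numeric valence score(s).
#' @examples
#' valence_of("Happiness")  # 0.76
#' @export
valence_of <- function(label, map = valence_map()) {
  unname(unclass(map)[canonical_emotion(label)])
}

#' Per-turn mean-valence reward
#'
#' The reward for one interaction turn is the average valence of the
#' emotion labels observed over the turn's frames:
#' `R = (1/T) * sum(V(e_t))`.
#'
#' @param frames character vector of emotion labels, one per frame, or
#'   a data.frame with a column `emotion`.
#' @param map a [valence_map()].
#' @param turn_index positive integer identifying the turn.
#' @param strict if `TRUE` (default) an empty frame sequence is an
#'   error; if `FALSE` the turn is recorded with a missing reward
#'   (`NA`), signalling that no face was detected and no policy update
#'   should be made for this turn.
#' @return a `turn_reward` object: list with `turn_index`, `reward`
#'   and `frame_count`.
#' @examples
#' turn_reward(rep("Happy", 50))$reward  # 0.76
#' turn_reward(c("Happy", "Sad"))$reward # 0.065
#' @export
turn_reward <- function(frames, map = valence_map(), turn_index = 1L,
                        strict = TRUE) {
  if (is.data.frame(frames)) frames <- frames$emotion
  turn_index <- as.integer(turn_index)
  if (turn_index < 1L) stop("turn_index must be positive", call. = FALSE)
  n <- length(frames)
  if (n == 0L) {
    if (strict)
      stop("empty frame sequence for turn ", turn_index,
           " (no face detected); use strict = FALSE to record a missing reward",
           call. = FALSE)
    r <- NA_real_
  } else {
    r <- mean(valence_of(frames, map))
  }
  structure(list(turn_index = turn_index, reward = r, frame_count = n),
            class = "turn_reward")
}

#' @export
print.turn_reward <- function(x, ...) {
  cat(sprintf("turn %d: reward = %s over %d frame(s)\n",
              x$turn_index,
              if (is.na(x$reward)) "NA" else format(x$reward), x$frame_count))
  invisible(x)
}

#' Turn-to-turn reward change
#'
#' Computes the variation of the mean-valence reward relative to the
#' previous turn, `dR = R_t - R_{t-1}`. A non-negative change counts as
#' a success for the style played at turn t; a negative change counts
#' as a failure.
#'
#' @param current,previous `turn_reward` objects for consecutive turns
#'   (`current$turn_index == previous$turn_index + 1`), or bare
#'   numeric rewards (in which case turn indices are not checked).
#' @return list with `delta` and `success` (logical, `delta >= 0`).
#' @examples
#' a <- turn_reward("Happy", turn_index = 2)
#' b <- turn_reward("Sad", turn_index = 1)
#' delta_reward(a, b)
#' @export
delta_reward <- function(current, previous) {
  if (inherits(current, "turn_reward") && inherits(previous, "turn_reward")) {
    if (current$turn_index != previous$turn_index + 1L)
      stop("turns are not consecutive: ", previous$turn_index, " -> ",
           current$turn_index, call. = FALSE)
    d <- current$reward - previous$reward
  } else {
    d <- as.numeric(current) - as.numeric(previous)
  }
  list(delta = d, success = d >= 0)
}

#' Read / write emotion-frame streams
#'
#' The stream format is UTF-8 CSV with header `turn,frame,emotion`,
#' one row per frame; turns are numbered from 1 and frames from 0
#' within each turn.
#'
#' @param path file path.
#' @return `read_emotion_stream()` returns a data.frame with columns
#'   `turn` (integer), `frame` (integer) and `emotion` (canonical
#'   label).
#' @export
read_emotion_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("turn", "frame", "emotion")
  if (!all(need %in% names(df)))
    stop("emotion stream must have header turn,frame,emotion", call. = FALSE)
  df <- df[need]
  df$turn <- as.integer(df$turn)
  df$frame <- as.integer(df$frame)
  df$emotion <- canonical_emotion(df$emotion)
  if (any(df$turn < 1L)) stop("turns are numbered from 1", call. = FALSE)
  if (any(df$frame < 0L)) stop("frames are numbered from 0", call. = FALSE)
  if (anyDuplicated(df[c("turn", "frame")]))
    stop("duplicate (turn, frame) pair in stream", call. = FALSE)
  df
}

#' @rdname read_emotion_stream
#' @param stream data.frame with columns `turn`, `frame`, `emotion`.
#' @export
write_emotion_stream <- function(stream, path) {
  utils::write.csv(stream[c("turn", "frame", "emotion")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Rewards for every turn of an emotion stream
#'
#' @param stream data.frame as returned by [read_emotion_stream()].
#' @inheritParams turn_reward
#' @return data.frame with columns `turn`, `reward`, `frame_count`.
#' @export
stream_rewards <- function(stream, map = valence_map(), strict = TRUE) {
  turns <- sort(unique(stream$turn))
  res <- lapply(turns, function(tt) {
    tr <- turn_reward(stream$emotion[stream$turn == tt], map,
                      turn_index = tt, strict = strict)
    data.frame(turn = tt, reward = tr$reward, frame_count = tr$frame_count)
  })
  do.call(rbind, res)
}
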