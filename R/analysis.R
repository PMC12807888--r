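#' Posterior-parameter trajectories of a session
#'
#' Extracts the turn-by-turn evolution of every arm's Beta parameters
#' from a session log (post-update snapshots). Alpha and beta columns
#' are non-decreasing in the turn index.
#'
#' @param log a `session_log`.
#' @return data.frame with `turn` plus one `alpha_*` and `beta_*`
#'   column per style.
#' @export
alpha_trajectories <- function(log) {
  stopifnot(inherits(log, "session_log"))
  cols <- grep("^(alpha|beta)_", names(log$turns), value = TRUE)
  log$turns[c("turn", cols)]
}

# all permutations of 1..n as an (n! x n) integer matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  vals <- seq_len(n)
  for (i in vals) {
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(vals[-i][sub], m)
  }
  out
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Computes Spearman's rho on average ranks (ties receive the mean of
#' the tied ranks) with a two-sided p-value. For `n <= 10` the p-value
#' is exact, obtained by enumerating all `n!` permutations of one
#' margin (valid with or without ties); for larger n the standard
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n` and `method`.
#' @examples
#' spearman_correlation(1:4, c(10, 20, 30, 40))$rho  # 1
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant input: rank correlation undefined", call. = FALSE)
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    perm <- all_permutations(n)
    # rho is monotone in the rank cross-product, so compare on that scale
    s_perm <- as.vector(matrix(ry[perm], nrow(perm)) %*% rx)
    center <- n * mean(rx) * mean(ry)
    p <- mean(abs(s_perm - center) >= abs(sum(rx * ry) - center) - 1e-9)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

#' Correlation between a user trait and a style's final alpha
#'
#' Spearman rank correlation between the cohort's trait values and the
#' final success count (alpha) of one style, the session-level summary
#' used to relate personality to the style the policy reinforced.
#'
#' @param logs list of `session_log` objects (or a [cohort_summary()]
#'   data.frame).
#' @param style style name (e.g. `"neutral"`).
#' @param traits optional data.frame with columns `user_id` and
#'   `trait` overriding the traits recorded in the logs; every logged
#'   user must be present.
#' @return a [spearman_correlation()] result.
#' @export
trait_style_correlation <- function(logs, style, traits = NULL) {
  summ <- if (is.data.frame(logs)) logs else cohort_summary(logs)
  col <- paste0("alpha_", style)
  if (!col %in% names(summ)) stop("unknown style: ", style, call. = FALSE)
  if (!is.null(traits)) {
    idx <- match(summ$user_id, traits$user_id)
    if (anyNA(idx))
      stop("missing trait for user(s): ",
           paste(summ$user_id[is.na(idx)], collapse = ", "), call. = FALSE)
    summ$trait <- traits$trait[idx]
  }
  spearman_correlation(summ$trait, summ[[col]])
}

#' Cumulative regret of a logged session
#'
#' Standard bandit diagnostic against simulator ground truth: the sum
#' over turns of the gap between the best style's success probability
#' and the played style's. Zero iff the best arm was played every
#' turn; non-negative and non-decreasing turn by turn.
#'
#' @param log a `session_log`.
#' @param success_probs true per-style success probabilities, named by
#'   style or in arm order.
#' @param cumulative if `TRUE` return the per-turn cumulative curve
#'   instead of the final total.
#' @return numeric scalar (or vector when `cumulative = TRUE`).
#' @export
cumulative_regret <- function(log, success_probs, cumulative = FALSE) {
  stopifnot(inherits(log, "session_log"))
  styles <- unique(log$turns$style)
  if (!is.null(names(success_probs))) {
    if (!all(styles %in% names(success_probs)))
      stop("unknown style in log: ",
           paste(setdiff(styles, names(success_probs)), collapse = ", "),
           call. = FALSE)
    p <- unname(success_probs[log$turns$style])
  } else {
    p <- success_probs[log$turns$chosen]
    if (anyNA(p)) stop("unknown style index in log", call. = FALSE)
  }
  gaps <- max(success_probs) - p
  if (cumulative) cumsum(gaps) else sum(gaps)
}
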