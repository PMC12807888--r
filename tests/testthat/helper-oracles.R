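# independent hand-counting oracle for Beta-Bernoulli bookkeeping:
# given played-arm indices and the reward sequence, count successes and
# failures per arm (updates start at the second turn; delta >= 0 is a
# success)
count_updates <- function(played, rewards, n_arms) {
  succ <- fail <- numeric(n_arms)
  for (t in seq_along(rewards)) {
    if (t < 2) next
    d <- rewards[t] - rewards[t - 1]
    if (d >= 0) succ[played[t]] <- succ[played[t]] + 1
    else fail[played[t]] <- fail[played[t]] + 1
  }
  list(successes = succ, failures = fail)
}

default_valences <- c(Happy = 0.76, Surprise = 0.40, Neutral = 0.00,
                      Angry = -0.43, Disgust = -0.60, Sad = -0.63,
                      Fear = -0.64)
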