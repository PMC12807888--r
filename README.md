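# affectbandit

Affect-adaptive interaction style selection with Thompson Sampling.

`affectbandit` implements the adaptation engine of an affect-aware
conversational agent for structured interactions such as
behavior-change questionnaires. At every interaction turn the agent
must choose a communicative style — by default *neutral* (concise,
factual, emotionally restrained) vs *enthusiastic* (supportive,
motivational, positively expressive) — and it learns online, per user,
which style best maintains or improves the emotional valence the user
expresses while responding. The package is aimed at researchers in
affective computing and digital health who want to study these
adaptation dynamics (convergence, regret, trait–style associations)
reproducibly at desk scale, without cameras, speech services or human
participants: inputs start at the level of categorical emotion labels.

## The model

Each frame of a turn carries one of seven basic-emotion labels, mapped
to a fixed valence score `V(e)`:

| Emotion  | V(e)  |
|----------|-------|
| Happy    | +0.76 |
| Surprise | +0.40 |
| Neutral  |  0.00 |
| Angry    | −0.43 |
| Disgust  | −0.60 |
| Sad      | −0.63 |
| Fear     | −0.64 |

The per-turn reward is the mean valence over the turn's `T` frames,

    R_t = (1/T) · Σ V(e_t),

and the learning signal is its change between consecutive turns,
`ΔR = R_t − R_{t−1}`. Each style `i` holds a Beta posterior
`Beta(α_i, β_i)` over its success probability, starting from uniform
priors `α_i = β_i = 1`. Every turn the policy samples
`θ_i ~ Beta(α_i, β_i)` and plays `argmax θ_i`; from the second turn
onward, `ΔR ≥ 0` increments the played arm's `α` (success) and
`ΔR < 0` its `β` (failure). Nothing else about the user's answer is
used by the policy.

Around this core the package provides a synthetic affective-user
simulator (per-style emotion-emission distributions coupled to a
personality-like trait through a monotone logistic link), a session
orchestrator producing replayable JSONL logs, baseline policies
(ε-greedy, UCB, uniform) for benchmarking, and analysis helpers:
posterior trajectories, Spearman trait correlations (exact permutation
p-values for n ≤ 10), and cumulative regret.

## Worked example

```r
library(affectbandit)

# a synthetic user whose trait (0-32 scale) tilts them toward the
# neutral style
user <- user_profile(user_id = 1, trait = 26,
                     preference_strength = 2, noise_level = 0.3)
user
#> synthetic user 1: trait = 26.00
#>   neutral        expected valence = +0.0660
#>   enthusiastic   expected valence = -0.1337

# one 32-item session under the Thompson Sampling policy
log <- run_session(user, make_default_script(), session_config(seed = 42))
log
#> session log: 32 turn(s), 31 update(s)
#> Thompson Sampling policy over 2 style(s)
#>   neutral        alpha = 14, beta = 10 (posterior mean 0.583)
#>   enthusiastic   alpha = 4, beta = 7 (posterior mean 0.364)
#> turns observed: 32

classify_dominant_style(log)
#> [1] "neutral"
```

The final `alpha = 14` vs `4` says the policy banked 13 successes on
the neutral style against 3 on the enthusiastic one (each arm starts
at 1), so over 32 turns it learned to favor the style this user's
emission profile actually rewards; `classify_dominant_style()` calls
the session for *neutral* because the α gap exceeds the 2-count
margin. `alpha_trajectories(log)` returns the turn-by-turn α/β table
behind this, and `build_style_prompt()` renders the exact rephrasing
instruction sent to a language model for any item and style.

Cohort-level experiments follow the same pattern: `make_cohort(50)`,
`run_cohort()`, `cohort_summary()`, then
`trait_style_correlation(logs, "neutral")` to measure how the trait
ranks against each style's final α.

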