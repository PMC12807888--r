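---
title: "Affect-adaptive style selection: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affect-adaptive style selection: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectbandit)
```

## The adaptation problem

A conversational agent delivering a fixed script of items (the
intended instrument is a 32-item readiness-to-change questionnaire)
can phrase each item in different communicative styles. Which style
keeps a given user emotionally engaged is unknown in advance and
differs between users, so the agent must learn it *during* the
session, from the only affective signal it observes: the stream of
categorical facial-emotion labels produced by a frame-level classifier
while the user responds.

`affectbandit` implements this loop as a Beta–Bernoulli multi-armed
bandit over styles, with a valence-based reward. The package starts at
the label level on purpose: face detection and emotion classification
are upstream concerns, and everything here is deterministic given the
label streams and the seeds.

## Reward model

Each label has a fixed valence score (Happy +0.76, Surprise +0.40,
Neutral 0.00, Angry −0.43, Disgust −0.60, Sad −0.63, Fear −0.64);
these empirical anchors are the package default and the only
calibration. A turn's reward is the mean valence over its frames.
Averaging suppresses frame-level classifier flicker; using the
*change* `ΔR = R_t − R_{t−1}` rather than the absolute level makes the
signal robust to inter-individual baseline expressiveness (a user who
rarely smiles can still reward a style by becoming *less* negative).

Two conventions matter and are fixed throughout:

* `ΔR = 0` is a **success**: stabilizing affect is as good as
  improving it.
* There is no update at the first turn — no previous reward exists.
  A 32-turn session therefore applies exactly 31 updates. The
  conventional initial value `R_0 = 0` is retained in logs only.

A custom valence map may be supplied but must cover all seven labels;
partial maps are rejected rather than silently defaulted. Labels are
matched case-insensitively and the noun forms (Happiness, Sadness,
Anger) are accepted, since both spellings circulate in the literature
on this classifier family.

### Empty turns

If no face is detected during a turn the frame sequence is empty and
the mean is undefined. In strict mode (default) this is an error; in
lenient mode (`strict = FALSE`) the turn is logged with a missing
reward, no update is applied, and the next delta is computed against
the last *observed* reward. Both behaviors are explicit and tested;
silent imputation was rejected because a fabricated reward would feed
the policy noise it cannot distinguish from signal.

## Selection policy

Each style holds `Beta(α_i, β_i)`, initialized at the uniform
`(1, 1)` unless overridden (priors are real-valued ≥ 1 to allow
sensitivity experiments; updates are always +1, so the defaults
reproduce the canonical integer bookkeeping). Selection samples
`θ_i ~ Beta(α_i, β_i)` in fixed arm-index order from the policy's
private seeded stream and plays the argmax. Floating-point ties break
to the lowest index — a measure-zero event for Beta samples, fixed
anyway for determinism.

Baseline selectors (ε-greedy, UCB with exploration constant
`c·sqrt(log N / n_i)` and unplayed-arms-first initialization, and
uniform) are provided purely as benchmarking contrasts; their
empirical success rates come from the same update counts.

### Seeding

A session's master seed deterministically derives two sub-streams —
one for the policy's Beta draws, one for the simulator — so logs are
bit-reproducible regardless of module call order, and cohort runs
derive one sub-seed per user from the cohort master seed. All derived
seeds stay below 2^31.

## The synthetic user

No deposited interaction data exist for this setting, so the simulator
is a first-class module. A user is a pair of categorical emission
distributions (one per style) over the seven labels, built by
exponentially tilting a common baseline `b` by the valence vector:

`π_s(e) ∝ b(e) · exp(κ_s · V(e))`

* The baseline `b` is Neutral-dominated (Neutral 0.55, Happy 0.15,
  Sad 0.08, Angry 0.06, Fear 0.06, Surprise 0.06, Disgust 0.04) — a
  realistic mix for a seated questionnaire interaction where most
  frames show a composed face.
* The per-style gain gap `κ_neutral − κ_enthusiastic` follows a
  logistic link in the standardized trait (default slope 1.5 per
  standardized unit), scaled by `preference_strength`. The trait scale
  defaults to 0–32 for interpretability against a psychoticism-type
  personality questionnaire, and the link direction is fixed so higher
  trait values favor the *neutral* style. Tilting is monotone (the
  derivative of the expected valence in κ is a variance), so the
  expected-valence gap is monotone in the trait by construction.
* `preference_strength = 0` collapses both styles onto one
  distribution — the null user used for exchangeability checks.
* `noise_level` mixes the emissions toward the uniform distribution
  with weight `noise/(1 + noise)`, flattening style differences.

Defaults (`preference_strength = 1`, `noise_level = 0.5`,
`link_slope = 1.5`, traits uniform over 0–32) were chosen once as a
realistic middle ground: style gaps in expected valence of a few
hundredths to ~0.2 valence units, i.e. clearly present but far from
deterministic, with per-frame noise dominating any single turn.

Frame labels are i.i.d. within a turn. Real classifier output is
temporally autocorrelated (expressions persist across frames); an
autocorrelation parameter was considered and left out because no
within-turn dynamics are documented for the target setting, and i.i.d.
frames make the closed-form mean `Σ π(e)·V(e)` an exact oracle for the
expected reward. The simulator also does not model item-content
effects on emotion (deliberately unmodeled in the reward), classifier
confusion structure, lighting/pose dropouts, or habituation across the
session. Passing tests therefore demonstrate that the *engine* behaves
correctly under a plausible generative model — not that real users
behave like the simulator.

### Reward-level users

Bandit diagnostics are cleanest when each arm has a known success
probability, but a frame-emission user cannot realize an exact
per-style `P(ΔR ≥ 0)` (consecutive-turn deltas couple both arms). The
`bernoulli_user()` abstraction therefore generates the reward sequence
directly: given the played arm, a Bernoulli draw with that arm's
probability decides the delta's sign, and the magnitude is a random
fraction of the remaining headroom to the valence bounds, keeping
rewards strictly inside the valence range so the sign is exact with
probability one. Convergence and regret checks use this user; the
emission-based user drives everything trait-related.

## Analysis choices

* **Spearman correlation**: rho is computed on average ranks (ties
  averaged). For n ≤ 10 the two-sided p-value is exact, by enumerating
  all n! permutations of one margin — valid with or without ties, and
  chosen because the motivating cohort sizes sit exactly in this
  range, where the t approximation is unreliable. For n > 10 the
  standard `t = ρ·sqrt((n−2)/(1−ρ²))` approximation is used. Full
  enumeration at n = 10 touches 3.6M permutations (~a few seconds and
  a few hundred MB transiently); beyond that the approximation is both
  accurate and necessary.
* **Dominant style**: a session counts as converged to a style when
  its final α exceeds the other's by at least a margin, default 2
  counts. No principled criterion exists for "comparable α values",
  so the margin is an explicit, surfaced knob rather than a hidden
  constant.
* **Regret** is computed against simulator ground truth as
  `Σ (p_best − p_played)` — available only for synthetic users, which
  is precisely its role as a diagnostic.

## Numerical and serialization details

* Session logs serialize as JSONL (one turn record per line plus a
  footer with the final policy state) with 17 significant digits, so
  that recomputing rewards from the logged frames reproduces the
  logged values bit-exactly after a round-trip.
* Policy states round-trip through JSON including their RNG stream, so
  a restored policy continues the exact selection sequence.
* The ledger identity `Σ(α_i + β_i) − Σ priors = updated turns` is
  checked on every generated log in the test suite.

## Problem sizes used in the test suite

The suite exercises: selection symmetry over 10,000 draws; convergence
and regret over 100 replicates of 500-turn sessions against success
probabilities (0.9, 0.1); trait-correlation sign recovery over 100
replicate cohorts of 50 users × 200 turns; and null-user
exchangeability over 200 replicates. These sizes were chosen so that
Monte-Carlo standard errors sit comfortably inside the asserted bands
while the full suite runs in a couple of minutes on one CPU.

## Known limitations

* The valence map is a fixed lookup; dimensional (valence–arousal)
  or confidence-weighted signals are out of scope.
* The policy is context-free: no discounting, windowing, or covariate
  conditioning. A long session with drifting preferences would be
  tracked only through the accumulating counts.
* Simulator parameters are conventions, not estimates — no generative
  ground truth exists for the target population, so cohort-level
  results should be read as engine validation, not behavioral
  prediction.
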