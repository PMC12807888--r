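# Seeded-stream helpers. Policy and simulator objects carry an opaque
# rng_state (a saved .Random.seed) so that results are reproducible
# regardless of what the calling session does with the global RNG.

rng_init <- function(seed) {
  seed <- as.integer(seed)
  with_preserved_rng({
    set.seed(seed)
    get(".Random.seed", envir = globalenv())
  })
}

# run expr with the global RNG swapped out, restoring it afterwards
with_preserved_rng <- function(expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# evaluate fn() with the RNG set from `state`; return value + advanced state
rng_eval <- function(state, fn) {
  with_preserved_rng({
    assign(".Random.seed", state, envir = globalenv())
    value <- fn()
    list(value = value, rng = get(".Random.seed", envir = globalenv()))
  })
}

# deterministic sub-seed derivation: independent streams for the policy
# and the simulator are derived from one master seed, kept below 2^31
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + 104729 * as.double(k)) %% 2147483647)
}
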