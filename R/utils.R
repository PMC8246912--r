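# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# All generators and seeded analysis steps route through this so that they are
# pure functions of (arguments, seed) and never perturb the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed derivation from one global seed: sub-streams for the
# k-th stage of a pipeline stay below 2^31 and never collide for k < 1000.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1009L + as.integer(k)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
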