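# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  Every stochastic operation in the package
# takes an explicit seed and runs through this, so no global RNG state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derivation of per-stage seeds from a master seed.  Keeps all
# derived seeds strictly inside the 32-bit signed-integer range.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index))
  as.integer((abs(as.numeric(master)) + 104729 * as.numeric(index)) %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
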