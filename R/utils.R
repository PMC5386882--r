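# Internal helpers shared across modules.

# Seed handling: every user-facing stochastic function takes `seed = NULL`.
# NULL continues the caller's RNG stream; an integer gives a self-contained,
# reproducible draw (the previous RNG state is restored on exit).
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = envir)
  } else {
    withr::defer(rm(".Random.seed", envir = globalenv()), envir = envir)
  }
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Derive a bounded child seed from a root seed and a stream label,
# so independent sub-simulations are reproducible without sharing a stream.
child_seed <- function(seed, k) {
  (as.integer(seed) * 48271 + as.integer(k) * 1103) %% 2147483629L
}

assert_scalar_prob <- function(p, name = "p", max = 1) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > max) {
    abort(sprintf("`%s` must be a single number in [0, %s], got %s",
                  name, format(max), format(p)))
  }
  invisible(p)
}
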