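# Internal RNG plumbing.
#
# Every user-facing stochastic function takes an explicit `seed` and must
# (a) be bit-reproducible for a given seed and (b) leave the caller's
# .Random.seed untouched.  Individuals get their own substream derived by an
# integer hash of (seed, replication, individual id), so enlarging a cohort
# never perturbs the draws of earlier individuals.

# Save the caller's RNG state; restore it when the calling frame exits.
preserve_rng <- function(envir = parent.frame()) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    expr <- quote(if (exists(".Random.seed", envir = globalenv(),
                             inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

# Deterministic 31-bit hash of a sequence of non-negative integers.
# Arithmetic in doubles; every intermediate stays below 2^53 so it is exact.
hash_seed <- function(...) {
  parts <- c(...)
  h <- 2166136261
  for (v in parts) {
    h <- (h * 16777619) %% 2147483629
    h <- (h + as.numeric(v) %% 2147483629) %% 2147483629
  }
  as.integer(h)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed %% 1 != 0) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed %% 2147483647)
}
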