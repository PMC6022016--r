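# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed from a master seed; stays below 2^31 - 1 and
# exact in double arithmetic (products < 2^53).
derive_seed <- function(master, i) {
  ((master %% 1000003) * 69069 + i * 104729 + 12345) %% 2147483587
}

# x * log2(x) with the 0 log 0 = 0 convention; preserves dim/names.
plogp <- function(x) {
  out <- x
  out[] <- 0
  ok <- x > 0
  out[ok] <- x[ok] * log2(x[ok])
  out
}

# Exact Euclidean disc structuring element of the given pixel radius.
disc_kernel <- function(radius) {
  stopifnot(radius >= 1)
  k <- 2L * as.integer(radius) + 1L
  d <- seq_len(k) - (radius + 1)
  outer(d^2, d^2, `+`) <= radius^2
}

stop_stage <- function(stage, msg) {
  stop(sprintf("[stage: %s] %s", stage, msg), call. = FALSE)
}
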