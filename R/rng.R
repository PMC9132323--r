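# Deterministic per-row RNG streams.
#
# Every stimulus row owns a 31-bit seed derived from the dataset seed, the row
# index and a purpose salt, so any subset of a dataset re-renders identically
# and generation order never matters.

# Mix integers into a 31-bit seed with a few exact LCG rounds.  All
# intermediates stay below 2^53 so double arithmetic is exact.
mix_seed <- function(...) {
  xs <- c(...)
  h <- 104729
  for (x in xs) {
    h <- (h * 69069 + (as.numeric(x) %% 2147483647)) %% 2147483647
    h <- (h * 48271 + 11) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# sample() without the length-1 surprise
sample_int <- function(x, n = 1, replace = FALSE) x[sample.int(length(x), n, replace = replace)]
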