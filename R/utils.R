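# Seed plumbing: every stochastic stage draws from a sub-seed derived
# deterministically from its caller's seed, so stages can be re-run
# independently. Sub-seeds stay below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  seed <- as.numeric(seed) %% 2147483647
  as.integer((seed * 69069 + as.numeric(offset) * 104729 + 1) %% 2147483647)
}

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sample() without the length-1 surprise
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

random_subset <- function(x, min_size = 1L, max_size = length(x)) {
  n <- sample.int(max_size - min_size + 1L, 1L) + min_size - 1L
  sort(resample(x, n))
}
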