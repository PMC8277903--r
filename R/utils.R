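# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample n entries of x without the scalar-x surprise of sample()
safe_sample <- function(x, n) x[sample.int(length(x), n)]

# derive a stream-specific child seed from a base seed (kept < 2^31)
child_seed <- function(seed, stream) {
  (seed * 1103515245 + stream * 12345) %% 2147483647
}
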