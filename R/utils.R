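# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for reproducibility")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Spawn `n` reproducible child seeds from one master seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
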