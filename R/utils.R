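# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing randomness in the package funnels through this so that a
# single integer seed fully determines a run.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_positive_count <- function(x) is_count(x) && x > 0

# sample n integers uniformly from [lo, hi]; safe when lo == hi (plain
# sample() would treat a scalar as a range)
sample_range <- function(lo, hi, n) {
  vals <- seq.int(lo, hi)
  vals[sample.int(length(vals), n, replace = TRUE)]
}
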