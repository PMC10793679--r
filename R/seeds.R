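# Deterministic seed streams.
#
# The cohort generator derives one sub-seed per (master seed, purpose,
# subject/sample) key with a stable polynomial string hash, so adding a
# patient to a config never reshuffles the random draws of existing
# patients. The hash is plain modular arithmetic on doubles (all
# intermediates < 2^53), so it is identical across platforms.

stable_seed <- function(master, ...) {
  key <- paste(c(format(master), ...), collapse = "/")
  h <- 0
  m <- 2147483629  # largest prime < 2^31, keeps set.seed() in range
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
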