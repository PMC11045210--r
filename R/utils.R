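# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
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

# Derive a per-stage seed from one global seed with a fixed LCG step; the
# result always fits a 32-bit integer so one number reproduces every stage.
derive_seed <- function(seed, stage) {
  stages <- c(split = 1L, folds = 2L, fixture = 3L, simulate = 4L)
  idx <- stages[[stage]]
  as.integer((as.double(seed) %% 2147483647 * 48271 + 7919 * idx) %% 2147483629 + 1)
}

stop_with_class <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dosig_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
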