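# Internal helpers shared across modules.

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so package functions never clobber the session RNG.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-record seed below 2^31, derived from a global seed and
# record coordinates (subject index, posture index, session index).
derive_seed <- function(seed, subject, posture_idx, session) {
  base <- (as.numeric(seed) %% 1e6) * 1009 +
    subject * 10007 + posture_idx * 101 + session
  as.integer(base %% .Machine$integer.max)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
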