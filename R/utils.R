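# Internal helpers shared across modules.

# logit / inverse logit
logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Derive a stream-specific child seed from a master seed, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1013) %% 2147483647
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr, .rng_kind = "Mersenne-Twister")
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Semiannual visit clock: years spanned by a run of `k` consecutive visits.
visits_to_years <- function(k) (k - 1) / 2
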