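# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Every user-facing generator routes its randomness through this so
# that identical seeds give byte-identical output and nothing leaks into (or
# depends on) .GlobalEnv's .Random.seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific sub-seed from a master seed. Keeps results for
# different components statistically unlinked while staying below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + stream * 7919L
}

stop_field <- function(cond, field, msg) {
  if (cond) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

# Signed standard-normal quantile of a two-sided p-value, computed on the
# log scale so extreme statistics do not underflow to Inf.
signed_z_from_logp <- function(log_p_two_sided, sign) {
  z <- -qnorm(log_p_two_sided - log(2), log.p = TRUE)
  sign * z
}
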