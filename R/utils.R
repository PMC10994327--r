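# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-participant substream seed: adding participants to a
# cohort must not reshuffle the data of existing ones.
participant_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * as.numeric(index)) %%
               2147483647)
}

stop_usage <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_unit_interval <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_usage("`%s` must lie in [0, 1]", name)
  }
  invisible(x)
}

# SSE at or below this is treated as a perfect fit (residuals are exact
# zeros whenever a model's preferred candidates reproduce the observed ones).
PERFECT_FIT_TOL <- 1e-12
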