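# Internal helpers: seeded sub-streams, RNG hygiene, logging.

# Derive a per-stage RNG seed from the user-facing seed. Stays inside
# 32-bit integer range so set.seed() always accepts it.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) %% 100000L) * 7919 + stage * 104729) %% 2147483647L
}

# Evaluate code under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  })
  set.seed(seed)
  force(code)
}

log_info <- function(...) {
  if (isTRUE(getOption("emtscreen.verbose", TRUE))) {
    message("[emtscreen] ", ...)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
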