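# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a single non-negative integer-valued scalar.
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# Seed scoping: set the RNG to `seed`, returning the previous global state so
# callers can restore it on exit. Keeps exported functions deterministic
# without clobbering the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive independent sub-seeds from one user-facing seed (fixed offsets so
# each stage is independently reproducible).
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}
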