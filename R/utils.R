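# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All user-facing stochastic operations take an
# explicit seed and route through this, so a fixed seed gives bit-identical
# output regardless of the surrounding session state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Positive scalar check with a consistent error message.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Fixed-format number rendering for deterministic CSV output: up to 6
# significant digits, integers written without a decimal point.
format_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  whole <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[whole] <- formatC(x[whole], format = "d")
  trimws(out)
}

# Unscaled median absolute deviation: median(|x - median(x)|).
mad_raw <- function(x) median(abs(x - median(x)))
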