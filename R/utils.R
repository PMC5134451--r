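# shared internal helpers

# Run `code` under a temporary RNG state seeded with `seed` (restores the
# caller's RNG). All stochastic steps in the package go through this, so a
# single user-facing seed makes every artifact reproducible.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic derived seeds for independent stages (restarts, splits, ...),
# kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# last-observation-carried-forward with a fixed fill for leading NAs
locf <- function(x, first = 0) {
  if (length(x) == 0L) return(x)
  if (is.na(x[1L])) x[1L] <- first
  filled <- !is.na(x)
  x[cummax(ifelse(filled, seq_along(x), 0L))]
}
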