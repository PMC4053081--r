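# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# When `seed` is NULL the current RNG stream is used as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Canonical gene-symbol normalization: trimmed, uppercased character.
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  invisible(x)
}
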