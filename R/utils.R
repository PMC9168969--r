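# Internal helpers: deterministic substream seeding and input checks.

# Derive a reproducible substream seed from a master seed and a label.
# Keeps every derived seed a valid 32-bit integer so the same master seed
# always yields the same, mutually distinct, substreams.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
# A NULL seed leaves the ambient RNG stream in charge.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

check_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  bad <- if (strict) x <= lower else x < lower
  if (bad) {
    stop(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  }
  invisible(x)
}
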