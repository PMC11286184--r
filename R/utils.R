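# Internal validation and RNG helpers.

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE, strict_lower = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower) {
    if (x <= lower) abort(sprintf("`%s` must be > %g.", name, lower))
  } else if (x < lower) {
    abort(sprintf("`%s` must be >= %g.", name, lower))
  }
  if (x > upper) abort(sprintf("`%s` must be <= %g.", name, upper))
  invisible(x)
}

# Evaluate `expr` under a fixed seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise evaluate as-is.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic child seeds for collection generators, kept below 2^31.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n)))
}

running_mean <- function(x, k) {
  # centred moving average with shrinking window at the edges
  n <- length(x)
  if (n == 0L || k <= 1L) return(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}
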