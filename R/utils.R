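# Internal helpers shared across modules.

# log10-spaced grid, inclusive of both endpoints
logspace <- function(from, to, n) 10^seq(log10(from), log10(to), length.out = n)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so design/simulation helpers never disturb
# the global stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a master seed and integer indices,
# kept strictly below .Machine$integer.max.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (i in seq_along(idx)) {
    s <- (s * 69069 + 104729 * idx[i] + 1013904223) %% 2147483647
  }
  as.integer(s)
}

stop_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

stop_not_positive <- function(x, name) {
  stop_not_scalar(x, name)
  if (x <= 0) abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  invisible(x)
}
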