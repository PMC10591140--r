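# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` means: use the current RNG
# stream as-is (caller is responsible for reproducibility).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed; keeps results < 2^31 and distinct
# across `k`.
derive_seed <- function(seed, k) {
  m <- 2147483587
  as.integer((as.numeric(seed) %% m * 7919 + as.numeric(k) %% m * 104729) %% m)
}

# Extract time slab t from a (B, n, T) array as a B x n matrix.
slab <- function(A, t) {
  d <- dim(A)
  matrix(A[, , t], nrow = d[1], ncol = d[2])
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
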