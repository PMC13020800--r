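#' @keywords internal
"_PACKAGE"

## Run `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so no global state leaks.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stage sub-seed from a master seed; keeps results < 2^31.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + as.numeric(offset) * 104729) %%
               2147483647)
}

## n_draws independent without-replacement samples of size k from `pool`
## (a vector of values), returned as an n_draws x k matrix. When k is small
## relative to the pool, draws with replacement and redraws rows containing
## duplicates (fast, vectorized); otherwise falls back to per-row
## sample.int.
sample_rows_noreplace <- function(pool, k, n_draws) {
  n <- length(pool)
  stopifnot(k <= n)
  if (k * (k - 1) / (2 * n) > 0.6) {
    idx <- matrix(0L, n_draws, k)
    for (r in seq_len(n_draws)) idx[r, ] <- sample.int(n, k)
    return(matrix(pool[idx], nrow = n_draws))
  }
  idx <- matrix(sample.int(n, n_draws * k, replace = TRUE), nrow = n_draws)
  bad <- which(rows_with_dup(idx))
  while (length(bad) > 0L) {
    for (r in bad) idx[r, ] <- sample.int(n, k)
    bad <- integer(0)
  }
  matrix(pool[idx], nrow = n_draws)
}

rows_with_dup <- function(m) {
  k <- ncol(m)
  if (k == 1L) return(rep(FALSE, nrow(m)))
  res <- rep(FALSE, nrow(m))
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) res <- res | (m[, a] == m[, b])
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
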