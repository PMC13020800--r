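## Independent brute-force oracles used across the suite. These deliberately
## re-derive each statistic from its definition with plain loops, staying
## independent of the package's vectorized implementations.

## Side-adjacency neighbor list of an n_rows x n_cols lattice patch
## (vertex order column-major, as make_patch produces).
lattice_side_neighbors <- function(n_rows, n_cols) {
  idx <- function(r, c) (c - 1L) * n_rows + r
  lapply(seq_len(n_rows * n_cols), function(i) {
    r <- (i - 1L) %% n_rows + 1L
    c <- (i - 1L) %/% n_rows + 1L
    c(if (r > 1) idx(r - 1, c), if (r < n_rows) idx(r + 1, c),
      if (c > 1) idx(r, c - 1), if (c < n_cols) idx(r, c + 1))
  })
}

## Dense row-standardized weight matrix from a spatial_weights object.
weights_dense <- function(w) {
  W <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) {
    nb <- if (is.matrix(w$neighbors)) w$neighbors[i, ] else w$neighbors[[i]]
    W[i, nb] <- 1 / length(nb)
  }
  W
}

## Local Moran's I by definition: I_i = z_i / (sum z^2 / n) * sum_j W_ij z_j.
local_moran_brute <- function(z, W) {
  n <- length(z)
  m2 <- sum(z^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    lag <- 0
    for (j in seq_len(n)) lag <- lag + W[i, j] * z[j]
    out[i] <- z[i] / m2 * lag
  }
  out
}

## Textbook global Moran's I: (n / S0) * sum_ij W_ij z_i z_j / sum z_i^2.
global_moran_brute <- function(z, W) {
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

## Matheron semivariance per distance bin by double loop.
variogram_brute <- function(z, D, bin_width) {
  n <- length(z)
  acc <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      b <- as.character(floor(D[i, j] / bin_width))
      acc[[b]] <- c(acc[[b]], (z[i] - z[j])^2)
    }
  }
  bins <- sort(as.integer(names(acc)))
  data.frame(bin_center_mm = (bins + 0.5) * bin_width,
             gamma = vapply(as.character(bins),
                            function(b) sum(acc[[b]]) / (2 * length(acc[[b]])), 0),
             pair_count = vapply(as.character(bins),
                                 function(b) length(acc[[b]]), 0L),
             row.names = NULL)
}

## Kendall tau-b by explicit pair counting with tie correction.
kendall_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

## Complete-linkage agglomeration by exhaustive search, returning the
## cophenetic (ultrametric) matrix. Ties broken toward the smallest pair of
## current cluster labels (lexicographic on sorted member indices).
complete_linkage_brute <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(D[clusters[[a]], clusters[[b]]])
        key <- c(min(clusters[[a]]), min(clusters[[b]]))
        if (is.null(best) || h < best$h - 1e-12 ||
            (abs(h - best$h) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(a = a, b = b, h = h, key = key)
        }
      }
    }
    coph[clusters[[best$a]], clusters[[best$b]]] <- best$h
    coph[clusters[[best$b]], clusters[[best$a]]] <- best$h
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  coph
}

## Tiny OLS by normal equations, for gradient-regression cross-checks.
ols_brute <- function(y, x) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
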