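#' Fit a psychometric function and extract the PSE
#'
#' Binomial regression (logit link) of the "comparison longer than
#' reference" response on comparison duration, fitted by iteratively
#' reweighted least squares. The point of subjective equality (PSE) — the
#' comparison duration judged longer exactly half the time — is
#' `-intercept / slope`.
#'
#' @param behavior a `behavior_table` (columns `duration_s`,
#'   `response_longer`) for one subject.
#' @return a `psychometric_fit` list: `intercept`, `slope` (1/s), `pse`
#'   (s; `NA` with a warning if the fitted slope is not positive),
#'   `converged`.
#' @examples
#' b <- simulate_behavior(0.55, 20, 200, seed = 2)
#' fit_psychometric(b)$pse
#' @export
fit_psychometric <- function(behavior) {
  d <- behavior$duration_s
  r <- behavior$response_longer
  stopifnot(all(r %in% c(0, 1)))
  if (length(unique(d)) < 2) stop("need responses at >= 2 distinct durations")
  if (length(unique(r)) < 2) {
    return(list(intercept = NA_real_, slope = NA_real_, pse = NA_real_,
                converged = FALSE))
  }
  fit <- suppressWarnings(
    stats::glm(r ~ d, family = stats::binomial(link = "logit")))
  co <- stats::coef(fit)
  ## a fitted logit span far beyond what data can support flags separation
  separated <- abs(co[2]) * diff(range(d)) > 50
  converged <- isTRUE(fit$converged) && !separated
  slope <- unname(co[2]); intercept <- unname(co[1])
  pse <- if (is.finite(slope) && slope > 0) -intercept / slope else {
    warning("non-positive psychometric slope; PSE undefined")
    NA_real_
  }
  list(intercept = intercept, slope = slope, pse = pse,
       converged = converged)
}

#' Kendall rank correlation (tau-b) with significance
#'
#' Tie-corrected Kendall correlation between two paired vectors. The
#' p-value is computed by exact permutation (all `n!` orderings) for
#' `n <= 9`, and by the tie-corrected normal approximation otherwise; both
#' are two-sided.
#'
#' @param x,y paired numeric vectors, `n >= 3`, finite.
#' @return list with `tau`, `p`, `n`, `method`.
#' @export
kendall_tau <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired finite values")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("Kendall tau undefined: one input is constant")
  }
  tau <- stats::cor(x, y, method = "kendall")
  if (n <= 9) {
    perms <- permutations_all(n)
    taus <- apply(perms, 1L, function(p) stats::cor(x, y[p],
                                                    method = "kendall"))
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- kendall_normal_p(x, y)
    method <- "normal approximation"
  }
  list(tau = tau, p = p, n = n, method = method)
}

## All permutations of 1..n as an n! x n matrix (n <= 9).
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

## Two-sided p from the tie-corrected normal approximation for S = C - D.
kendall_normal_p <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  s <- sum(sx[upper.tri(sx)] * sy[upper.tri(sy)])
  tx <- table(x); ty <- table(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  2 * stats::pnorm(-abs(s) / sqrt(v))
}

#' Variance-stabilizing transform of Kendall's tau
#'
#' `z(tau) = atanh(sin(pi * tau / 2))`: an odd, strictly increasing map of
#' (-1, 1) onto the real line used before regressing correlations on the
#' cortical hierarchy.
#'
#' @param tau Kendall correlation(s) with `|tau| < 1`.
#' @param clamp if `TRUE`, `|tau| >= 1` is clamped to `1 - 1e-6` in
#'   magnitude instead of raising an error.
#' @return transformed value(s).
#' @examples
#' z_transform_tau(0.5)  # atanh(sin(pi/4))
#' @export
z_transform_tau <- function(tau, clamp = FALSE) {
  if (any(abs(tau) >= 1, na.rm = TRUE)) {
    if (!clamp) stop("|tau| >= 1 maps to +/-Inf; set clamp = TRUE to proceed")
    tau <- sign(tau) * pmin(abs(tau), 1 - 1e-6)
  }
  atanh(sin(pi * tau / 2))
}

#' Link duration preferences to perceptual bias
#'
#' For each region, the Kendall correlation across subjects between the
#' region's median preferred duration and the subject's PSE, the
#' z-transformed correlation, and the linear gradient of z along the
#' occipital-to-frontal hierarchy. P-values are uncorrected.
#'
#' @param pse named numeric vector of per-subject PSEs.
#' @param median_mu numeric matrix, subjects x regions (dimnames required),
#'   of per-subject median preferred durations.
#' @param ordering character vector of region names in hierarchy order
#'   (default: column order).
#' @param clamp passed to [z_transform_tau()].
#' @return list with `table` (data.frame: region, hierarchy_rank, tau, p,
#'   z_tau, n_subjects) and `gradient` (see [hierarchy_regression()]).
#' @export
pse_preference_link <- function(pse, median_mu, ordering = colnames(median_mu),
                                clamp = FALSE) {
  stopifnot(is.matrix(median_mu), !is.null(colnames(median_mu)))
  subj <- if (!is.null(names(pse)) && !is.null(rownames(median_mu))) {
    intersect(names(pse), rownames(median_mu))
  } else {
    stopifnot(length(pse) == nrow(median_mu))
    seq_len(nrow(median_mu))
  }
  if (length(subj) < 3) stop("need >= 3 subjects with both PSE and medians")
  rows <- lapply(seq_along(ordering), function(ri) {
    r <- ordering[ri]
    kt <- kendall_tau(median_mu[subj, r], if (is.numeric(subj)) pse else
      pse[subj])
    data.frame(region = r, hierarchy_rank = ri, tau = kt$tau, p = kt$p,
               z_tau = z_transform_tau(kt$tau, clamp = clamp),
               n_subjects = kt$n, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       gradient = hierarchy_regression(tab$z_tau, tab$hierarchy_rank))
}
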