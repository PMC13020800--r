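#' Gaussian duration tuning function
#'
#' The position-invariant duration pRF: a Gaussian over stimulus duration
#' with preferred duration `mu_d` (the duration eliciting the greatest
#' response) and tuning width `sigma_d` (the sensitivity of the response to
#' changes in duration). Peaks at exactly 1 when `d == mu_d`.
#'
#' @param d stimulus duration(s), seconds.
#' @param mu_d preferred duration, seconds.
#' @param sigma_d tuning width, seconds (> 0).
#' @return unitless response in (0, 1].
#' @examples
#' gaussian_response(0.4, 0.5, 0.1)  # one sigma away: exp(-0.5)
#' @export
gaussian_response <- function(d, mu_d, sigma_d) {
  if (any(sigma_d <= 0)) stop("sigma_d must be positive")
  exp(-(d - mu_d)^2 / (2 * sigma_d^2))
}

#' Closed-form condition predictions
#'
#' Predicted amplitude for each of the 24 duration x position conditions:
#' `baseline + gain * gaussian_response(d_k, mu_d, sigma_d)`. The model is
#' position invariant, so the four positions sharing a duration receive
#' identical predictions.
#'
#' @inheritParams predict_via_tensor
#' @return numeric vector, one prediction per condition (psc).
#' @export
predict_conditions <- function(params, stim = stimulus_spec()) {
  params[["baseline"]] +
    params[["gain"]] * gaussian_response(stim$conditions$duration_s,
                                         params[["mu_d"]], params[["sigma_d"]])
}

#' Default (mu, sigma) search grid
#'
#' Preferred duration from 0.1 to 0.9 s in 0.01 s steps; tuning width over
#' 0.02 to 0.5 s in 30 log-spaced steps. Nodes are ordered by ascending
#' sigma then mu so residual ties resolve deterministically toward sharper,
#' shorter-preferring candidates.
#'
#' @return data.frame with columns `mu` and `sigma`, one row per node.
#' @export
default_prf_grid <- function() {
  mu <- seq(0.1, 0.9, by = 0.01)
  sigma <- exp(seq(log(0.02), log(0.5), length.out = 30))
  g <- expand.grid(mu = mu, sigma = sigma, KEEP.OUT.ATTRS = FALSE)
  g[order(g$sigma, g$mu), , drop = FALSE]
}

## Node x condition matrix of unit-amplitude Gaussian predictions.
grid_prediction_matrix <- function(grid, stim) {
  d <- stim$conditions$duration_s
  exp(-outer(grid$mu, d, "-")^2 / (2 * grid$sigma^2))
}

## Closed-form least squares of betas on a unit-amplitude prediction g:
## gain and baseline minimizing sum((b - baseline - gain * g)^2).
solve_gain_baseline <- function(g, b) {
  n <- length(b)
  sxx <- sum(g^2) - sum(g)^2 / n
  if (sxx < 1e-14) return(c(gain = 0, baseline = mean(b)))
  gain <- (sum(g * b) - sum(g) * sum(b) / n) / sxx
  c(gain = gain, baseline = mean(b) - gain * mean(g))
}

new_tuning_fit <- function(mu_d = NA_real_, sigma_d = NA_real_,
                           gain = NA_real_, baseline = NA_real_,
                           r2_grid = NA_real_, r2_final = NA_real_,
                           valid = FALSE, exclusion_reason = "none") {
  list(mu_d = mu_d, sigma_d = sigma_d, gain = gain, baseline = baseline,
       r2_grid = r2_grid, r2_final = r2_final, valid = valid,
       exclusion_reason = exclusion_reason)
}

#' Grid-search stage of the pRF fit
#'
#' Evaluates every (mu, sigma) node of the grid, solving the per-vertex
#' response gain and baseline in closed form by least squares at each node,
#' and returns the node with the smallest residual sum of squares. Ties are
#' broken toward smaller sigma, then smaller mu.
#'
#' @param betas24 numeric vector of condition amplitudes (psc), one per
#'   condition of `stim`.
#' @param stim a `stimulus_spec`.
#' @param grid data.frame of candidate `mu`, `sigma` (see
#'   [default_prf_grid()]).
#' @return a tuning-fit list: `mu_d`, `sigma_d`, `gain`, `baseline`,
#'   `r2_grid`, `r2_final` (equal to `r2_grid` at this stage), `valid`,
#'   `exclusion_reason`. Zero-variance input yields `exclusion_reason =
#'   "fit_failure"`.
#' @export
grid_fit <- function(betas24, stim = stimulus_spec(), grid = default_prf_grid()) {
  stopifnot(length(betas24) == nrow(stim$conditions), nrow(grid) >= 1)
  if (any(!is.finite(betas24))) {
    return(new_tuning_fit(exclusion_reason = "fit_failure"))
  }
  res <- as.list(grid_fit_matrix(matrix(betas24, ncol = 1), stim, grid)[1, ])
  if (is.na(res$mu_d)) return(new_tuning_fit(exclusion_reason = "fit_failure"))
  new_tuning_fit(mu_d = res$mu_d, sigma_d = res$sigma_d, gain = res$gain,
                 baseline = res$baseline, r2_grid = res$r2_grid,
                 r2_final = res$r2_final, valid = FALSE)
}

## Vectorized grid search over many vertices. B: n_cond x n_vert matrix.
## Returns data.frame with one row per vertex (NA row = zero-variance input).
grid_fit_matrix <- function(B, stim, grid) {
  n <- nrow(B)
  G <- grid_prediction_matrix(grid, stim)      # nodes x cond
  gsum <- rowSums(G)
  sxx <- rowSums(G^2) - gsum^2 / n             # nodes
  bsum <- colSums(B)
  syy <- colSums(B^2) - bsum^2 / n             # vertices
  sxy <- G %*% B - outer(gsum, bsum) / n       # nodes x vertices
  ok_node <- sxx > 1e-14
  gain_all <- sxy / sxx
  gain_all[!ok_node, ] <- 0
  rss <- matrix(syy, nrow(grid), ncol(B), byrow = TRUE)
  rss[ok_node, ] <- rss[ok_node, , drop = FALSE] -
    sxy[ok_node, , drop = FALSE]^2 / sxx[ok_node]
  best <- apply(rss, 2L, which.min)            # grid pre-sorted: ties -> small sigma, mu
  out <- data.frame(
    mu_d = grid$mu[best], sigma_d = grid$sigma[best],
    gain = gain_all[cbind(best, seq_len(ncol(B)))],
    baseline = NA_real_, r2_grid = NA_real_, r2_final = NA_real_
  )
  out$baseline <- bsum / n - out$gain * gsum[best] / n
  out$r2_grid <- 1 - rss[cbind(best, seq_len(ncol(B)))] / syy
  out$r2_final <- out$r2_grid
  degenerate <- syy <= 1e-14
  out[degenerate, ] <- NA_real_
  out
}

#' Iterative (bounded simplex) refinement of a grid fit
#'
#' Refines the grid-stage (mu, sigma) by Nelder-Mead simplex minimization of
#' the residual sum of squares, with gain and baseline re-solved in closed
#' form at every evaluation. The box constraint is realized by a logistic
#' coordinate transform, so the simplex explores an unbounded space whose
#' image is the interior of the bounds. Seeds explaining less than
#' `r2_threshold` of variance in the grid stage are returned unrefined and
#' marked excluded (`low_r2`); refined fits with non-positive gain are
#' marked `negative_prf`.
#'
#' @param betas24 condition amplitudes (psc).
#' @param seed_fit tuning-fit list from [grid_fit()].
#' @param stim a `stimulus_spec`.
#' @param bounds list with `mu` and `sigma` ranges for the simplex stage.
#' @param r2_threshold minimum grid-stage variance explained (default 0.10).
#' @param control passed to [stats::optim()] (Nelder-Mead); defaults: relative
#'   tolerance 1e-8, at most 2000 evaluations.
#' @return a tuning-fit list (see [grid_fit()]); `r2_final >= r2_grid` always.
#' @export
iterative_fit <- function(betas24, seed_fit, stim = stimulus_spec(),
                          bounds = list(mu = c(0.05, 1.0), sigma = c(0.01, 1.0)),
                          r2_threshold = 0.10,
                          control = list(reltol = 1e-8, maxit = 2000)) {
  if (identical(seed_fit$exclusion_reason, "fit_failure") ||
      is.na(seed_fit$r2_grid)) {
    return(new_tuning_fit(exclusion_reason = "fit_failure"))
  }
  if (seed_fit$r2_grid < r2_threshold) {
    out <- seed_fit
    out$valid <- FALSE
    out$exclusion_reason <- "low_r2"
    return(out)
  }
  d <- stim$conditions$duration_s
  n <- length(betas24)
  tss <- sum((betas24 - mean(betas24))^2)

  to_box <- function(theta, lim) lim[1] + diff(lim) / (1 + exp(-theta))
  from_box <- function(x, lim) {
    p <- (x - lim[1]) / diff(lim)
    p <- min(max(p, 1e-9), 1 - 1e-9)
    log(p / (1 - p))
  }
  rss_of <- function(theta) {
    mu <- to_box(theta[1], bounds$mu)
    sigma <- to_box(theta[2], bounds$sigma)
    g <- exp(-(d - mu)^2 / (2 * sigma^2))
    gb <- solve_gain_baseline(g, betas24)
    sum((betas24 - gb["baseline"] - gb["gain"] * g)^2)
  }

  theta0 <- c(from_box(seed_fit$mu_d, bounds$mu),
              from_box(seed_fit$sigma_d, bounds$sigma))
  opt <- tryCatch(
    stats::optim(theta0, rss_of, method = "Nelder-Mead", control = control),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    return(new_tuning_fit(r2_grid = seed_fit$r2_grid,
                          exclusion_reason = "fit_failure"))
  }
  mu <- to_box(opt$par[1], bounds$mu)
  sigma <- to_box(opt$par[2], bounds$sigma)
  g <- exp(-(d - mu)^2 / (2 * sigma^2))
  gb <- solve_gain_baseline(g, betas24)
  rss <- sum((betas24 - gb["baseline"] - gb["gain"] * g)^2)
  r2 <- 1 - rss / tss

  if (r2 < seed_fit$r2_grid) {  # simplex never accepted beats the seed: keep it
    mu <- seed_fit$mu_d; sigma <- seed_fit$sigma_d
    gb <- c(gain = seed_fit$gain, baseline = seed_fit$baseline)
    r2 <- seed_fit$r2_grid
  }
  fit <- new_tuning_fit(mu_d = mu, sigma_d = sigma,
                        gain = unname(gb["gain"]),
                        baseline = unname(gb["baseline"]),
                        r2_grid = seed_fit$r2_grid, r2_final = r2,
                        valid = TRUE)
  if (fit$gain <= 0) {
    fit$valid <- FALSE
    fit$exclusion_reason <- "negative_prf"
  }
  fit
}

#' Fit the duration pRF model to every vertex of a beta table
#'
#' Runs the two-stage fit (grid search, then bounded simplex refinement) on
#' each vertex of a beta table and assembles a tuning field over the patch.
#' Vertices failing the 10%-variance grid retention rule, showing a negative
#' pRF (non-positive fitted gain), or with degenerate input are marked
#' invalid with the corresponding exclusion reason; downstream statistics
#' consume only valid vertices.
#'
#' @param betas a `beta_table` (see [simulate_betas()]) or numeric matrix
#'   with one row per vertex and one column per condition.
#' @param patch the `surface_patch` the rows align with.
#' @param stim a `stimulus_spec`.
#' @param grid,bounds,r2_threshold,control see [grid_fit()] and
#'   [iterative_fit()].
#' @return a `tuning_field`: data.frame with columns `vertex_id`, `mu_d`,
#'   `sigma_d`, `gain`, `baseline`, `r2_grid`, `r2_final`, `valid`,
#'   `exclusion_reason`; the patch is attached as attribute `patch` and
#'   exclusion counts as attribute `exclusions`.
#' @examples
#' p <- make_patch(3, 3, 2)
#' tr <- plant_field(p, "constant", list(mu = 0.5), seed = 1)
#' b <- simulate_betas(tr, noise_sd = 0, seed = 1)
#' f <- fit_field(b, p)
#' all(abs(f$mu_d - 0.5) < 1e-4)
#' @export
fit_field <- function(betas, patch, stim = stimulus_spec(),
                      grid = default_prf_grid(),
                      bounds = list(mu = c(0.05, 1.0), sigma = c(0.01, 1.0)),
                      r2_threshold = 0.10,
                      control = list(reltol = 1e-8, maxit = 2000)) {
  B <- if (is.matrix(betas)) betas else as.matrix(betas[, grep("^d\\d+_p\\d+$",
                                                               names(betas))])
  if (nrow(B) != nrow(patch)) stop("beta rows do not align with patch vertices")
  seeds <- grid_fit_matrix(t(B), stim, grid)
  fits <- vector("list", nrow(B))
  for (i in seq_len(nrow(B))) {
    s <- as.list(seeds[i, ])
    if (is.na(s$mu_d)) {
      fits[[i]] <- new_tuning_fit(exclusion_reason = "fit_failure")
      next
    }
    s$valid <- FALSE
    s$exclusion_reason <- "none"
    fits[[i]] <- iterative_fit(B[i, ], s, stim, bounds, r2_threshold, control)
  }
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(mu_d = f$mu_d, sigma_d = f$sigma_d, gain = f$gain,
               baseline = f$baseline, r2_grid = f$r2_grid,
               r2_final = f$r2_final, valid = f$valid,
               exclusion_reason = f$exclusion_reason,
               stringsAsFactors = FALSE)
  }))
  out <- cbind(vertex_id = patch$vertex_id, out)
  rownames(out) <- NULL
  structure(out, patch = patch,
            exclusions = table(out$exclusion_reason),
            class = c("tuning_field", "data.frame"))
}

#' @export
print.tuning_field <- function(x, ...) {
  cat(sprintf("tuning_field: %d vertices, %d valid (%.1f%%)\n",
              nrow(x), sum(x$valid), 100 * mean(x$valid)))
  exc <- attr(x, "exclusions")
  if (!is.null(exc)) print(exc)
  invisible(x)
}
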