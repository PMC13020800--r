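#' Plant a ground-truth duration-preference field on a patch
#'
#' Generates per-vertex "true" tuning parameters for forward simulation:
#' the preferred duration `mu_true` (s), tuning width `sigma_true` (s),
#' response `gain_true` and `baseline_true` (percent signal change). The
#' `kind` argument selects the spatial regime of `mu_true`:
#'
#' * `"gradient"` — linear ramp of preferred duration along one lattice axis,
#'   emulating a smooth chronotopic progression spanning the presented range;
#' * `"grf"` — Gaussian random field: Gaussian-kernel-smoothed white noise
#'   (correlation length `correlation_length_mm`) rescaled to unit variance
#'   and mixed with fresh white noise in proportion `nugget_fraction`;
#' * `"white"` — i.i.d. uniform preferences over `mu_range` (no topography);
#' * `"boundary"` — preferences tightly and independently distributed around
#'   the category boundary (`center`, `spread`), emulating regions tuned to
#'   the mean duration;
#' * `"constant"` — a single preferred duration everywhere.
#'
#' `mu_true` is clipped into `mu_range` after generation; the clipped
#' fraction is recorded in attribute `clip_fraction`.
#'
#' @param patch a `surface_patch`.
#' @param kind one of `"gradient"`, `"grf"`, `"white"`, `"boundary"`,
#'   `"constant"`.
#' @param params named list of kind-specific parameters; common entries are
#'   `mu_range` (default `c(0.2, 0.8)` s), `sigma_range` (default
#'   `c(0.05, 0.3)` s, i.i.d. uniform), `gain` (default 1 psc) and `baseline`
#'   (default 0 psc). Kind-specific: `axis` ("col"/"row") for gradient;
#'   `correlation_length_mm` and `nugget_fraction` plus `mu_center`, `mu_sd`
#'   for grf; `center`, `spread` for boundary; `mu` for constant.
#' @param seed integer; all randomness derives from it.
#' @return a `ground_truth_field`: data.frame with columns `vertex_id`,
#'   `mu_true`, `sigma_true`, `gain_true`, `baseline_true`.
#' @examples
#' p <- make_patch(10, 10, 2)
#' f <- plant_field(p, "gradient", seed = 1)
#' range(f$mu_true)
#' @export
plant_field <- function(patch, kind, params = list(), seed = 1L) {
  kind <- match.arg(kind, c("gradient", "grf", "white", "boundary", "constant"))
  n <- nrow(patch)
  mu_range <- params$mu_range %||% c(0.2, 0.8)
  sigma_range <- params$sigma_range %||% c(0.05, 0.3)
  gain <- params$gain %||% 1
  baseline <- params$baseline %||% 0

  mu_raw <- with_seed(seed, {
    mu <- switch(kind,
      constant = rep(params$mu %||% 0.5, n),
      white = stats::runif(n, mu_range[1], mu_range[2]),
      boundary = stats::rnorm(n,
                              mean = params$center %||% 0.5,
                              sd = params$spread %||% 0.02),
      gradient = {
        axis <- params$axis %||% "col"
        pos <- if (axis == "col") patch$x_mm else patch$y_mm
        t <- if (diff(range(pos)) == 0) rep(0.5, n) else
          (pos - min(pos)) / diff(range(pos))
        mu_range[1] + t * diff(mu_range)
      },
      grf = {
        cl <- params$correlation_length_mm
        if (is.null(cl) || cl <= 0) {
          stop("grf fields need params$correlation_length_mm > 0")
        }
        nugget <- params$nugget_fraction %||% 0
        if (nugget < 0 || nugget > 1) stop("nugget_fraction must be in [0, 1]")
        z <- grf_lattice(attr(patch, "n_rows"), attr(patch, "n_cols"),
                         attr(patch, "spacing_mm"), cl, nugget)
        ## lattice stored column-major matching make_patch vertex order
        (params$mu_center %||% 0.5) + (params$mu_sd %||% 0.12) * as.vector(z)
      })
    ## sigma/gain drawn after mu so mu fields are comparable across kinds
    sigma <- stats::runif(n, sigma_range[1], sigma_range[2])
    list(mu = mu, sigma = sigma)
  })

  clipped <- mu_raw$mu < mu_range[1] | mu_raw$mu > mu_range[2]
  mu <- pmin(pmax(mu_raw$mu, mu_range[1]), mu_range[2])

  out <- data.frame(
    vertex_id = patch$vertex_id,
    mu_true = mu,
    sigma_true = mu_raw$sigma,
    gain_true = rep_len(gain, n),
    baseline_true = rep_len(baseline, n)
  )
  support <- params$support %||% c(min(0.2, mu_range[1]), max(0.8, mu_range[2]))
  structure(out, kind = kind, seed = seed,
            clip_fraction = mean(clipped), mu_range = mu_range,
            support = support,
            class = c("ground_truth_field", "data.frame"))
}

## Unit-variance Gaussian random field on an n_rows x n_cols lattice.
## Smoothing by exact dense separable convolution with a row-normalized
## (edge-corrected) Gaussian kernel; nugget mixes in fresh white noise.
grf_lattice <- function(n_rows, n_cols, spacing_mm, correlation_length_mm,
                        nugget_fraction) {
  sd_px <- correlation_length_mm / spacing_mm
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  kr <- gauss_kernel_matrix(n_rows, sd_px)
  kc <- gauss_kernel_matrix(n_cols, sd_px)
  sm <- kr %*% w %*% t(kc)
  sm <- (sm - mean(sm)) / stats::sd(as.vector(sm))
  if (nugget_fraction > 0) {
    fresh <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    sm <- sqrt(1 - nugget_fraction) * sm + sqrt(nugget_fraction) * fresh
    sm <- (sm - mean(sm)) / stats::sd(as.vector(sm))
  }
  sm
}

gauss_kernel_matrix <- function(n, sd_px) {
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sd_px^2))
  k / rowSums(k)
}
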