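#' Duration preference category scheme
#'
#' The five duration-preference categories over the presented range:
#' short (0.2-0.32 s), mid-short (0.32-0.44 s), medium (0.44-0.56 s),
#' mid-long (0.56-0.68 s), long (0.68-0.8 s).
#'
#' @param edges six strictly increasing bin edges, seconds.
#' @param labels five category labels.
#' @return a `category_scheme` list with `edges` and `labels`.
#' @export
category_scheme <- function(edges = c(0.2, 0.32, 0.44, 0.56, 0.68, 0.8),
                            labels = c("short", "mid-short", "medium",
                                       "mid-long", "long")) {
  stopifnot(length(edges) == length(labels) + 1, all(diff(edges) > 0))
  structure(list(edges = edges, labels = labels), class = "category_scheme")
}

#' Categorize duration preferences
#'
#' Assigns each preferred duration to its category. Intervals are
#' left-closed, right-open, except the final interval which is closed, so
#' the top edge (0.8 s) is `long`. Out-of-range values are flagged
#' `NA` rather than silently binned.
#'
#' @param mu_d preferred durations, seconds.
#' @param scheme a [category_scheme()].
#' @return factor with the scheme's labels; `NA` for out-of-range input.
#' @examples
#' categorize(c(0.50, 0.30, 0.80))
#' @export
categorize <- function(mu_d, scheme = category_scheme()) {
  out <- cut(mu_d, breaks = scheme$edges, labels = scheme$labels,
             right = FALSE, include.lowest = TRUE)
  ## cut(right = FALSE, include.lowest = TRUE) closes the LAST interval's
  ## right edge, which is exactly the convention wanted
  out[mu_d < scheme$edges[1] | mu_d > scheme$edges[length(scheme$edges)]] <- NA
  out
}

#' Per-ROI summary of a tuning field
#'
#' For each ROI: the median preferred duration over valid vertices, the
#' five category fractions, and (when a quadrant summary is supplied) the
#' LL - HH fraction difference. An explicit hierarchy ordering assigns each
#' ROI its occipital-to-frontal rank.
#'
#' @param field a `tuning_field` from [fit_field()].
#' @param scheme a [category_scheme()].
#' @param quadrants optional data.frame from [summarize_quadrants()].
#' @param ordering optional character vector of ROI names in
#'   occipital-to-frontal order; ranks are assigned by position.
#' @return data.frame, one row per ROI: `roi`, `stream`, `hierarchy_rank`,
#'   `n_valid`, `median_mu`, `frac_<category>` columns, `unassigned`, and
#'   `ll_minus_hh` if quadrants were supplied. Empty ROIs produce a warning
#'   and an NA row.
#' @export
summarize_roi <- function(field, scheme = category_scheme(),
                          quadrants = NULL, ordering = NULL) {
  patch <- attr(field, "patch")
  stopifnot(!is.null(patch), nrow(field) == nrow(patch))
  rois <- if (is.null(ordering)) unique(patch$roi) else ordering
  frac_names <- paste0("frac_", gsub("-", "_", scheme$labels))
  rows <- lapply(seq_along(rois), function(ri) {
    r <- rois[ri]
    sel <- patch$roi == r & field$valid
    base <- data.frame(roi = r,
                       stream = patch$stream[match(r, patch$roi)],
                       hierarchy_rank = if (is.null(ordering)) ri else ri,
                       n_valid = sum(sel), stringsAsFactors = FALSE)
    if (!any(sel)) {
      warning(sprintf("ROI %s has no valid vertices", r))
      base$median_mu <- NA_real_
      for (fn in frac_names) base[[fn]] <- NA_real_
      base$unassigned <- NA_real_
      return(base)
    }
    mu <- field$mu_d[sel]
    cats <- categorize(mu, scheme)
    fr <- as.numeric(table(cats)[scheme$labels]) / sum(!is.na(cats))
    base$median_mu <- stats::median(mu)
    for (j in seq_along(frac_names)) base[[frac_names[j]]] <- fr[j]
    base$unassigned <- mean(is.na(cats))
    base
  })
  out <- do.call(rbind, rows)
  if (!is.null(quadrants)) {
    out$ll_minus_hh <- quadrants$ll_minus_hh[match(out$roi, quadrants$roi)]
  }
  rownames(out) <- NULL
  out
}

#' Linear gradient of a summary statistic along the cortical hierarchy
#'
#' Ordinary least-squares regression of a per-ROI scalar (median preference,
#' LL - HH difference, z-transformed correlation, ...) on its
#' occipital-to-frontal hierarchy rank; reports the slope with its
#' t-statistic and two-sided p-value.
#'
#' @param values per-ROI scalar, ordered consistently with `ranks`.
#' @param ranks hierarchy ranks (default `seq_along(values)`).
#' @return list with `slope`, `intercept`, `t_stat`, `p_value`, `n`.
#' @export
hierarchy_regression <- function(values, ranks = seq_along(values)) {
  keep <- is.finite(values) & is.finite(ranks)
  values <- values[keep]; ranks <- ranks[keep]
  if (length(values) < 3) stop("need at least 3 ROIs")
  if (stats::sd(values) == 0) {  # flat data: no trend, by convention
    return(list(slope = 0, intercept = values[1], t_stat = 0, p_value = 1,
                n = length(values)))
  }
  fit <- stats::lm(values ~ ranks)
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  slope <- unname(co["ranks", "Estimate"])
  tv <- co["ranks", "t value"]
  pv <- co["ranks", "Pr(>|t|)"]
  if (!is.finite(tv)) {  # zero residual variance
    if (abs(slope) < 1e-12) {       # flat data: no trend
      tv <- 0; pv <- 1
    } else {                        # exactly linear: infinitely strong trend
      tv <- sign(slope) * Inf; pv <- 0
    }
  }
  list(slope = slope, intercept = unname(co["(Intercept)", "Estimate"]),
       t_stat = unname(tv), p_value = unname(pv), n = length(values))
}

#' Render a preference map on a regular grid
#'
#' Resamples valid vertices' preferred durations onto an isotropic 2-D grid
#' (default 2 mm) as a Gaussian-kernel-weighted mean (default kernel FWHM
#' 4 mm): each cell is `sum(K * mu) / sum(K)` over valid vertices, with
#' `K = exp(-dist^2 / (2 sigma^2))`, `sigma = fwhm / 2.355`. Cells whose
#' total kernel weight falls below `weight_threshold` are masked `NA`
#' (locations outside the sampled surface).
#'
#' @param field a `tuning_field`.
#' @param grid_mm grid resolution, mm.
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @param weight_threshold minimum total kernel weight for an unmasked cell.
#' @return numeric matrix (rows = y, cols = x) with attributes `x_mm`,
#'   `y_mm` giving cell-center coordinates.
#' @export
render_preference_map <- function(field, grid_mm = 2.0, fwhm_mm = 4.0,
                                  weight_threshold = 0.05) {
  patch <- attr(field, "patch")
  ok <- field$valid
  if (!any(ok)) stop("no valid vertices to render")
  x <- patch$x_mm[ok]; y <- patch$y_mm[ok]; mu <- field$mu_d[ok]
  sigma <- fwhm_mm / 2.355
  gx <- seq(min(x), max(x), by = grid_mm)
  gy <- seq(min(y), max(y), by = grid_mm)
  out <- matrix(NA_real_, length(gy), length(gx))
  for (iy in seq_along(gy)) {
    for (ix in seq_along(gx)) {
      k <- exp(-((x - gx[ix])^2 + (y - gy[iy])^2) / (2 * sigma^2))
      w <- sum(k)
      if (w >= weight_threshold) out[iy, ix] <- sum(k * mu) / w
    }
  }
  structure(out, x_mm = gx, y_mm = gy)
}
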