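#' Empirical variogram of duration preferences
#'
#' Semivariance of duration preferences as a function of inter-vertex
#' distance, computed over all vertex pairs within scope. Values are
#' z-scored first, so the sill expected under no spatial structure is the
#' total (unit) variance. Pairwise distances are grouped into bins of width
#' `bin_width_mm` (bin i covers `[i*w, (i+1)*w)`, center `(i + 0.5)*w`) and
#' each bin receives the Matheron estimator
#' `gamma(h) = sum((z_i - z_j)^2) / (2 N(h))`. Empty bins are omitted.
#'
#' @param values per-vertex duration preferences (>= 2 vertices, nonzero
#'   variance).
#' @param patch a `surface_patch`; distances from [patch_distances()], so a
#'   precomputed (e.g., geodesic) matrix attached to the patch is honored.
#' @param bin_width_mm distance bin width, mm (default 2, the map-analysis
#'   resolution).
#' @param estimator `"matheron"` (default) or `"pairwise_variance"` (the
#'   plain within-bin variance of pair values, kept for comparison).
#' @param scale z-score the values first (default `TRUE`). With `FALSE` the
#'   values are used as given and the recorded total variance is their
#'   sample variance.
#' @return a `variogram_result` data.frame: `bin_center_mm`, `gamma`,
#'   `pair_count`; attributes `max_distance_mm`, `total_variance` (1 after
#'   z-scoring), `bin_width_mm`.
#' @export
empirical_variogram <- function(values, patch, bin_width_mm = 2.0,
                                estimator = c("matheron",
                                              "pairwise_variance"),
                                scale = TRUE) {
  estimator <- match.arg(estimator)
  stopifnot(length(values) == nrow(patch), length(values) >= 2)
  if (stats::sd(values) == 0 || !all(is.finite(values))) {
    stop("degenerate input: values must be finite with nonzero variance")
  }
  z <- if (scale) as.vector(base::scale(values)) else values
  D <- patch_distances(patch)
  iu <- which(upper.tri(D))
  d <- D[iu]
  ij <- arrayInd(iu, dim(D))
  dz2 <- (z[ij[, 1]] - z[ij[, 2]])^2
  bin <- floor(d / bin_width_mm)
  gamma <- if (estimator == "matheron") {
    tapply(dz2, bin, function(x) sum(x) / (2 * length(x)))
  } else {
    ## variance over the pooled pair endpoints within the bin
    vapply(split(seq_along(bin), bin), function(k) {
      stats::var(c(z[ij[k, 1]], z[ij[k, 2]]))
    }, 0)
  }
  cnt <- tapply(dz2, bin, length)
  bins <- as.integer(names(gamma))
  out <- data.frame(bin_center_mm = (bins + 0.5) * bin_width_mm,
                    gamma = as.numeric(gamma),
                    pair_count = as.integer(cnt))
  out <- out[order(out$bin_center_mm), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, max_distance_mm = max(d),
            total_variance = if (scale) 1 else stats::var(values),
            bin_width_mm = bin_width_mm,
            class = c("variogram_result", "data.frame"))
}

#' Variogram nugget
#'
#' The semivariance at the shortest inter-vertex distance (the first
#' nonempty bin), expressed as a fraction of the total variance. Near 1 for
#' spatially unstructured fields, near 0 for smooth maps.
#'
#' @param vg a `variogram_result`.
#' @param total_variance total (aspatial) variance; 1 for z-scored input.
#' @param min_pair_count smallest pair count a bin needs to define the
#'   nugget (default 1).
#' @return nugget fraction.
#' @export
extract_nugget <- function(vg, total_variance = attr(vg, "total_variance"),
                           min_pair_count = 1L) {
  ok <- vg$pair_count >= min_pair_count
  if (!any(ok)) stop("no variogram bin meets min_pair_count")
  vg$gamma[which(ok)[1]] / total_variance
}

#' Variogram range
#'
#' The smallest binned distance at which the semivariance first reaches the
#' total (aspatial) variance of the scope, expressed as a fraction of the
#' maximum inter-vertex distance. If the sill is never reached the range is
#' reported as 1 with `reached_sill = FALSE`.
#'
#' @inheritParams extract_nugget
#' @param max_distance_mm maximum inter-vertex distance, mm.
#' @return list with `range` (fraction in (0, 1]) and `reached_sill`.
#' @export
extract_range <- function(vg, total_variance = attr(vg, "total_variance"),
                          max_distance_mm = attr(vg, "max_distance_mm")) {
  hit <- which(vg$gamma >= total_variance)
  if (length(hit) == 0) return(list(range = 1, reached_sill = FALSE))
  list(range = min(1, vg$bin_center_mm[hit[1]] / max_distance_mm),
       reached_sill = TRUE)
}
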