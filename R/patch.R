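#' Build a regular lattice surface patch
#'
#' Creates a flat, regularly sampled stand-in for a patch of cortical surface:
#' `n_rows * n_cols` vertices on a rectangular lattice with `spacing_mm`
#' between neighbors, partitioned into contiguous rectangular ROI blocks.
#' The patch carries everything downstream spatial statistics need: vertex
#' coordinates in mm, an ROI label, a functional-stream label, and a
#' hemisphere code.
#'
#' @param n_rows,n_cols lattice dimensions (each >= 2).
#' @param spacing_mm distance between adjacent lattice vertices, in mm (> 0).
#' @param roi_blocks either `NULL` (a single ROI spanning the patch) or a
#'   data.frame with columns `roi` (label), `cols` (number of lattice columns
#'   assigned to that ROI, summing to `n_cols`) and optionally `stream`.
#'   ROIs are laid out as contiguous column bands, mimicking a strip of
#'   cortex traversed from one end to the other.
#' @param hemisphere `"L"` or `"R"`.
#'
#' @return A `surface_patch`: a data.frame with columns `vertex_id` (0-based,
#'   contiguous), `x_mm`, `y_mm`, `roi`, `stream`, `hemi`, plus attributes
#'   `n_rows`, `n_cols`, `spacing_mm`.
#' @examples
#' p <- make_patch(4, 8, 1, roi_blocks = data.frame(roi = c("A", "B"), cols = c(4, 4)))
#' table(p$roi)
#' @export
make_patch <- function(n_rows, n_cols, spacing_mm,
                       roi_blocks = NULL, hemisphere = "L") {
  if (n_rows < 2 || n_cols < 2) stop("n_rows and n_cols must each be >= 2")
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  if (is.null(roi_blocks)) {
    roi_blocks <- data.frame(roi = "ROI1", cols = n_cols, stream = "stream1")
  }
  if (is.null(roi_blocks$stream)) roi_blocks$stream <- roi_blocks$roi
  if (sum(roi_blocks$cols) != n_cols) {
    stop("roi_blocks$cols must sum to n_cols")
  }
  row_i <- rep(seq_len(n_rows) - 1L, times = n_cols)
  col_i <- rep(seq_len(n_cols) - 1L, each = n_rows)
  roi_of_col <- rep(roi_blocks$roi, times = roi_blocks$cols)
  stream_of_col <- rep(roi_blocks$stream, times = roi_blocks$cols)
  patch <- data.frame(
    vertex_id = seq_len(n_rows * n_cols) - 1L,
    x_mm = col_i * spacing_mm,
    y_mm = row_i * spacing_mm,
    roi = roi_of_col[col_i + 1L],
    stream = stream_of_col[col_i + 1L],
    hemi = hemisphere,
    stringsAsFactors = FALSE
  )
  structure(patch,
            n_rows = n_rows, n_cols = n_cols, spacing_mm = spacing_mm,
            class = c("surface_patch", "data.frame"))
}

#' Inter-vertex distance matrix of a patch
#'
#' Euclidean distances between stored vertex coordinates. A precomputed
#' (e.g., geodesic) distance matrix can be attached to a patch as attribute
#' `dist_matrix`, in which case it is returned instead.
#'
#' @param patch a `surface_patch`.
#' @return dense symmetric matrix (mm), zero diagonal.
#' @export
patch_distances <- function(patch) {
  pre <- attr(patch, "dist_matrix")
  if (!is.null(pre)) {
    stopifnot(nrow(pre) == nrow(patch), ncol(pre) == nrow(patch))
    return(pre)
  }
  as.matrix(stats::dist(cbind(patch$x_mm, patch$y_mm)))
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("surface_patch: %d vertices (%d x %d lattice, %.3g mm spacing), ROIs: %s\n",
              nrow(x), attr(x, "n_rows"), attr(x, "n_cols"),
              attr(x, "spacing_mm"), paste(unique(x$roi), collapse = ", ")))
  invisible(x)
}
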