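#' Kendall correlation matrix of preferences across regions
#'
#' Pairwise tau-b over subjects for every pair of regions, from a
#' subjects x regions table of median preferred durations. Symmetric with
#' unit diagonal; a region whose medians are constant across subjects
#' yields `NA` entries with a warning.
#'
#' @param median_mu numeric matrix, subjects x regions (column names are
#'   region labels).
#' @return a `corr_matrix`: square symmetric matrix of tau values.
#' @export
preference_corr_matrix <- function(median_mu) {
  stopifnot(is.matrix(median_mu), nrow(median_mu) >= 3, ncol(median_mu) >= 2)
  constant <- apply(median_mu, 2L, function(v) length(unique(v)) == 1)
  m <- suppressWarnings(stats::cor(median_mu, method = "kendall"))
  if (any(constant)) {
    warning(sprintf("constant region(s) %s: correlations undefined",
                    paste(colnames(median_mu)[constant], collapse = ", ")))
    m[constant, ] <- NA_real_
    m[, constant] <- NA_real_
  }
  diag(m) <- 1
  structure(m, class = c("corr_matrix", "matrix", "array"))
}

#' Convert a correlation matrix to inter-region distances
#'
#' Either Euclidean distance between the correlation matrix's rows (each
#' region's correlation profile treated as its coordinates — the behavior
#' of passing the matrix straight to a row-wise distance computation), or
#' simply `1 - tau`.
#'
#' @param m a `corr_matrix`.
#' @param method `"row_euclidean"` (default) or `"one_minus_tau"`.
#' @return a `stats::dist` object.
#' @export
corr_to_distance <- function(m, method = c("row_euclidean",
                                           "one_minus_tau")) {
  method <- match.arg(method)
  if (any(is.na(m))) stop("correlation matrix has missing entries")
  if (method == "row_euclidean") stats::dist(unclass(m))
  else stats::as.dist(1 - unclass(m))
}

#' Complete-linkage dendrogram of regional preferences
#'
#' Agglomerative hierarchical clustering of the inter-region distance
#' matrix with complete linkage.
#'
#' @param d a `stats::dist` object (from [corr_to_distance()]) or a
#'   symmetric square matrix.
#' @param linkage agglomeration method (default `"complete"`).
#' @return a `stats::hclust` object.
#' @export
hierarchical_cluster <- function(d, linkage = "complete") {
  if (!inherits(d, "dist")) {
    dm <- as.matrix(d)
    if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-12)) {
      stop("distance input must be a dist object or symmetric square matrix")
    }
    d <- stats::as.dist(dm)
  }
  if (attr(d, "Size") < 2) stop("need at least 2 items to cluster")
  stats::hclust(d, method = linkage)
}

#' Dendrogram as a Newick string
#'
#' @param hc a `stats::hclust` object.
#' @return single-element character vector (Newick, with branch lengths).
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
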