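## Headered TSV dialect shared by all interfaces: UTF-8, tab separated,
## '.' decimal, no quoting, no row names.

#' Write a pipeline table as TSV
#'
#' @param x data.frame (patch, beta table, tuning field, behavior table,
#'   ROI summary, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(format_numeric(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

## Round-trippable numeric formatting (17 significant digits).
format_numeric <- function(x) {
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- sprintf("%.17g", x[[j]])
  }
  x
}

#' Read a pipeline TSV
#' @param path TSV written by [write_tsv()].
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a JSON parameter sidecar
#'
#' Records generator/fit parameters and seeds alongside a stage's TSV
#' output.
#'
#' @param params named list.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a surface patch written by [write_tsv()]
#' @param path patch TSV.
#' @return a `surface_patch` (lattice attributes reconstructed from the
#'   coordinates when possible).
#' @export
read_patch_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("vertex_id", "x_mm", "y_mm", "roi", "stream", "hemi")
  stopifnot(all(need %in% names(df)))
  xs <- sort(unique(df$x_mm)); ys <- sort(unique(df$y_mm))
  structure(df,
            n_rows = length(ys), n_cols = length(xs),
            spacing_mm = if (length(xs) > 1) min(diff(xs)) else NA_real_,
            class = c("surface_patch", "data.frame"))
}
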