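sidecar_path <- function(path) paste0(path, ".json")

#' Read a labelled point cloud from CSV
#'
#' Reads a comma-separated file with a mandatory header row and columns
#' `x`, `y`, `category` and (optionally) `mark`. Empty `mark` cells are read
#' as `NA` (no mark). If a JSON sidecar `<path>.json` written by
#' [write_point_cloud()] exists, its domain bounds, boundary mode and time
#' are used; otherwise, and when `domain` is `NULL`, the bounding box of the
#' points (zero margin, clipped boundary) is used and recorded on the cloud.
#'
#' @param path CSV file path.
#' @param domain Optional [pp_domain()] overriding any sidecar.
#' @return A validated [point_cloud()].
#' @export
read_point_cloud <- function(path, domain = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!("mark" %in% names(df))) df$mark <- NA_real_
  bad <- which(!(df$category %in% PP_CATEGORIES))
  if (length(bad) > 0) {
    stop(sprintf("%s: unknown category '%s' on data row %d",
                 path, df$category[bad[1]], bad[1]), call. = FALSE)
  }
  time <- NULL
  if (is.null(domain) && file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    domain <- pp_domain(meta$xmin, meta$xmax, meta$ymin, meta$ymax,
                        boundary = meta$boundary)
    if (!is.null(meta$time)) time <- meta$time
  }
  point_cloud(df$x, df$y, df$category, mark = df$mark,
              domain = domain, time = time)
}

#' Write a labelled point cloud to CSV
#'
#' Writes the points as CSV (`x`, `y`, `category`, `mark`; `NA` marks become
#' empty cells, never 0) plus a JSON sidecar `<path>.json` holding the domain
#' bounds, boundary mode and snapshot time, so that
#' [read_point_cloud()] round-trips the cloud losslessly.
#'
#' @param cloud A [point_cloud()].
#' @param path Output CSV path.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, sidecar = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  utils::write.csv(cloud$points, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  if (sidecar) {
    d <- cloud$domain
    meta <- list(xmin = d$xmin, xmax = d$xmax, ymin = d$ymin, ymax = d$ymax,
                 boundary = d$boundary)
    if (!is.null(cloud$time)) meta$time <- cloud$time
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
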