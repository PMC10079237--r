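#' @useDynLib wpcf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Category vocabulary: blood vessel, macrophage, stromal, tumour, necrotic.
PP_CATEGORIES <- c("B", "M", "S", "T", "N")

#' Labelled 2D point cloud
#'
#' The core container: points on a bounded rectangular window, each carrying a
#' categorical label in `{B, M, S, T, N}` (blood vessel, macrophage, stromal,
#' tumour, necrotic) and, optionally, a continuous mark in `[0, 1]`. Marks
#' represent macrophage phenotype (0 = anti-tumour M1, 1 = pro-tumour M2) and
#' are `NA` for points where no mark is meaningful: an `NA` mark is "no mark",
#' distinct from a mark of 0, which is a definite M1 phenotype.
#'
#' @param x,y Numeric coordinates (cell diameters).
#' @param category Character or factor vector of labels in `{B, M, S, T, N}`.
#' @param mark Optional numeric vector of marks in `[0, 1]`; `NA` where
#'   undefined. Defaults to all-`NA`.
#' @param domain A [pp_domain()], or `NULL` to use the bounding box of the
#'   points (clipped boundary).
#' @param time Optional snapshot time in hours.
#' @return An object of class `point_cloud`: a list with a `points`
#'   data frame (`x`, `y`, `category`, `mark`), the `domain` and `time`.
#' @examples
#' pc <- point_cloud(c(1, 2), c(1, 2), c("B", "M"), mark = c(NA, 0.5),
#'                   domain = pp_domain(0, 4, 0, 4))
#' npoints(pc)
#' @export
point_cloud <- function(x, y, category, mark = NULL, domain = NULL, time = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n, length(category) == n)
  category <- as.character(category)
  bad <- which(!(category %in% PP_CATEGORIES))
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown category '%s' at point %d (vocabulary: %s)",
      category[bad[1]], bad[1], paste(PP_CATEGORIES, collapse = ", ")
    ), call. = FALSE)
  }
  if (is.null(mark)) mark <- rep(NA_real_, n)
  mark <- as.numeric(mark)
  stopifnot(length(mark) == n)
  bad_mark <- which(!is.na(mark) & (mark < 0 | mark > 1))
  if (length(bad_mark) > 0) {
    stop(sprintf("mark %g at point %d is outside [0, 1]",
                 mark[bad_mark[1]], bad_mark[1]), call. = FALSE)
  }
  if (is.null(domain)) {
    if (n == 0) stop("domain must be given for an empty cloud", call. = FALSE)
    # bounding box with zero margin; a hair of padding keeps degenerate
    # (collinear) input from producing a zero-area window
    pad_x <- if (min(x) < max(x)) 0 else 1e-9
    pad_y <- if (min(y) < max(y)) 0 else 1e-9
    domain <- pp_domain(min(x) - pad_x, max(x) + pad_x,
                        min(y) - pad_y, max(y) + pad_y)
  }
  stopifnot(is_pp_domain(domain))
  eps <- 1e-9
  inside <- x >= domain$xmin - eps & x <= domain$xmax + eps &
    y >= domain$ymin - eps & y <= domain$ymax + eps
  if (!all(inside)) {
    stop(sprintf("point %d at (%g, %g) lies outside the domain",
                 which(!inside)[1], x[!inside][1], y[!inside][1]), call. = FALSE)
  }
  structure(
    list(
      points = data.frame(x = x, y = y, category = category, mark = mark,
                          stringsAsFactors = FALSE),
      domain = domain,
      time = time
    ),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  counts <- category_counts(x)
  cat(sprintf("point cloud: %d points%s\n", npoints(x),
              if (!is.null(x$time)) sprintf(" at t = %g h", x$time) else ""))
  cat("  ", paste(sprintf("%s=%d", names(counts), counts), collapse = "  "), "\n")
  print(x$domain)
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A [point_cloud()].
#' @return Integer count.
#' @export
npoints <- function(cloud) nrow(cloud$points)

#' Per-category point counts
#'
#' Counts over the full vocabulary `{B, M, S, T, N}`; absent categories count 0,
#' so the counts always sum to [npoints()].
#'
#' @param cloud A [point_cloud()].
#' @return Named integer vector over the five categories.
#' @export
category_counts <- function(cloud) {
  tab <- table(factor(cloud$points$category, levels = PP_CATEGORIES))
  stats::setNames(as.integer(tab), PP_CATEGORIES)
}

#' Select the points of one category
#'
#' Returns the sub-cloud of points whose label equals `Q`, on the same domain.
#' This realises the binary target indicator of the cross-PCF (a point is
#' retained exactly when its label matches the target) as a selection.
#'
#' @param cloud A [point_cloud()].
#' @param Q A single category in `{B, M, S, T, N}`.
#' @return A [point_cloud()] with the matching points (possibly empty).
#' @export
subset_by_category <- function(cloud, Q) {
  stopifnot(inherits(cloud, "point_cloud"), length(Q) == 1)
  if (!(Q %in% PP_CATEGORIES)) {
    stop(sprintf("unknown category '%s'", Q), call. = FALSE)
  }
  keep <- cloud$points$category == Q
  out <- cloud
  out$points <- cloud$points[keep, , drop = FALSE]
  rownames(out$points) <- NULL
  out
}
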