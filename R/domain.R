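#' Rectangular observation window
#'
#' A bounded rectangular domain on which point patterns live. Lengths are in
#' units of one cell diameter, with the origin at the lower-left corner.
#' The `boundary` mode controls how the spatial statistics treat the window
#' edge: `"clipped"` restricts annuli to the window (border correction) and
#' uses the Euclidean metric, while `"periodic"` identifies opposite edges
#' (torus metric, no border correction needed).
#'
#' @param xmin,xmax,ymin,ymax Window bounds (cell diameters); must satisfy
#'   `xmin < xmax` and `ymin < ymax`.
#' @param boundary Either `"clipped"` (default) or `"periodic"`.
#' @return An object of class `pp_domain` with fields `xmin`, `xmax`, `ymin`,
#'   `ymax`, `boundary` and the window `area`.
#' @examples
#' d <- pp_domain(0, 40, 0, 40)
#' d$area
#' @export
pp_domain <- function(xmin = 0, xmax = 1, ymin = 0, ymax = 1,
                      boundary = c("clipped", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(xmin), is.numeric(xmax), is.numeric(ymin), is.numeric(ymax))
  if (!(xmin < xmax && ymin < ymax)) {
    stop("invalid domain: need xmin < xmax and ymin < ymax", call. = FALSE)
  }
  structure(
    list(
      xmin = as.numeric(xmin), xmax = as.numeric(xmax),
      ymin = as.numeric(ymin), ymax = as.numeric(ymax),
      boundary = boundary,
      area = (xmax - xmin) * (ymax - ymin)
    ),
    class = "pp_domain"
  )
}

#' @export
print.pp_domain <- function(x, ...) {
  cat(sprintf(
    "window [%g, %g] x [%g, %g] (%s), area %g\n",
    x$xmin, x$xmax, x$ymin, x$ymax, x$boundary, x$area
  ))
  invisible(x)
}

is_pp_domain <- function(x) inherits(x, "pp_domain")

domain_width <- function(domain) domain$xmax - domain$xmin
domain_height <- function(domain) domain$ymax - domain$ymin

#' Pairwise distances respecting the domain metric
#'
#' Euclidean distances for clipped domains; minimum-image (torus) distances
#' for periodic domains.
#'
#' @param x1,y1 Coordinates of the first point set.
#' @param x2,y2 Coordinates of the second point set.
#' @param domain A [pp_domain()].
#' @return A `length(x1)` by `length(x2)` matrix of distances.
#' @keywords internal
pair_distances <- function(x1, y1, x2, y2, domain) {
  dx <- outer(x1, x2, "-")
  dy <- outer(y1, y2, "-")
  if (domain$boundary == "periodic") {
    w <- domain_width(domain)
    h <- domain_height(domain)
    dx <- dx - w * round(dx / w)
    dy <- dy - h * round(dy / h)
  }
  sqrt(dx * dx + dy * dy)
}
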