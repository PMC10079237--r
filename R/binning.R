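#' Radial binning for pair correlation functions
#'
#' Contiguous half-open annuli `[r_k, r_k + dr)` with `r_0 = 0`, so bin `k`
#' (1-based) covers distances in `[(k-1) dr, k dr)`. The defaults
#' (`dr = 0.1`, `n_bins = 191`, radii up to 19.1 cell diameters) match the
#' 0-20 cell-diameter range over which tumour-scale spatial structure is
#' resolved, and give the default signature vector its standard length.
#'
#' @param dr Bin width in cell diameters (> 0).
#' @param n_bins Number of bins.
#' @return An object of class `radial_binning` with fields `dr`, `n_bins`,
#'   inner radii `r` and bin midpoints `r_mid`.
#' @export
radial_binning <- function(dr = 0.1, n_bins = 191) {
  stopifnot(is.numeric(dr), length(dr) == 1, dr > 0,
            is.numeric(n_bins), length(n_bins) == 1, n_bins >= 1)
  n_bins <- as.integer(n_bins)
  r <- (seq_len(n_bins) - 1) * dr
  structure(list(dr = dr, n_bins = n_bins, r = r, r_mid = r + dr / 2),
            class = "radial_binning")
}

#' @export
print.radial_binning <- function(x, ...) {
  cat(sprintf("radial binning: %d bins of width %g, r in [0, %g)\n",
              x$n_bins, x$dr, x$n_bins * x$dr))
  invisible(x)
}

#' Mark weighting function specification
#'
#' How closely a point's continuous mark `p` must match a target mark `P` to
#' contribute to the wPCF. The `triangular` kernel (the default),
#' `max(1 - |P - p| / delta_p, 0)`, is 1 at an exact match and falls linearly
#' to 0 at `|P - p| = delta_p`. The `gaussian` kernel,
#' `exp(-(P - p)^2 / (2 delta_p^2))`, is a smooth alternative. The
#' `indicator` kernel is 1 when `|P - p| <= tol` and 0 otherwise; it is the
#' limit of the triangular kernel as `delta_p` shrinks to 0, under which each
#' wPCF row reduces to the cross-PCF of the exactly-matching sub-population.
#'
#' @param kind One of `"triangular"`, `"gaussian"`, `"indicator"`.
#' @param delta_p Width parameter (> 0): triangular half-width or gaussian
#'   standard deviation. The default 0.2 trades smoothness of the surface
#'   (larger widths pool more points per row) against phenotype resolution.
#' @param tol Match tolerance for the indicator kernel.
#' @return An object of class `weight_spec`.
#' @export
weight_spec <- function(kind = c("triangular", "gaussian", "indicator"),
                        delta_p = 0.2, tol = 1e-9) {
  kind <- match.arg(kind)
  if (kind != "indicator" && !(is.numeric(delta_p) && delta_p > 0)) {
    stop("delta_p must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, delta_p = delta_p, tol = tol),
            class = "weight_spec")
}

#' Evaluate a mark weighting function
#'
#' @param spec A [weight_spec()].
#' @param P Target mark(s) in `[0, 1]`.
#' @param p Observed mark(s) in `[0, 1]`. `P` and `p` are recycled.
#' @return Weights in `[0, 1]`.
#' @examples
#' mark_weight(weight_spec(), 0.3, 0.2)  # 0.5 with the default width 0.2
#' @export
mark_weight <- function(spec, P, p) {
  stopifnot(inherits(spec, "weight_spec"))
  d <- abs(P - p)
  switch(spec$kind,
    triangular = pmax(1 - d / spec$delta_p, 0),
    gaussian = exp(-d^2 / (2 * spec$delta_p^2)),
    indicator = as.numeric(d <= spec$tol)
  )
}

#' Default target-mark grid
#'
#' An ascending grid of 101 target marks, 0 to 1 in steps of 0.01, at which
#' wPCF rows are evaluated.
#'
#' @return Numeric vector of length 101.
#' @export
default_p_grid <- function() seq(0, 1, by = 0.01)
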