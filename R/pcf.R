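# Shared kernel for the pair correlation statistics.
#
# For annulus centres (x1, y1) and counted target points (x2, y2), returns the
# n_centres x n_bins matrix M with
#   M[i, k] = sum_j (A / A_rk(x_i)) I_k(|x_i - x_j|),
# i.e. the border-corrected, CSR-normalised count of targets in annulus k of
# centre i. `self` gives, per centre, the index into the target set that is
# the same physical point (NA if none); such pairs are excluded.
pair_bin_counts <- function(x1, y1, x2, y2, binning, domain, self = NULL) {
  ns <- length(x1)
  nt <- length(x2)
  nb <- binning$n_bins
  d <- pair_distances(x1, y1, x2, y2, domain)
  if (!is.null(self)) {
    has <- which(!is.na(self))
    if (length(has) > 0) d[cbind(has, self[has])] <- NA_real_
  }
  bin <- floor(d / binning$dr) + 1
  ok <- which(!is.na(bin) & bin >= 1 & bin <= nb)
  counts <- matrix(0, ns, nb)
  if (length(ok) > 0) {
    i <- ((ok - 1) %% ns) + 1          # row index of each retained pair
    cell <- i + (bin[ok] - 1) * ns
    counts[] <- tabulate(cell, nbins = ns * nb)
  }
  areas <- annulus_area_matrix(x1, y1, binning, domain)
  m <- matrix(0, ns, nb)
  nz <- counts > 0
  m[nz] <- counts[nz] * domain$area / areas[nz]
  m
}

#' Cross-type pair correlation function
#'
#' For each radial bin, the density of `target` points in annuli centred on
#' `source` points, relative to the density expected under complete spatial
#' randomness (CSR). Values above 1 indicate clustering of targets at that
#' distance from sources; values below 1 indicate exclusion. Annuli are
#' border-corrected on clipped domains (only the in-window area counts), and
#' distances use the torus metric on periodic domains. Because the border
#' correction is attached to the annulus centres, the statistic is not
#' symmetric in `source` and `target` on clipped domains (it is on periodic
#' ones). Self-pairs are excluded when `source == target`.
#'
#' @param cloud A [point_cloud()].
#' @param source Category whose points centre the annuli.
#' @param target Category counted within the annuli.
#' @param binning A [radial_binning()].
#' @return An object of class `cross_pcf`: fields `binning`, `values` (one per
#'   bin; all `NA` with `undefined = TRUE` when either population is empty),
#'   `source`, `target`, `n_source`, `n_target`.
#' @export
cross_pcf <- function(cloud, source, target, binning = radial_binning()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(binning, "radial_binning"))
  src <- cloud$points$category == source
  tgt <- cloud$points$category == target
  ns <- sum(src)
  nt <- sum(tgt)
  out <- structure(
    list(binning = binning, values = rep(NA_real_, binning$n_bins),
         source = source, target = target, n_source = ns, n_target = nt,
         undefined = TRUE),
    class = "cross_pcf"
  )
  if (ns == 0 || nt == 0) return(out)
  p <- cloud$points
  self <- NULL
  if (source == target) self <- seq_len(ns)  # same ordering in both subsets
  m <- pair_bin_counts(p$x[src], p$y[src], p$x[tgt], p$y[tgt],
                       binning, cloud$domain, self = self)
  out$values <- colSums(m) / (ns * nt)
  out$undefined <- FALSE
  out
}

#' @export
print.cross_pcf <- function(x, ...) {
  cat(sprintf("cross-PCF g_%s%s: %d bins (dr = %g), n_%s = %d, n_%s = %d%s\n",
              x$source, x$target, x$binning$n_bins, x$binning$dr,
              x$source, x$n_source, x$target, x$n_target,
              if (x$undefined) " [undefined]" else ""))
  invisible(x)
}

#' Weighted pair correlation function
#'
#' Generalises the cross-PCF to continuous marks: annuli are centred on the
#' mark-carrying points, and each centre's contribution is weighted by how
#' closely its mark matches a target mark `P`, via the weighting kernel in
#' `spec`. For each `P` on `p_grid` and each radial bin, the value is the
#' weighted, border-corrected density of `target` points around mark-carriers,
#' normalised by the total weight `W_P = sum_i w(P, p_i)` and the CSR density,
#' so that 1 again means "no correlation". Rows where `W_P = 0` (no point has
#' a mark near `P`) are undefined and returned as `NA` with the row flagged in
#' `undefined`, never silently 0 or 1.
#'
#' @param cloud A [point_cloud()] with at least one non-`NA` mark.
#' @param target Category counted within the annuli (e.g. `"B"` for vessels).
#' @param binning A [radial_binning()].
#' @param p_grid Ascending target-mark grid in `[0, 1]`.
#' @param spec A [weight_spec()].
#' @return An object of class `wpcf_surface`: `values` is a
#'   `length(p_grid)` by `n_bins` matrix (rows indexed by `P`), with
#'   `total_weight` (`W_P` per row), logical `undefined` per row, plus the
#'   grids and `target`.
#' @export
wpcf <- function(cloud, target, binning = radial_binning(),
                 p_grid = default_p_grid(), spec = weight_spec()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(binning, "radial_binning"),
            inherits(spec, "weight_spec"))
  if (is.unsorted(p_grid)) stop("p_grid must be ascending", call. = FALSE)
  p <- cloud$points
  carriers <- which(!is.na(p$mark))
  tgt <- which(p$category == target)
  np <- length(p_grid)
  nb <- binning$n_bins
  out <- structure(
    list(binning = binning, p_grid = p_grid,
         values = matrix(NA_real_, np, nb),
         total_weight = rep(0, np),
         undefined = rep(TRUE, np),
         target = target, n_target = length(tgt)),
    class = "wpcf_surface"
  )
  if (length(carriers) == 0) {
    warning("cloud has no mark-carrying points; wPCF surface is fully undefined")
    return(out)
  }
  w <- vapply(seq_along(carriers),
              function(i) mark_weight(spec, p_grid, p$mark[carriers[i]]),
              numeric(np))
  if (np == 1) w <- matrix(w, nrow = 1)
  w_p <- rowSums(w)
  out$total_weight <- w_p
  if (length(tgt) == 0) return(out)  # all rows stay undefined: nothing to count
  self <- match(carriers, tgt)       # carrier that is itself a target point
  m <- pair_bin_counts(p$x[carriers], p$y[carriers], p$x[tgt], p$y[tgt],
                       binning, cloud$domain, self = self)
  vals <- (w %*% m) / (w_p * length(tgt))
  vals[w_p == 0, ] <- NA_real_
  out$values <- vals
  out$undefined <- w_p == 0
  out
}

#' @export
print.wpcf_surface <- function(x, ...) {
  cat(sprintf(
    "wPCF surface vs '%s': %d target marks x %d bins (dr = %g), %d undefined row(s)\n",
    x$target, length(x$p_grid), x$binning$n_bins, x$binning$dr,
    sum(x$undefined)))
  invisible(x)
}

#' Horizontal slice through a wPCF surface
#'
#' Extracts the row of the surface at a fixed target mark `P`. The slice is
#' interpretable as a cross-PCF between the target category and the points
#' whose marks are close to `P`. By default `P` must lie on the surface's
#' mark grid (within numerical tolerance); with `interpolate = TRUE` a
#' linear interpolation between the two bracketing rows is returned instead.
#'
#' @param surface A [wpcf()] result.
#' @param P Target mark at which to slice.
#' @param interpolate Allow off-grid `P` by linear interpolation.
#' @return An object of class `wpcf_slice` with `binning`, `values`, `P`,
#'   `total_weight` and `undefined`.
#' @export
wpcf_slice <- function(surface, P, interpolate = FALSE) {
  stopifnot(inherits(surface, "wpcf_surface"), length(P) == 1)
  g <- surface$p_grid
  if (P < min(g) - 1e-9 || P > max(g) + 1e-9) {
    stop(sprintf("P = %g is outside the surface's mark grid [%g, %g]",
                 P, min(g), max(g)), call. = FALSE)
  }
  hit <- which(abs(g - P) < 1e-9)
  if (length(hit) == 1) {
    values <- surface$values[hit, ]
    tw <- surface$total_weight[hit]
    und <- surface$undefined[hit]
  } else if (interpolate) {
    hi <- which(g > P)[1]
    lo <- hi - 1
    f <- (P - g[lo]) / (g[hi] - g[lo])
    values <- (1 - f) * surface$values[lo, ] + f * surface$values[hi, ]
    tw <- (1 - f) * surface$total_weight[lo] + f * surface$total_weight[hi]
    und <- surface$undefined[lo] || surface$undefined[hi]
  } else {
    stop(sprintf("P = %g is not on the mark grid (set interpolate = TRUE to allow)",
                 P), call. = FALSE)
  }
  structure(list(binning = surface$binning, values = values, P = P,
                 total_weight = tw, undefined = und, target = surface$target),
            class = "wpcf_slice")
}

#' Two-mark weighted pair correlation function
#'
#' Extends the wPCF to a pair of mark-carrying point sets: annuli are centred
#' on points of `cloud_a` weighted towards target mark `P1`, and points of
#' `cloud_b` weighted towards `P2` are counted, giving a surface over
#' `(P1, P2, r)` that resolves, e.g., colocalisation of low-mark with
#' high-mark cells. Normalisation is by `W_P1 * W_P2` and the CSR density,
#' analogously to [wpcf()]. When the same cloud is supplied twice, self-pairs
#' are excluded.
#'
#' @param cloud_a,cloud_b [point_cloud()]s on the same domain, both with marks.
#' @param binning A [radial_binning()].
#' @param p1_grid,p2_grid Target-mark grids for the two clouds.
#' @param spec A [weight_spec()].
#' @return An object of class `wpcf2_surface` with `values` an array of
#'   dimension `(length(p1_grid), length(p2_grid), n_bins)`, per-grid total
#'   weights and a logical `undefined` matrix over `(P1, P2)`.
#' @export
wpcf_two_marks <- function(cloud_a, cloud_b, binning = radial_binning(),
                           p1_grid = default_p_grid(),
                           p2_grid = default_p_grid(),
                           spec = weight_spec()) {
  stopifnot(inherits(cloud_a, "point_cloud"), inherits(cloud_b, "point_cloud"))
  a <- cloud_a$points[!is.na(cloud_a$points$mark), , drop = FALSE]
  b <- cloud_b$points[!is.na(cloud_b$points$mark), , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("both clouds must carry marks", call. = FALSE)
  }
  domain <- cloud_a$domain
  nb <- binning$n_bins
  n1 <- length(p1_grid)
  n2 <- length(p2_grid)
  w1 <- vapply(a$mark, function(pm) mark_weight(spec, p1_grid, pm), numeric(n1))
  w2 <- vapply(b$mark, function(pm) mark_weight(spec, p2_grid, pm), numeric(n2))
  if (n1 == 1) w1 <- matrix(w1, nrow = 1)  # n1 x nrow(a)
  if (n2 == 1) w2 <- matrix(w2, nrow = 1)  # n2 x nrow(b)
  w1_tot <- rowSums(w1)
  w2_tot <- rowSums(w2)
  same <- identical(cloud_a$points, cloud_b$points)
  d <- pair_distances(a$x, a$y, b$x, b$y, domain)
  if (same) diag(d) <- NA_real_
  bin <- floor(d / binning$dr) + 1
  areas <- annulus_area_matrix(a$x, a$y, binning, domain)
  af <- domain$area / areas
  vals <- array(NA_real_, c(n1, n2, nb))
  denom <- outer(w1_tot, w2_tot)
  ok <- denom > 0
  for (k in seq_len(nb)) {
    ck <- (!is.na(bin) & bin == k) * 1
    mk <- ck * af[, k]              # scales row i by A / A_rk(x_i)
    num <- (w1 %*% mk) %*% t(w2)
    vk <- matrix(NA_real_, n1, n2)
    vk[ok] <- num[ok] / denom[ok]
    vals[, , k] <- vk
  }
  structure(
    list(binning = binning, p1_grid = p1_grid, p2_grid = p2_grid,
         values = vals, total_weight_1 = w1_tot, total_weight_2 = w2_tot,
         undefined = !ok),
    class = "wpcf2_surface"
  )
}
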