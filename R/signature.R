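#' PCF signature of a labelled point cloud
#'
#' The three-statistic spatial summary of one snapshot: the wPCF between
#' macrophage phenotype and blood vessels, the wPCF between macrophage
#' phenotype and tumour cells, and the vessel-to-tumour cross-PCF, all
#' computed from the same cloud with shared radial and mark grids. Undefined
#' rows (mark values carried by no macrophage) and undefined curves (empty
#' populations) are preserved as `NA` plus masks.
#'
#' @param cloud A [point_cloud()].
#' @param binning A [radial_binning()] shared by all three statistics.
#' @param p_grid Target-mark grid shared by both wPCF surfaces.
#' @param spec A [weight_spec()].
#' @return An object of class `pcf_signature` with components `wpcf_B`,
#'   `wpcf_T` (surfaces) and `g_BT` (cross-PCF), plus the snapshot `time`.
#' @export
compute_signature <- function(cloud, binning = radial_binning(),
                              p_grid = default_p_grid(),
                              spec = weight_spec()) {
  has_marks <- any(!is.na(cloud$points$mark))
  empty_surface <- function(target) {
    structure(
      list(binning = binning, p_grid = p_grid,
           values = matrix(NA_real_, length(p_grid), binning$n_bins),
           total_weight = rep(0, length(p_grid)),
           undefined = rep(TRUE, length(p_grid)),
           target = target, n_target = sum(cloud$points$category == target)),
      class = "wpcf_surface"
    )
  }
  structure(
    list(
      wpcf_B = if (has_marks) wpcf(cloud, "B", binning, p_grid, spec)
               else empty_surface("B"),
      wpcf_T = if (has_marks) wpcf(cloud, "T", binning, p_grid, spec)
               else empty_surface("T"),
      g_BT = cross_pcf(cloud, "B", "T", binning),
      time = cloud$time
    ),
    class = "pcf_signature"
  )
}

#' @export
print.pcf_signature <- function(x, ...) {
  cat(sprintf(
    "PCF signature%s: %d mark values x %d bins; undefined rows B/T: %d/%d; g_BT %s\n",
    if (!is.null(x$time)) sprintf(" (t = %g h)", x$time) else "",
    length(x$wpcf_B$p_grid), x$wpcf_B$binning$n_bins,
    sum(x$wpcf_B$undefined), sum(x$wpcf_T$undefined),
    if (x$g_BT$undefined) "undefined" else "defined"))
  invisible(x)
}

#' Flatten a PCF signature into a numeric vector
#'
#' Concatenates the three statistics in the fixed order
#' `[wPCF vs B (mark-major, radius-minor), wPCF vs T, g_BT]`, giving a
#' vector of length `n_bins * (2 * length(p_grid) + 1)` — 38,773 with the
#' default grids. Undefined entries are imputed with 1, the no-correlation
#' (CSR) baseline, and recorded in the imputation mask so the choice remains
#' auditable.
#'
#' @param signature A [compute_signature()] result.
#' @return An object of class `signature_vector`: list with `values`,
#'   logical `imputation_mask`, and the `layout` (grids and block order)
#'   needed to invert the flattening.
#' @export
vectorize_signature <- function(signature) {
  stopifnot(inherits(signature, "pcf_signature"))
  sb <- signature$wpcf_B
  st <- signature$wpcf_T
  g <- signature$g_BT
  if (!identical(sb$binning, st$binning) || !identical(sb$binning, g$binning) ||
      !identical(sb$p_grid, st$p_grid)) {
    stop("signature components use different grids", call. = FALSE)
  }
  # mark-major, radius-minor: rows of the surface matrix laid end to end
  v <- c(as.vector(t(sb$values)), as.vector(t(st$values)), g$values)
  mask <- is.na(v)
  v[mask] <- 1
  structure(
    list(values = v, imputation_mask = mask,
         layout = list(n_bins = sb$binning$n_bins, dr = sb$binning$dr,
                       p_grid = sb$p_grid)),
    class = "signature_vector"
  )
}

#' @export
print.signature_vector <- function(x, ...) {
  cat(sprintf("signature vector: length %d, %d imputed entries\n",
              length(x$values), sum(x$imputation_mask)))
  invisible(x)
}

#' Expected signature vector length for given grids
#'
#' `n_bins * (2 * n_marks + 1)`: two wPCF blocks plus one cross-PCF block.
#'
#' @param binning A [radial_binning()].
#' @param p_grid Target-mark grid.
#' @return Integer length (38,773 at the defaults).
#' @export
signature_length <- function(binning = radial_binning(),
                             p_grid = default_p_grid()) {
  binning$n_bins * (2L * length(p_grid) + 1L)
}

# Invert vectorize_signature's layout: reshape a flat vector back into the
# three-component signature structure (used for centroid back-projection).
reshape_signature <- function(values, layout) {
  nb <- layout$n_bins
  np <- length(layout$p_grid)
  stopifnot(length(values) == nb * (2 * np + 1))
  binning <- radial_binning(dr = layout$dr, n_bins = nb)
  surf <- function(block, target) {
    structure(
      list(binning = binning, p_grid = layout$p_grid,
           values = matrix(block, np, nb, byrow = TRUE),
           total_weight = rep(NA_real_, np),
           undefined = rep(FALSE, np), target = target, n_target = NA),
      class = "wpcf_surface"
    )
  }
  structure(
    list(
      wpcf_B = surf(values[seq_len(np * nb)], "B"),
      wpcf_T = surf(values[np * nb + seq_len(np * nb)], "T"),
      g_BT = structure(
        list(binning = binning, values = values[2 * np * nb + seq_len(nb)],
             source = "B", target = "T", n_source = NA, n_target = NA,
             undefined = FALSE),
        class = "cross_pcf"
      ),
      time = NULL
    ),
    class = "pcf_signature"
  )
}
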