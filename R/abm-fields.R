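# Diffusible fields on a regular, cell-centred grid. Node (i, j) sits at
# ((i - 1/2) h, (j - 1/2) h) relative to the domain's lower-left corner.

FIELD_NAMES <- c("oxygen", "csf1", "cxcl12", "tgfb", "egf")

new_field <- function(name, D, lambda, domain, h, init = 0) {
  nx <- max(2L, as.integer(round(domain_width(domain) / h)))
  ny <- max(2L, as.integer(round(domain_height(domain) / h)))
  list(name = name, D = D, lambda = lambda, h = h, nx = nx, ny = ny,
       m = matrix(init, nx, ny))
}

# Nearest grid node of each point (returns linear indices into the matrix).
field_node_index <- function(field, domain, x, y) {
  i <- pmin(pmax(floor((x - domain$xmin) / field$h) + 1, 1), field$nx)
  j <- pmin(pmax(floor((y - domain$ymin) / field$h) + 1, 1), field$ny)
  cbind(i, j)
}

# Deposit per-point rates onto nearest nodes as a source/sink density map
# (rate / h^2, the grid delta function).
deposit_rates <- function(field, domain, x, y, rate) {
  m <- matrix(0, field$nx, field$ny)
  if (length(x) > 0) {
    ij <- field_node_index(field, domain, x, y)
    lin <- ij[, 1] + (ij[, 2] - 1) * field$nx
    if (length(rate) == 1) {
      m[] <- tabulate(lin, nbins = field$nx * field$ny) * (rate / field$h^2)
    } else {
      dens <- rate / field$h^2
      agg <- rowsum(dens, lin)
      m[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  m
}

# One reaction-diffusion update of duration dt_total, sub-stepped to respect
# the explicit stability bound.
advance_field <- function(field, src, sink, dt_total, periodic = FALSE) {
  rate <- 4 * field$D / field$h^2 + field$lambda + max(sink)
  nsub <- max(1L, as.integer(ceiling(dt_total * rate / 0.45)))
  field$m <- field_substeps(field$m, src, sink, field$D, field$lambda,
                            field$h, dt_total, nsub, periodic)
  field
}

# Field values at arbitrary points by bilinear interpolation.
field_at <- function(field, domain, x, y) {
  h <- field$h
  gx <- (x - domain$xmin) / h + 0.5
  gy <- (y - domain$ymin) / h + 0.5
  i0 <- pmin(pmax(floor(gx), 1), field$nx - 1)
  j0 <- pmin(pmax(floor(gy), 1), field$ny - 1)
  fx <- pmin(pmax(gx - i0, 0), 1)
  fy <- pmin(pmax(gy - j0, 0), 1)
  m <- field$m
  v00 <- m[cbind(i0, j0)]
  v10 <- m[cbind(i0 + 1, j0)]
  v01 <- m[cbind(i0, j0 + 1)]
  v11 <- m[cbind(i0 + 1, j0 + 1)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# Gradient at arbitrary points: central differences at the nearest node
# (one-sided at the grid edge).
field_gradient_at <- function(field, domain, x, y) {
  ij <- field_node_index(field, domain, x, y)
  i <- ij[, 1]
  j <- ij[, 2]
  m <- field$m
  h <- field$h
  ip <- pmin(i + 1, field$nx); im <- pmax(i - 1, 1)
  jp <- pmin(j + 1, field$ny); jm <- pmax(j - 1, 1)
  gx <- (m[cbind(ip, j)] - m[cbind(im, j)]) / ((ip - im) * h)
  gy <- (m[cbind(i, jp)] - m[cbind(i, jm)]) / ((jp - jm) * h)
  cbind(gx, gy)
}

# Source (additive) and sink (linear, multiplies the field) maps of each
# field given the current cells and vessels.
field_source_maps <- function(state) {
  p <- state$params
  cl <- state$cells
  d <- p$domain
  f <- state$fields
  is_t <- cl$type == CELL_TUMOUR
  is_s <- cl$type == CELL_STROMAL
  is_m <- cl$type == CELL_MACRO
  zero <- function(fl) matrix(0, fl$nx, fl$ny)
  list(
    oxygen = list(
      src = deposit_rates(f$oxygen, d, state$vessels$x, state$vessels$y,
                          p$kappa_omega),
      sink = deposit_rates(f$oxygen, d, cl$x[is_t | is_s], cl$y[is_t | is_s],
                           p$uptake_omega)
    ),
    csf1 = list(
      src = deposit_rates(f$csf1, d, cl$x[is_t], cl$y[is_t], p$kappa_csf1),
      sink = zero(f$csf1)
    ),
    cxcl12 = list(
      src = deposit_rates(f$cxcl12, d, state$vessels$x, state$vessels$y,
                          p$kappa_cxcl12),
      sink = zero(f$cxcl12)
    ),
    tgfb = list(
      src = deposit_rates(f$tgfb, d, cl$x[is_t], cl$y[is_t], p$kappa_tgfb),
      sink = zero(f$tgfb)
    ),
    egf = list(
      src = deposit_rates(f$egf, d, cl$x[is_m], cl$y[is_m],
                          p$kappa_egf * cl$phen[is_m]),
      sink = zero(f$egf)
    )
  )
}

#' Advance the diffusible fields by one step
#'
#' Each of the five fields takes one reaction-diffusion update of duration
#' `dt`: explicit five-point-Laplacian diffusion with zero-flux boundaries,
#' linear decay, and point sources deposited on the nearest grid node
#' (vessels supply oxygen and CXCL12; tumour cells supply CSF-1 and
#' TGF-beta and, with stromal cells, consume oxygen; macrophages supply EGF
#' at a rate proportional to phenotype). Sub-stepping keeps the explicit
#' scheme inside its diffusive stability bound, and concentrations remain
#' non-negative.
#'
#' @param state An ABM state (see [abm_init()]).
#' @param dt Duration in hours (defaults to the params timestep).
#' @return The state with updated fields.
#' @export
update_fields <- function(state, dt = state$params$dt) {
  maps <- field_source_maps(state)
  for (nm in FIELD_NAMES) {
    state$fields[[nm]] <- advance_field(state$fields[[nm]],
                                        maps[[nm]]$src, maps[[nm]]$sink, dt)
  }
  state
}
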