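#' Parameters of the tumour-macrophage agent-based model
#'
#' All lengths are in cell diameters, all times in hours, and forces in units
#' of drag x diameter/hour (the drag coefficient `nu` is 1 by default, so a
#' force of 1 moves a cell at 1 diameter/hour). The model couples four cell
#' populations (stromal, tumour, necrotic, macrophage) and fixed point
#' vessels to five diffusible fields (oxygen, CSF-1, CXCL12, TGF-beta, EGF)
#' on a regular grid.
#'
#' Defaults describe a 40 x 40 diameter tissue patch with about 20 vessels
#' kept away from the centre, an initial tumour disc of 30 cells, and stroma
#' filling the rest. They were chosen so that the qualitative growth regimes
#' (Equilibrium / Escape / Elimination) emerge as the macrophage CSF-1
#' chemotactic sensitivity `chi_c_m` and the extravasation half-saturation
#' `c_half` are varied; see the methods vignette for the reasoning behind
#' each value.
#'
#' @param nu Drag coefficient.
#' @param r_int Interaction radius for cell-cell springs and macrophage
#'   killing (diameters).
#' @param spring_k Stiffness of the repulsive (volume-exclusion) branch of
#'   the pairwise linear force law.
#' @param spring_adhesion Stiffness of the attractive (adhesion) branch,
#'   acting between the rest length and the cutoff. Kept well below
#'   `spring_k`: if adhesion matches repulsion, the long-range attraction of
#'   second-shell neighbours compresses tissue into collapsing clusters.
#' @param chi_c_m,chi_xi_m Macrophage chemotactic force magnitudes towards
#'   CSF-1 (anti-tumour, weighted `1 - p`) and CXCL12 (pro-tumour, weighted
#'   `p`).
#' @param chi_eps_t Tumour-cell chemotactic force magnitude up EGF gradients.
#' @param p_star Maximum macrophage extravasation probability per hour per
#'   vessel.
#' @param c_half CSF-1 concentration of half-maximal extravasation.
#' @param p_phi_star Maximum tumour-kill probability per hour.
#' @param t_cool Cooldown after a kill during which a macrophage cannot kill
#'   (hours).
#' @param delta_p Phenotype progression rate (per hour) while TGF-beta
#'   exceeds `g_crit`.
#' @param g_crit TGF-beta threshold driving the M1 -> M2 transition.
#' @param random_motility Magnitude of the isotropic random force on
#'   macrophages.
#' @param grad_tol Gradient magnitude below which a chemotactic force is
#'   treated as zero (avoids normalising a zero gradient).
#' @param egf_grad_tol Gradient threshold for the tumour cells' EGF
#'   response. Because chemotactic forces follow the unit gradient, any
#'   non-zero field would otherwise pull at full strength; the higher
#'   threshold means tumour cells respond only to the strong EGF fields of
#'   a substantial pro-tumour macrophage population, not to one or two
#'   stray M2 cells.
#' @param kappa_omega,uptake_omega Oxygen supply rate per vessel and linear
#'   consumption coefficient per stromal/tumour cell.
#' @param kappa_csf1 CSF-1 production rate per tumour cell.
#' @param kappa_cxcl12 CXCL12 production rate per vessel.
#' @param kappa_tgfb TGF-beta production rate per tumour cell.
#' @param kappa_egf EGF production rate per macrophage at phenotype `p = 1`
#'   (scales linearly with `p`).
#' @param D_omega,D_csf1,D_cxcl12,D_tgfb,D_egf Diffusivities.
#' @param lambda_omega,lambda_csf1,lambda_cxcl12,lambda_tgfb,lambda_egf Decay
#'   rates.
#' @param omega_H_tum,omega_N_tum Oxygen thresholds below which tumour cells
#'   pause their cycle (hypoxia, reversible) or die (necrosis, irreversible);
#'   must satisfy `omega_N < omega_H`.
#' @param omega_H_str,omega_N_str The stromal analogues.
#' @param a_h_str Contact-inhibition threshold: a stromal cell pauses when its
#'   effective area falls below this fraction of its relaxed area.
#' @param cycle_duration Mean cell-cycle time (hours); per-cell durations are
#'   drawn uniformly within 25 percent of the mean.
#' @param necrosis_clear_time Hours over which a necrotic cell shrinks
#'   linearly to zero radius and is removed.
#' @param cell_radius Relaxed cell radius (0.5 diameter).
#' @param division_offset Distance at which a daughter cell is placed.
#' @param dt Timestep (hours); events use probability `rate * dt`, so
#'   `p_star * dt` and `p_phi_star * dt` must not exceed 1.
#' @param mech_substeps Number of sub-steps for the overdamped position
#'   update within each `dt` (the spring forces are the stiffest part of the
#'   system; sub-stepping keeps crowded regions stable without shrinking the
#'   event timestep).
#' @param domain A clipped [pp_domain()].
#' @param field_spacing PDE grid spacing (must not exceed `r_int`).
#' @param n_vessels Number of vessels.
#' @param vessel_min_sep Minimum pairwise vessel separation.
#' @param vessel_exclusion Minimum vessel distance from the domain centre
#'   (keeps the vasculature clear of the initial tumour).
#' @param n_tumour_init Initial tumour cell count.
#' @param stroma_spacing Initial stromal lattice spacing.
#' @param omega_init Initial (and burn-in) oxygen level.
#' @param burn_in Hours of field-only equilibration before cells move.
#' @param max_cells Safety cap on the total cell count; divisions are
#'   suppressed beyond it.
#' @return An object of class `abm_params`.
#' @export
abm_params <- function(nu = 1,
                       r_int = 1.5,
                       spring_k = 10,
                       spring_adhesion = 1,
                       chi_c_m = 2,
                       chi_xi_m = 2,
                       chi_eps_t = 1.5,
                       p_star = 0.35,
                       c_half = 0.5,
                       p_phi_star = 0.06,
                       t_cool = 2,
                       delta_p = 0.1,
                       g_crit = 0.3,
                       random_motility = 0.7,
                       grad_tol = 1e-3,
                       egf_grad_tol = 0.08,
                       kappa_omega = 5, uptake_omega = 0.12,
                       kappa_csf1 = 0.5,
                       kappa_cxcl12 = 2,
                       kappa_tgfb = 0.2,
                       kappa_egf = 2,
                       D_omega = 10, lambda_omega = 0.05,
                       D_csf1 = 5, lambda_csf1 = 0.05,
                       D_cxcl12 = 5, lambda_cxcl12 = 0.08,
                       D_tgfb = 2, lambda_tgfb = 0.5,
                       D_egf = 2, lambda_egf = 0.2,
                       omega_H_tum = 0.12, omega_N_tum = 0.06,
                       omega_H_str = 0.2, omega_N_str = 0.05,
                       a_h_str = 0.8,
                       cycle_duration = 30,
                       necrosis_clear_time = 48,
                       cell_radius = 0.5,
                       division_offset = 0.3,
                       dt = 0.05,
                       mech_substeps = 4,
                       domain = pp_domain(0, 40, 0, 40),
                       field_spacing = 1,
                       n_vessels = 20,
                       vessel_min_sep = 4,
                       vessel_exclusion = 14,
                       n_tumour_init = 30,
                       stroma_spacing = 1,
                       omega_init = 1,
                       burn_in = 5,
                       max_cells = 10000) {
  p <- as.list(environment())
  rates <- c(nu = nu, r_int = r_int, spring_k = spring_k,
             t_cool = t_cool, delta_p = delta_p,
             cycle_duration = cycle_duration,
             necrosis_clear_time = necrosis_clear_time, dt = dt,
             field_spacing = field_spacing, cell_radius = cell_radius)
  if (any(rates <= 0)) {
    stop(sprintf("parameter(s) must be > 0: %s",
                 paste(names(rates)[rates <= 0], collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(spring_adhesion >= 0,
            p_star >= 0, p_phi_star >= 0, chi_c_m >= 0, chi_xi_m >= 0,
            chi_eps_t >= 0, c_half > 0, g_crit >= 0,
            a_h_str > 0, a_h_str < 1)
  if (!(omega_N_tum < omega_H_tum && omega_N_str < omega_H_str)) {
    stop("necrosis thresholds must lie below hypoxia thresholds", call. = FALSE)
  }
  if (p_star * dt > 1) {
    stop(sprintf("p_star * dt = %g exceeds 1: extravasation probability overflows",
                 p_star * dt), call. = FALSE)
  }
  if (field_spacing > r_int) {
    stop("field_spacing must not exceed r_int (grid must resolve interactions)",
         call. = FALSE)
  }
  stopifnot(is_pp_domain(domain))
  structure(p, class = "abm_params")
}

#' @export
print.abm_params <- function(x, ...) {
  cat(sprintf(
    "ABM parameters: %g x %g domain, dt = %g h, %d vessels\n",
    domain_width(x$domain), domain_height(x$domain), x$dt, x$n_vessels))
  cat(sprintf("  chi_c_m = %g, c_half = %g, chi_xi_m = %g, chi_eps_t = %g\n",
              x$chi_c_m, x$c_half, x$chi_xi_m, x$chi_eps_t))
  cat(sprintf("  p_star = %g/h, p_phi_star = %g/h, delta_p = %g/h, g_crit = %g\n",
              x$p_star, x$p_phi_star, x$delta_p, x$g_crit))
  invisible(x)
}
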