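# Build a bare ABM state with explicit cells/vessels/field levels, bypassing
# abm_init, so individual operations can be probed in isolation.
make_test_state <- function(params,
                            cell_x = numeric(), cell_y = numeric(),
                            cell_type = integer(), phen = numeric(),
                            ktimer = numeric(),
                            vessel_x = numeric(), vessel_y = numeric(),
                            oxygen = 1, csf1 = 0, cxcl12 = 0, tgfb = 0,
                            egf = 0) {
  n <- length(cell_x)
  phen_full <- rep(NA_real_, n)
  is_mac <- cell_type == 4L
  phen_full[is_mac] <- if (length(phen) > 0) phen else 0
  cl <- list(x = cell_x, y = cell_y, type = as.integer(cell_type),
             clock = numeric(n),
             cdur = rep(params$cycle_duration, n),
             phen = phen_full,
             ktimer = if (length(ktimer) > 0) ktimer else
               rep(params$t_cool, n),
             nclock = numeric(n))
  d <- params$domain
  mk <- function(name, D, lam, init) {
    f <- new_field(name, D, lam, d, params$field_spacing, init = init)
    f
  }
  fields <- list(
    oxygen = mk("oxygen", params$D_omega, params$lambda_omega, oxygen),
    csf1 = mk("csf1", params$D_csf1, params$lambda_csf1, csf1),
    cxcl12 = mk("cxcl12", params$D_cxcl12, params$lambda_cxcl12, cxcl12),
    tgfb = mk("tgfb", params$D_tgfb, params$lambda_tgfb, tgfb),
    egf = mk("egf", params$D_egf, params$lambda_egf, egf)
  )
  list(time = 0, cells = cl, vessels = list(x = vessel_x, y = vessel_y),
       fields = fields, params = params, dmin = rep(Inf, n))
}

# Small, fast parameter set for whole-simulation tests.
small_abm_params <- function(...) {
  abm_params(domain = pp_domain(0, 20, 0, 20), n_vessels = 5,
             vessel_exclusion = 6, vessel_min_sep = 3, n_tumour_init = 10,
             burn_in = 1, ...)
}
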