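CELL_STROMAL <- 1L
CELL_TUMOUR <- 2L
CELL_NECROTIC <- 3L
CELL_MACRO <- 4L
CELL_TYPE_LABEL <- c("S", "T", "N", "M")

# Cells are stored as parallel vectors for speed; this builds the record.
new_cells <- function(x = numeric(), y = numeric(), type = integer(),
                      clock = numeric(), cdur = numeric(),
                      phen = numeric(), ktimer = numeric(),
                      nclock = numeric()) {
  list(x = x, y = y, type = type, clock = clock, cdur = cdur,
       phen = phen, ktimer = ktimer, nclock = nclock)
}

cells_bind <- function(a, b) {
  mapply(c, a, b, SIMPLIFY = FALSE)
}

cells_keep <- function(cl, keep) {
  lapply(cl, function(v) v[keep])
}

n_cells <- function(cl) length(cl$x)

# Per-cell current radius: necrotic cells shrink linearly to zero.
cell_radii <- function(state) {
  p <- state$params
  r <- rep(p$cell_radius, n_cells(state$cells))
  nec <- state$cells$type == CELL_NECROTIC
  if (any(nec)) {
    frac <- pmax(0, 1 - state$cells$nclock[nec] / p$necrosis_clear_time)
    r[nec] <- p$cell_radius * frac
  }
  r
}

# Draw a per-cell cycle duration: uniform within 25% of the mean, which
# desynchronises divisions.
draw_cycle_duration <- function(n, mean_dur) {
  stats::runif(n, 0.75 * mean_dur, 1.25 * mean_dur)
}

#' Initialise an ABM state
#'
#' Builds the initial tissue: vessels placed uniformly at random with a
#' minimum pairwise separation and a vessel-free disc around the domain
#' centre, a hexagonally packed tumour disc of `n_tumour_init` cells at the
#' centre, stroma on a jittered square lattice elsewhere, oxygen initialised
#' at `omega_init` and the signalling fields at zero. The fields then
#' equilibrate for `burn_in` hours with the initial sources (so CSF-1
#' gradients exist when the simulation proper starts).
#'
#' @param params An [abm_params()].
#' @param seed RNG seed (the subsequent trajectory is reproducible given the
#'   same seed and parameters).
#' @return An ABM state: a list with `time`, `cells`, `vessels`, `fields`,
#'   `params` and bookkeeping fields.
#' @export
abm_init <- function(params, seed = 1) {
  stopifnot(inherits(params, "abm_params"))
  with_seed(seed, abm_init_impl(params))
}

abm_init_impl <- function(p) {
  d <- p$domain
  cx <- (d$xmin + d$xmax) / 2
  cy <- (d$ymin + d$ymax) / 2

  # vessels: rejection sampling with min separation + central exclusion
  vx <- numeric(0); vy <- numeric(0)
  tries <- 0
  while (length(vx) < p$n_vessels && tries < 100000) {
    tries <- tries + 1
    x <- stats::runif(1, d$xmin + 1, d$xmax - 1)
    y <- stats::runif(1, d$ymin + 1, d$ymax - 1)
    if (sqrt((x - cx)^2 + (y - cy)^2) < p$vessel_exclusion) next
    if (length(vx) > 0 &&
        min(sqrt((vx - x)^2 + (vy - y)^2)) < p$vessel_min_sep) next
    vx <- c(vx, x); vy <- c(vy, y)
  }
  if (length(vx) < p$n_vessels) {
    stop("could not place vessels: relax vessel_min_sep or vessel_exclusion",
         call. = FALSE)
  }

  # tumour disc: hexagonal packing, n_tumour_init nodes nearest the centre
  s <- 0.95  # packing spacing slightly under one diameter
  reach <- ceiling(sqrt(p$n_tumour_init)) + 2
  ij <- expand.grid(i = -reach:reach, j = -reach:reach)
  tx <- cx + s * (ij$i + 0.5 * (ij$j %% 2))
  ty <- cy + s * ij$j * sqrt(3) / 2
  ord <- order((tx - cx)^2 + (ty - cy)^2)
  tx <- tx[ord[seq_len(p$n_tumour_init)]]
  ty <- ty[ord[seq_len(p$n_tumour_init)]]
  tumour_r <- max(sqrt((tx - cx)^2 + (ty - cy)^2))

  # stroma: jittered lattice outside the tumour disc
  gx <- seq(d$xmin + p$stroma_spacing / 2, d$xmax - p$stroma_spacing / 2,
            by = p$stroma_spacing)
  gy <- seq(d$ymin + p$stroma_spacing / 2, d$ymax - p$stroma_spacing / 2,
            by = p$stroma_spacing)
  g <- expand.grid(x = gx, y = gy)
  g$x <- g$x + stats::runif(nrow(g), -0.1, 0.1)
  g$y <- g$y + stats::runif(nrow(g), -0.1, 0.1)
  far <- sqrt((g$x - cx)^2 + (g$y - cy)^2) > tumour_r + 1
  g <- g[far, ]

  ns <- nrow(g)
  nt <- length(tx)
  cl <- new_cells(
    x = c(g$x, tx), y = c(g$y, ty),
    type = c(rep(CELL_STROMAL, ns), rep(CELL_TUMOUR, nt)),
    clock = numeric(ns + nt), cdur = draw_cycle_duration(ns + nt,
                                                         p$cycle_duration),
    phen = rep(NA_real_, ns + nt),
    ktimer = numeric(ns + nt), nclock = numeric(ns + nt)
  )
  cl$clock <- stats::runif(ns + nt, 0, cl$cdur)

  fields <- list(
    oxygen = new_field("oxygen", p$D_omega, p$lambda_omega, d,
                       p$field_spacing, init = p$omega_init),
    csf1 = new_field("csf1", p$D_csf1, p$lambda_csf1, d, p$field_spacing),
    cxcl12 = new_field("cxcl12", p$D_cxcl12, p$lambda_cxcl12, d,
                       p$field_spacing),
    tgfb = new_field("tgfb", p$D_tgfb, p$lambda_tgfb, d, p$field_spacing),
    egf = new_field("egf", p$D_egf, p$lambda_egf, d, p$field_spacing)
  )

  state <- list(time = 0, cells = cl,
                vessels = list(x = vx, y = vy),
                fields = fields, params = p,
                dmin = rep(Inf, ns + nt))
  if (p$burn_in > 0) state <- update_fields(state, dt = p$burn_in)
  state
}

#' Macrophage extravasation probability
#'
#' Probability per hour that a macrophage enters at a vessel, an increasing,
#' saturating function of the local CSF-1 concentration:
#' `p_star * c / (c + c_half)`. It is half-maximal at `c = c_half`.
#'
#' @param c_local CSF-1 concentration(s), >= 0.
#' @param params An [abm_params()].
#' @return Probability per hour in `[0, p_star]`.
#' @export
extravasation_probability <- function(c_local, params) {
  stopifnot(all(c_local >= 0))
  params$p_star * c_local / (c_local + params$c_half)
}

#' Attempt macrophage extravasation at each vessel
#'
#' Each vessel admits a new macrophage with probability
#' `extravasation_probability(c) * dt`, where `c` is the CSF-1 level at the
#' vessel. New macrophages appear adjacent to their vessel with phenotype
#' `p = 0` (fully anti-tumour) and their kill timer expired (eligible to
#' kill immediately).
#'
#' @param state ABM state.
#' @param dt Timestep in hours; `dt * p_star` must not exceed 1.
#' @return Updated state.
#' @export
attempt_extravasation <- function(state, dt = state$params$dt) {
  p <- state$params
  if (dt * p$p_star > 1) {
    stop("dt * p_star > 1: extravasation probability overflows", call. = FALSE)
  }
  c_v <- field_at(state$fields$csf1, p$domain, state$vessels$x,
                  state$vessels$y)
  prob <- extravasation_probability(c_v, p) * dt
  fire <- stats::runif(length(prob)) < prob
  if (any(fire)) {
    ang <- stats::runif(sum(fire), 0, 2 * pi)
    nx <- state$vessels$x[fire] + cos(ang) * 2 * p$cell_radius
    ny <- state$vessels$y[fire] + sin(ang) * 2 * p$cell_radius
    nx <- pmin(pmax(nx, p$domain$xmin + 1e-6), p$domain$xmax - 1e-6)
    ny <- pmin(pmax(ny, p$domain$ymin + 1e-6), p$domain$ymax - 1e-6)
    k <- sum(fire)
    state$cells <- cells_bind(state$cells, new_cells(
      x = nx, y = ny, type = rep(CELL_MACRO, k),
      clock = numeric(k), cdur = rep(Inf, k),
      phen = numeric(k), ktimer = rep(p$t_cool, k), nclock = numeric(k)
    ))
    state$dmin <- c(state$dmin, rep(Inf, k))
  }
  state
}

#' Advance macrophage phenotypes
#'
#' Macrophages whose local TGF-beta exceeds `g_crit` and whose phenotype is
#' below 1 gain `delta_p * dt`, capped at 1; all others are unchanged.
#' Phenotype never decreases, and once a macrophage reaches `p = 1` it stays
#' fully M2.
#'
#' @param state ABM state.
#' @param dt Timestep in hours.
#' @return Updated state.
#' @export
update_phenotypes <- function(state, dt = state$params$dt) {
  p <- state$params
  mac <- which(state$cells$type == CELL_MACRO)
  if (length(mac) == 0) return(state)
  g <- field_at(state$fields$tgfb, p$domain, state$cells$x[mac],
                state$cells$y[mac])
  adv <- g > p$g_crit & state$cells$phen[mac] < 1
  state$cells$phen[mac[adv]] <-
    pmin(1, state$cells$phen[mac[adv]] + p$delta_p * dt)
  state
}

#' Macrophage kill probability
#'
#' Probability per hour that a macrophage kills an adjacent tumour cell: a
#' steep, monotone-decreasing Hill function of phenotype,
#' `p_phi_star * (1 - p^10 / (p^10 + 0.5^10))`, so anti-tumour (M1,
#' `p = 0`) macrophages kill at the maximal rate, the rate halves at
#' `p = 0.5`, and fully M2 macrophages barely kill. During the post-kill
#' cooldown (`t_phi < t_cool`) the probability is exactly 0.
#'
#' @param p Phenotype(s) in `[0, 1]`.
#' @param t_phi Time since last kill (hours).
#' @param params An [abm_params()].
#' @return Probability per hour in `[0, p_phi_star]`.
#' @export
kill_probability <- function(p, t_phi, params) {
  stopifnot(all(p >= 0 & p <= 1), all(t_phi >= 0))
  base <- params$p_phi_star * (1 - p^10 / (p^10 + 0.5^10))
  ifelse(t_phi >= params$t_cool, base, 0)
}

#' Attempt macrophage killing of tumour cells
#'
#' Each macrophage whose cooldown has expired fires with probability
#' `kill_probability(p, t_phi) * dt`; if it fires and at least one tumour
#' cell lies within the interaction radius, one of those tumour cells is
#' selected uniformly at random, becomes necrotic, and the macrophage's kill
#' timer resets to 0. A macrophage kills at most one cell per event, and a
#' tumour cell already killed this step cannot be killed again.
#'
#' @param state ABM state.
#' @param dt Timestep in hours.
#' @return Updated state.
#' @export
attempt_killing <- function(state, dt = state$params$dt) {
  p <- state$params
  cl <- state$cells
  mac <- which(cl$type == CELL_MACRO)
  tum <- which(cl$type == CELL_TUMOUR)
  if (length(mac) == 0 || length(tum) == 0) return(state)
  prob <- kill_probability(cl$phen[mac], cl$ktimer[mac], p) * dt
  fire <- which(stats::runif(length(mac)) < pmin(prob, 1))
  if (length(fire) == 0) return(state)
  shooters <- mac[fire]
  cand <- points_within(cl$x[shooters], cl$y[shooters],
                        cl$x[tum], cl$y[tum], p$r_int)
  killed <- logical(length(tum))
  for (s in seq_along(shooters)) {
    opts <- cand[[s]]
    opts <- opts[!killed[opts]]
    if (length(opts) == 0) next
    pick <- if (length(opts) == 1) opts else opts[sample.int(length(opts), 1)]
    killed[pick] <- TRUE
    state$cells$ktimer[shooters[s]] <- 0
  }
  if (any(killed)) {
    idx <- tum[killed]
    state$cells$type[idx] <- CELL_NECROTIC
    state$cells$nclock[idx] <- 0
  }
  state
}

#' Chemotactic force on a macrophage
#'
#' The CSF-1 term has magnitude `chi_c_m * (1 - p)` along the unit CSF-1
#' gradient (anti-tumour macrophages chase tumour-derived CSF-1) and the
#' CXCL12 term has magnitude `chi_xi_m * p` along the unit CXCL12 gradient
#' (pro-tumour macrophages home to perivascular CXCL12). A gradient whose
#' magnitude falls below `grad_tol` contributes zero force (the direction of
#' a vanishing gradient is undefined).
#'
#' @param p Macrophage phenotype in `[0, 1]`.
#' @param grad_c,grad_xi Length-2 gradient vectors of CSF-1 and CXCL12.
#' @param params An [abm_params()].
#' @return Length-2 force vector.
#' @export
chemotactic_force <- function(p, grad_c, grad_xi, params) {
  unit <- function(g) {
    n <- sqrt(sum(g^2))
    if (n < params$grad_tol) c(0, 0) else g / n
  }
  params$chi_c_m * (1 - p) * unit(grad_c) + params$chi_xi_m * p * unit(grad_xi)
}

# Vectorised unit-gradient helper: rows below the tolerance give zero rows.
unit_rows <- function(g, tol) {
  n <- sqrt(rowSums(g^2))
  out <- g / ifelse(n < tol, Inf, n)
  out
}

#' Pairwise mechanical (spring) forces
#'
#' The deterministic cell-cell interaction forces: linear springs between
#' cells whose centres are within `r_int`, repulsive below the rest length
#' (sum of radii), attractive between rest length and cutoff. Necrotic cells
#' interact with forces scaled by their shrinking radius. Vessels exert and
#' receive no mechanical force. Pair forces are equal and opposite, so the
#' columns of the result sum to zero.
#'
#' @param state ABM state.
#' @return An `n_cells` x 2 matrix of forces; the nearest-neighbour distance
#'   per cell is attached as attribute `"dmin"`.
#' @export
mechanical_forces <- function(state) {
  p <- state$params
  cl <- state$cells
  n <- n_cells(cl)
  if (n == 0) {
    out <- matrix(0, 0, 2)
    attr(out, "dmin") <- numeric(0)
    return(out)
  }
  radius <- cell_radii(state)
  scale <- rep(1, n)
  nec <- cl$type == CELL_NECROTIC
  scale[nec] <- radius[nec] / p$cell_radius
  f <- pair_spring_forces(cl$x, cl$y, radius, scale, p$spring_k,
                          p$spring_adhesion, p$r_int,
                          p$domain$xmin, p$domain$xmax,
                          p$domain$ymin, p$domain$ymax, FALSE)
  out <- cbind(f$fx, f$fy)
  attr(out, "dmin") <- f$dmin
  out
}

#' Advance cell cycles, hypoxia, necrosis and division
#'
#' Stromal and tumour cells progress their cycle clock only while the local
#' oxygen exceeds their hypoxic threshold (the pause is reversible); stromal
#' cells additionally pause when mechanically compressed below the
#' contact-inhibition area fraction. Oxygen below the necrosis threshold
#' irreversibly converts a cell to necrotic. A clock reaching the cell's
#' cycle duration triggers division: the daughter is placed at a small
#' random offset and both clocks restart. Necrotic cells shrink linearly
#' and are removed once fully degraded. Macrophages never divide.
#'
#' @param state ABM state.
#' @param dt Timestep in hours.
#' @return Updated state.
#' @export
update_cell_cycle <- function(state, dt = state$params$dt) {
  p <- state$params
  cl <- state$cells
  n <- n_cells(cl)
  if (n == 0) return(state)
  live <- cl$type %in% c(CELL_STROMAL, CELL_TUMOUR)
  if (any(live)) {
    om <- field_at(state$fields$oxygen, p$domain, cl$x[live], cl$y[live])
    idx <- which(live)
    is_t <- cl$type[idx] == CELL_TUMOUR
    omega_n <- rep(p$omega_N_str, length(idx)); omega_n[is_t] <- p$omega_N_tum
    omega_h <- rep(p$omega_H_str, length(idx)); omega_h[is_t] <- p$omega_H_tum
    gone <- om < omega_n
    if (any(gone)) {
      g <- idx[gone]
      cl$type[g] <- CELL_NECROTIC
      cl$nclock[g] <- 0
    }
    # compressed stromal cells pause: effective radius from the nearest
    # neighbour (half the separation, capped at the relaxed radius)
    dmin <- state$dmin
    r_eff <- pmin(dmin[idx] / 2, p$cell_radius)
    squeezed <- !is_t & (r_eff^2 / p$cell_radius^2) < p$a_h_str
    run <- !gone & om > omega_h & !squeezed
    adv <- idx[run]
    cl$clock[adv] <- cl$clock[adv] + dt
    div <- adv[cl$clock[adv] >= cl$cdur[adv]]
    if (length(div) > 0 && n + length(div) <= p$max_cells) {
      ang <- stats::runif(length(div), 0, 2 * pi)
      dx <- cos(ang) * p$division_offset
      dy <- sin(ang) * p$division_offset
      nx <- pmin(pmax(cl$x[div] + dx, p$domain$xmin + 1e-6), p$domain$xmax - 1e-6)
      ny <- pmin(pmax(cl$y[div] + dy, p$domain$ymin + 1e-6), p$domain$ymax - 1e-6)
      k <- length(div)
      cl$clock[div] <- 0
      cl$cdur[div] <- draw_cycle_duration(k, p$cycle_duration)
      daughters <- new_cells(
        x = nx, y = ny, type = cl$type[div],
        clock = numeric(k), cdur = draw_cycle_duration(k, p$cycle_duration),
        phen = rep(NA_real_, k), ktimer = numeric(k), nclock = numeric(k)
      )
      cl <- cells_bind(cl, daughters)
      state$dmin <- c(state$dmin, rep(Inf, k))
    }
  }
  nec <- which(cl$type == CELL_NECROTIC)
  if (length(nec) > 0) {
    cl$nclock[nec] <- cl$nclock[nec] + dt
    drop <- nec[cl$nclock[nec] >= p$necrosis_clear_time]
    if (length(drop) > 0) {
      keep <- rep(TRUE, n_cells(cl))
      keep[drop] <- FALSE
      cl <- cells_keep(cl, keep)
      state$dmin <- state$dmin[keep]
    }
  }
  state$cells <- cl
  state
}

#' One ABM timestep
#'
#' Applies, in order: field updates, macrophage extravasation, phenotype
#' progression, killing attempts, cell-cycle/necrosis bookkeeping, then the
#' overdamped position update `x += F dt / nu` with the net force combining
#' pairwise springs, macrophage chemotaxis (CSF-1 and CXCL12) and random
#' motility, and tumour-cell chemotaxis up EGF. Kill timers advance by `dt`.
#' The trajectory is reproducible given the seed used at initialisation.
#'
#' @param state ABM state.
#' @param params An [abm_params()] (defaults to the state's own).
#' @return The state advanced by one timestep.
#' @export
abm_step <- function(state, params = state$params) {
  p <- params
  state$params <- p
  dt <- p$dt
  state <- update_fields(state, dt)
  state <- attempt_extravasation(state, dt)
  state <- update_phenotypes(state, dt)
  mac0 <- state$cells$type == CELL_MACRO
  state$cells$ktimer[mac0] <- state$cells$ktimer[mac0] + dt
  state <- attempt_killing(state, dt)
  state <- update_cell_cycle(state, dt)

  cl <- state$cells
  n <- n_cells(cl)
  if (n > 0) {
    # active (non-spring) forces are held fixed over the step ...
    fa <- matrix(0, n, 2)
    mac <- which(cl$type == CELL_MACRO)
    if (length(mac) > 0) {
      gc_ <- field_gradient_at(state$fields$csf1, p$domain, cl$x[mac], cl$y[mac])
      gx_ <- field_gradient_at(state$fields$cxcl12, p$domain, cl$x[mac], cl$y[mac])
      phen <- cl$phen[mac]
      chem <- p$chi_c_m * (1 - phen) * unit_rows(gc_, p$grad_tol) +
        p$chi_xi_m * phen * unit_rows(gx_, p$grad_tol)
      ang <- stats::runif(length(mac), 0, 2 * pi)
      fa[mac, ] <- chem + p$random_motility * cbind(cos(ang), sin(ang))
    }
    tum <- which(cl$type == CELL_TUMOUR)
    if (length(tum) > 0 && p$chi_eps_t > 0) {
      ge <- field_gradient_at(state$fields$egf, p$domain, cl$x[tum], cl$y[tum])
      fa[tum, ] <- p$chi_eps_t * unit_rows(ge, p$egf_grad_tol)
    }
    # ... while the stiff spring forces are integrated with sub-steps (in
    # one fused kernel call), so crowded regions relax smoothly instead of
    # overshooting
    radius <- cell_radii(state)
    scale <- rep(1, n)
    nec <- cl$type == CELL_NECROTIC
    scale[nec] <- radius[nec] / p$cell_radius
    res <- integrate_positions(cl$x, cl$y, radius, scale,
                               fa[, 1], fa[, 2],
                               p$spring_k, p$spring_adhesion, p$r_int,
                               p$domain$xmin, p$domain$xmax,
                               p$domain$ymin, p$domain$ymax,
                               p$nu, dt, p$mech_substeps)
    if (res$max_disp > 1) {
      stop(sprintf(
        "instability: a cell moved %.2f diameters in one sub-step; reduce dt below %g",
        res$max_disp, dt / res$max_disp), call. = FALSE)
    }
    state$cells$x <- res$x
    state$cells$y <- res$y
    state$dmin <- res$dmin
  }
  state$time <- state$time + dt
  state
}

#' Export an ABM state as a labelled point cloud
#'
#' Vessels become category `B`; stromal, tumour, necrotic and macrophage
#' cells become `S`, `T`, `N`, `M`. Macrophage phenotypes are carried as the
#' continuous mark; all other points have no mark. The snapshot is tagged
#' with the simulation time.
#'
#' @param state ABM state.
#' @return A [point_cloud()].
#' @export
as_point_cloud <- function(state) {
  cl <- state$cells
  v <- state$vessels
  nv <- length(v$x)
  point_cloud(
    x = c(v$x, cl$x), y = c(v$y, cl$y),
    category = c(rep("B", nv), CELL_TYPE_LABEL[cl$type]),
    mark = c(rep(NA_real_, nv), cl$phen),
    domain = state$params$domain,
    time = state$time
  )
}

#' Run the ABM and collect snapshots
#'
#' Initialises a state from `params` and `seed`, advances it to `t_end`, and
#' records a labelled point cloud every `snapshot_every` hours (including
#' the initial state at `t = 0` and the final state at `t_end`).
#'
#' @param params An [abm_params()].
#' @param t_end End time in hours.
#' @param snapshot_every Snapshot cadence in hours (a multiple of `dt`).
#' @param seed RNG seed; identical `(seed, params)` give identical output.
#' @param keep_state Attach the final state as attribute `"state"`.
#' @return A list of [point_cloud()] snapshots, oldest first.
#' @export
abm_run <- function(params, t_end, snapshot_every = 10, seed = 1,
                    keep_state = FALSE) {
  stopifnot(inherits(params, "abm_params"), t_end >= 0)
  steps_per_snap <- snapshot_every / params$dt
  if (abs(steps_per_snap - round(steps_per_snap)) > 1e-8) {
    stop("snapshot_every must be a multiple of dt", call. = FALSE)
  }
  steps_per_snap <- round(steps_per_snap)
  n_steps <- round(t_end / params$dt)
  with_seed(seed, {
    state <- abm_init_impl(params)
    snaps <- list(as_point_cloud(state))
    if (n_steps > 0) {
      for (s in seq_len(n_steps)) {
        state <- abm_step(state)
        if (s %% steps_per_snap == 0 || s == n_steps) {
          if (abs(state$time - snaps[[length(snaps)]]$time) > 1e-9) {
            snaps[[length(snaps) + 1]] <- as_point_cloud(state)
          }
        }
      }
    }
    if (keep_state) attr(snaps, "state") <- state
    snaps
  })
}
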