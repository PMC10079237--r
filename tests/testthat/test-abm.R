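test_that("extravasation probability saturates with half-maximum at c_half", {
  pr <- abm_params(p_star = 0.4, c_half = 0.3)
  expect_equal(extravasation_probability(0.3, pr), 0.2)
  expect_equal(extravasation_probability(0, pr), 0)
  expect_equal(extravasation_probability(1e9, pr), 0.4, tolerance = 1e-8)
  c_seq <- seq(0, 2, 0.1)
  expect_true(all(diff(extravasation_probability(c_seq, pr)) > 0))
})

test_that("kill probability follows the phenotype Hill curve and cooldown", {
  pr <- abm_params(p_phi_star = 2, t_cool = 3)
  expect_equal(kill_probability(0, 3, pr), 2)
  expect_equal(kill_probability(0.5, 3, pr), 1)   # p^10 halves at p = 0.5
  expect_equal(kill_probability(0, 2.9, pr), 0)   # cooling down
  expect_equal(kill_probability(1, 10, pr), 2 * (1 - 1 / (1 + 2^-10)))
  p_seq <- seq(0, 1, 0.05)
  expect_true(all(diff(kill_probability(p_seq, 99, pr)) <= 0))
})

test_that("chemotactic force interpolates linearly between the two cues", {
  pr <- abm_params(chi_c_m = 3, chi_xi_m = 2)
  up <- c(0, 1)
  right <- c(1, 0)
  expect_equal(chemotactic_force(0, up, right, pr), c(0, 3))
  expect_equal(chemotactic_force(1, up, right, pr), c(2, 0))
  f <- chemotactic_force(0.5, c(5, 0), c(3, 0), pr)  # magnitudes, not raw
  expect_equal(f, c((3 + 2) / 2, 0))
  # zero gradient contributes nothing
  expect_equal(chemotactic_force(0.5, c(0, 0), c(0, 0), pr), c(0, 0))
})

test_that("phenotype advances only above g_crit, ramps in 1/delta_p hours, and caps", {
  pr <- abm_params(delta_p = 0.1, g_crit = 0.3, dt = 0.5)
  st <- make_test_state(pr, cell_x = 10, cell_y = 10, cell_type = 4L,
                        tgfb = 0.2)
  st2 <- update_phenotypes(st, dt = 0.5)
  expect_equal(st2$cells$phen, 0)  # below threshold: unchanged

  st$fields$tgfb$m[] <- 1
  hours <- 0
  while (st$cells$phen < 1 && hours < 20) {
    st <- update_phenotypes(st, dt = 0.5)
    hours <- hours + 0.5
  }
  expect_equal(hours, 1 / pr$delta_p, tolerance = 0.5 / (1 / pr$delta_p))
  st3 <- update_phenotypes(st, dt = 0.5)
  expect_equal(st3$cells$phen, 1)  # capped, stays fully M2
})

test_that("extravasation produces p = 0 macrophages at the binomial rate", {
  pr <- abm_params(p_star = 0.5, c_half = 0.2, dt = 0.5)
  # zero CSF-1: no entries ever
  st0 <- make_test_state(pr, vessel_x = c(5, 10, 15), vessel_y = c(5, 10, 15),
                         csf1 = 0)
  for (i in 1:20) st0 <- attempt_extravasation(st0, dt = 0.5)
  expect_equal(n_cells(st0$cells), 0)

  # saturating CSF-1: expected entries ~ n_vessels * p_star * T
  n_entries <- with_seed_test(314, {
    vapply(1:200, function(r) {
      st <- make_test_state(pr, vessel_x = c(5, 10, 15),
                            vessel_y = c(5, 10, 15), csf1 = 1000)
      for (i in 1:10) st <- attempt_extravasation(st, dt = 0.5)  # 5 hours
      n_cells(st$cells)
    }, numeric(1))
  })
  expected <- 3 * pr$p_star * 5  # 30 vessel-steps at probability 0.25 each
  se <- sqrt(30 * 0.25 * 0.75 / 200)
  expect_lt(abs(mean(n_entries) - expected), 3 * se)
  # every newborn macrophage is fully anti-tumour and ready to kill
  st <- with_seed_test(99, {
    s <- make_test_state(pr, vessel_x = 10, vessel_y = 10, csf1 = 1000)
    for (i in 1:40) s <- attempt_extravasation(s, dt = 0.5)
    s
  })
  expect_gt(n_cells(st$cells), 0)
  expect_true(all(st$cells$phen == 0))
  expect_true(all(st$cells$ktimer >= pr$t_cool))
  expect_error(attempt_extravasation(st, dt = 3), "overflows")
})

test_that("killing requires contact, resets the timer, and picks targets uniformly", {
  pr <- abm_params(p_phi_star = 1 / 0.05, t_cool = 2, dt = 0.05)
  # certain kill: p_phi_star * dt = 1, adjacent tumour cell
  st <- make_test_state(pr, cell_x = c(10, 10.8), cell_y = c(10, 10),
                        cell_type = c(4L, 2L), ktimer = c(5, 0))
  st2 <- with_seed_test(1, attempt_killing(st, dt = 0.05))
  expect_equal(st2$cells$type[2], 3L)       # tumour became necrotic
  expect_equal(st2$cells$ktimer[1], 0)      # cooldown restarted

  # no tumour cell within reach: nothing happens
  far <- make_test_state(pr, cell_x = c(10, 15), cell_y = c(10, 10),
                         cell_type = c(4L, 2L), ktimer = c(5, 0))
  far2 <- with_seed_test(1, attempt_killing(far, dt = 0.05))
  expect_equal(far2$cells$type[2], 2L)

  # three candidates in reach are chosen about equally often
  picks <- with_seed_test(2024, {
    vapply(1:600, function(r) {
      s <- make_test_state(pr, cell_x = c(10, 10.9, 9.1, 10),
                           cell_y = c(10, 10, 10, 10.9),
                           cell_type = c(4L, 2L, 2L, 2L), ktimer = c(5, 0, 0, 0))
      s <- attempt_killing(s, dt = 0.05)
      which(s$cells$type == 3L)
    }, integer(1))
  })
  freq <- table(picks) / length(picks)
  expect_true(all(abs(freq - 1 / 3) < 0.06))
})

test_that("spring forces vanish at rest length, obey the third law, and relax overlaps", {
  pr <- abm_params()
  # exactly at rest length (two relaxed radii): no force
  st <- make_test_state(pr, cell_x = c(5, 6), cell_y = c(5, 5),
                        cell_type = c(1L, 1L))
  f <- mechanical_forces(st)
  expect_equal(unclass(f), matrix(0, 2, 2), ignore_attr = TRUE)

  # random crowded cluster: pair forces cancel in the aggregate
  st2 <- with_seed_test(8, make_test_state(
    pr, cell_x = runif(40, 9, 12), cell_y = runif(40, 9, 12),
    cell_type = rep(1L, 40)))
  f2 <- mechanical_forces(st2)
  expect_equal(colSums(f2), c(0, 0), tolerance = 1e-10)

  # two overlapping cells relax towards rest length like the linear-spring ODE
  x <- c(10, 10.5)
  dt <- 0.001
  for (i in 1:1000) {
    sti <- make_test_state(pr, cell_x = x, cell_y = c(5, 5),
                           cell_type = c(1L, 1L))
    fi <- mechanical_forces(sti)
    x <- x + fi[, 1] * dt / pr$nu
  }
  # ds/dt = -2 k (s - rest) / nu  =>  s(t) = rest - (rest - s0) e^(-2kt/nu)
  s_exact <- 1 - (1 - 0.5) * exp(-2 * pr$spring_k * 1 / pr$nu)
  expect_equal(x[2] - x[1], s_exact, tolerance = 0.01)
})

test_that("a source-free uniform field decays exponentially to high precision", {
  pr <- abm_params()
  st <- make_test_state(pr, egf = 2)
  for (i in 1:40) st <- update_fields(st, dt = 0.25)  # 10 hours
  expected <- 2 * exp(-pr$lambda_egf * 10)
  expect_lt(max(abs(st$fields$egf$m - expected)) / expected, 1e-6)
})

test_that("field mass obeys the per-step source/decay budget and stays non-negative", {
  pr <- abm_params(kappa_egf = 2)
  st <- make_test_state(pr, cell_x = 10.2, cell_y = 9.7, cell_type = 4L,
                        phen = 1, egf = 0.1)
  h2 <- pr$field_spacing^2
  for (i in 1:20) {
    m0 <- sum(st$fields$egf$m) * h2
    st <- update_fields(st, dt = pr$dt)
    m1 <- sum(st$fields$egf$m) * h2
    dm_expected <- (pr$kappa_egf * 1 - pr$lambda_egf * m0) * pr$dt
    expect_equal(m1 - m0, dm_expected, tolerance = 0.02 * max(abs(dm_expected), 1e-3))
    expect_true(all(st$fields$egf$m >= 0))
  }
})

test_that("cell cycle pauses reversibly under hypoxia and necrosis is irreversible", {
  pr <- abm_params()
  mid <- (pr$omega_N_tum + pr$omega_H_tum) / 2
  st <- make_test_state(pr, cell_x = 10, cell_y = 10, cell_type = 2L,
                        oxygen = mid)
  st$cells$clock <- 1
  st2 <- update_cell_cycle(st, dt = 0.5)
  expect_equal(st2$cells$clock, 1)          # frozen between the thresholds
  expect_equal(st2$cells$type, 2L)
  st2$fields$oxygen$m[] <- 1
  st3 <- update_cell_cycle(st2, dt = 0.5)
  expect_equal(st3$cells$clock, 1.5)        # resumed after reoxygenation

  # necrosis below the lower threshold, irreversible even if oxygen returns
  st4 <- make_test_state(pr, cell_x = 10, cell_y = 10, cell_type = 2L,
                         oxygen = pr$omega_N_tum / 2)
  st5 <- update_cell_cycle(st4, dt = 0.5)
  expect_equal(st5$cells$type, 3L)
  st5$fields$oxygen$m[] <- 1
  st6 <- update_cell_cycle(st5, dt = 0.5)
  expect_equal(st6$cells$type, 3L)

  # necrotic cells shrink linearly and are removed at the end
  st6$cells$nclock <- pr$necrosis_clear_time / 2
  expect_equal(cell_radii(st6), pr$cell_radius / 2)
  st7 <- update_cell_cycle(st6, dt = pr$necrosis_clear_time / 2 + 0.5)
  expect_equal(n_cells(st7$cells), 0)
})

test_that("an oxygen-rich isolated tumour cell divides once per cycle", {
  pr <- abm_params()
  st <- make_test_state(pr, cell_x = 10, cell_y = 10, cell_type = 2L,
                        oxygen = 1)
  st$cells$cdur <- 20
  n_steps <- round(20 / 0.5)
  st <- with_seed_test(7, {
    for (i in seq_len(n_steps)) st <- update_cell_cycle(st, dt = 0.5)
    st
  })
  expect_equal(n_cells(st$cells), 2)  # exactly one division after one cycle
  expect_true(all(st$cells$clock < 20))
})

test_that("macrophage phenotypes never decrease over a running simulation", {
  pr <- small_abm_params(p_star = 1e-9)  # no new entries: stable indexing
  st <- abm_init(pr, seed = 2)
  n0 <- n_cells(st$cells)
  st$cells <- cells_bind(st$cells, new_cells(
    x = runif(10, 6, 14), y = runif(10, 6, 14), type = rep(4L, 10),
    clock = numeric(10), cdur = rep(Inf, 10), phen = runif(10, 0, 0.4),
    ktimer = rep(pr$t_cool, 10), nclock = numeric(10)))
  st$dmin <- c(st$dmin, rep(Inf, 10))
  st$fields$tgfb$m[] <- 1  # force the transition on
  prev <- st$cells$phen[st$cells$type == 4L]
  ok <- TRUE
  for (i in 1:30) {
    st <- abm_step(st)
    cur <- st$cells$phen[st$cells$type == 4L]
    if (length(cur) == length(prev)) ok <- ok && all(cur >= prev - 1e-12)
    prev <- cur
    for (f in st$fields) ok <- ok && all(f$m >= 0)
  }
  expect_true(ok)
})

test_that("simulations are deterministic per seed and sensitive to it", {
  pr <- small_abm_params()
  a <- abm_run(pr, t_end = 2, snapshot_every = 1, seed = 42)
  b <- abm_run(pr, t_end = 2, snapshot_every = 1, seed = 42)
  expect_identical(a, b)
  c_ <- abm_run(pr, t_end = 2, snapshot_every = 1, seed = 43)
  expect_false(identical(a, c_))
})

test_that("snapshot cadence and empty-run behaviour match the contract", {
  pr <- small_abm_params()
  one <- abm_run(pr, t_end = 0, snapshot_every = 1, seed = 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$time, 0)
  snaps <- abm_run(pr, t_end = 3, snapshot_every = 1, seed = 1)
  expect_length(snaps, floor(3 / 1) + 1)
  expect_equal(vapply(snaps, function(s) s$time, numeric(1)), 0:3)
  expect_error(abm_run(pr, t_end = 1, snapshot_every = 0.033, seed = 1),
               "multiple of dt")
  # snapshots are valid labelled point clouds with macrophage-only marks
  s <- snaps[[4]]
  expect_s3_class(s, "point_cloud")
  expect_true(all(is.na(s$points$mark[s$points$category != "M"])))
})

test_that("parameter validation catches inconsistent configurations", {
  expect_error(abm_params(omega_N_tum = 0.5, omega_H_tum = 0.4), "thresholds")
  expect_error(abm_params(p_star = 30, dt = 0.05), "overflow")
  expect_error(abm_params(field_spacing = 2, r_int = 1.5), "resolve")
  expect_error(abm_params(dt = -1), "> 0")
})
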