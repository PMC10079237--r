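test_that("a single source-target pair lands in exactly one bin with the CSR value", {
  d <- pp_domain(0, 10, 0, 10, boundary = "periodic")
  b <- radial_binning(dr = 0.5, n_bins = 10)
  # distance 1.7 falls in bin 4 ([1.5, 2))
  pc <- point_cloud(c(2, 3.7), c(2, 2), c("B", "T"), domain = d)
  g <- cross_pcf(pc, "B", "T", b)
  expect_equal(which(g$values > 0), 4L)
  expect_equal(g$values[4], d$area / (pi * (2 * 1.5 + 0.5) * 0.5))
})

test_that("cross_pcf matches the double-loop oracle on random clouds", {
  for (seed in 1:4) {
    for (boundary in c("clipped", "periodic")) {
      d <- pp_domain(0, 8, 0, 8, boundary = boundary)
      cl <- random_cloud(25, d, seed = seed * 11)
      b <- radial_binning(dr = 0.6, n_bins = 8)
      g <- cross_pcf(cl, "B", "T", b)
      expect_equal(g$values, oracle_cross_pcf(cl, "B", "T", b),
                   tolerance = 1e-12)
      # self-pairs excluded when source == target
      gm <- cross_pcf(cl, "M", "M", b)
      expect_equal(gm$values, oracle_cross_pcf(cl, "M", "M", b),
                   tolerance = 1e-12)
    }
  }
})

test_that("empty populations give an undefined result, not an exception", {
  d <- pp_domain(0, 5, 0, 5)
  pc <- point_cloud(c(1, 2), c(1, 2), c("B", "B"), domain = d)
  g <- cross_pcf(pc, "B", "T", radial_binning(0.5, 5))
  expect_true(g$undefined)
  expect_true(all(is.na(g$values)))
  expect_equal(g$n_target, 0)
})

test_that("cross_pcf is symmetric on periodic domains and not on clipped", {
  dp <- pp_domain(0, 9, 0, 9, boundary = "periodic")
  cl <- random_cloud(40, dp, seed = 5)
  b <- radial_binning(0.5, 8)
  g1 <- cross_pcf(cl, "B", "T", b)
  g2 <- cross_pcf(cl, "T", "B", b)
  expect_equal(g1$values, g2$values, tolerance = 1e-12)

  dc <- pp_domain(0, 9, 0, 9)
  clc <- point_cloud(cl$points$x, cl$points$y, cl$points$category,
                     mark = cl$points$mark, domain = dc)
  h1 <- cross_pcf(clc, "B", "T", b)
  h2 <- cross_pcf(clc, "T", "B", b)
  expect_false(isTRUE(all.equal(h1$values, h2$values)))
})

test_that("statistics are invariant under a common rescaling of lengths", {
  d <- pp_domain(0, 8, 0, 8)
  cl <- random_cloud(30, d, seed = 3)
  b <- radial_binning(0.5, 8)
  g <- cross_pcf(cl, "B", "T", b)
  s <- 3.7
  cl2 <- point_cloud(cl$points$x * s, cl$points$y * s, cl$points$category,
                     mark = cl$points$mark,
                     domain = pp_domain(0, 8 * s, 0, 8 * s))
  g2 <- cross_pcf(cl2, "B", "T", radial_binning(0.5 * s, 8))
  expect_equal(g$values, g2$values, tolerance = 1e-12)

  s1 <- wpcf(cl, "B", b, p_grid = seq(0, 1, 0.2))
  s2 <- wpcf(cl2, "B", radial_binning(0.5 * s, 8), p_grid = seq(0, 1, 0.2))
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
})

test_that("wpcf matches the double-loop oracle, clipped and periodic", {
  for (boundary in c("clipped", "periodic")) {
    d <- pp_domain(0, 8, 0, 8, boundary = boundary)
    cl <- random_cloud(22, d, seed = 7)
    b <- radial_binning(0.75, 6)
    pg <- seq(0, 1, 0.25)
    spec <- weight_spec()
    s <- wpcf(cl, "B", b, pg, spec)
    expect_equal(s$values, oracle_wpcf(cl, "B", b, pg, spec),
                 tolerance = 1e-12)
  }
})

test_that("constant marks reduce the wPCF row to the carrier-target cross-PCF", {
  d <- pp_domain(0, 8, 0, 8)
  with_seed_test(21, {
    n <- 30
    cat_ <- sample(c("B", "M"), n, replace = TRUE, prob = c(0.4, 0.6))
    mark <- ifelse(cat_ == "M", 0.6, NA)
    cl <- point_cloud(runif(n, 0, 8), runif(n, 0, 8), cat_, mark = mark,
                      domain = d)
    b <- radial_binning(0.5, 8)
    s <- wpcf(cl, "B", b, p_grid = c(0, 0.6, 1))
    g <- cross_pcf(cl, "M", "B", b)
    expect_equal(s$values[2, ], g$values, tolerance = 1e-12)
  })
})

test_that("indicator weighting on binary marks recovers sub-population cross-PCFs", {
  d <- pp_domain(0, 8, 0, 8)
  with_seed_test(31, {
    n <- 40
    cat_ <- c(rep("B", 12), rep("M", 28))
    mark <- c(rep(NA, 12), sample(c(0, 1), 28, replace = TRUE))
    cl <- point_cloud(runif(n, 0, 8), runif(n, 0, 8), cat_, mark = mark,
                      domain = d)
    b <- radial_binning(0.5, 8)
    s <- wpcf(cl, "B", b, p_grid = c(0, 1), spec = weight_spec("indicator"))
    for (v in c(0, 1)) {
      # build the cloud in which only the matching sub-population remains M
      keep_cat <- cl$points$category
      keep_cat[keep_cat == "M" & cl$points$mark != v] <- "S"
      sub <- point_cloud(cl$points$x, cl$points$y, keep_cat,
                         mark = cl$points$mark, domain = d)
      g <- cross_pcf(sub, "M", "B", b)
      expect_equal(s$values[ifelse(v == 0, 1, 2), ], g$values,
                   tolerance = 1e-12)
    }
  })
})

test_that("rows with zero total weight are undefined, and slices extract rows", {
  d <- pp_domain(0, 8, 0, 8)
  with_seed_test(41, {
    cl <- point_cloud(runif(20, 0, 8), runif(20, 0, 8),
                      c(rep("B", 8), rep("M", 12)),
                      mark = c(rep(NA, 8), runif(12, 0, 0.3)), domain = d)
  })
  b <- radial_binning(0.5, 6)
  s <- wpcf(cl, "B", b, p_grid = seq(0, 1, 0.1))
  # marks stop at 0.3; rows beyond 0.3 + delta_p have no weight
  expect_true(all(s$undefined[s$p_grid > 0.5 + 1e-9]))
  expect_true(all(is.na(s$values[s$undefined, ])))
  expect_false(any(is.na(s$values[!s$undefined, ])))
  expect_equal(s$undefined, s$total_weight == 0)

  sl <- wpcf_slice(s, 0.2)
  expect_equal(sl$values, s$values[which(abs(s$p_grid - 0.2) < 1e-9), ])
  sl_und <- wpcf_slice(s, 0.9)
  expect_true(sl_und$undefined)
  expect_true(all(is.na(sl_und$values)))
  expect_error(wpcf_slice(s, 0.123), "not on the mark grid")
  expect_error(wpcf_slice(s, 1.5), "outside")
  sl_int <- wpcf_slice(s, 0.15, interpolate = TRUE)
  expect_equal(sl_int$values, (s$values[2, ] + s$values[3, ]) / 2)
})

test_that("a cloud with no marks yields a fully undefined surface with warning", {
  d <- pp_domain(0, 5, 0, 5)
  cl <- point_cloud(c(1, 2), c(1, 2), c("B", "T"), domain = d)
  expect_warning(s <- wpcf(cl, "B", radial_binning(0.5, 4), seq(0, 1, 0.5)),
                 "no mark-carrying points")
  expect_true(all(s$undefined))
})

test_that("two-mark wPCF reduces, specialises and is symmetric as expected", {
  d <- pp_domain(0, 6, 0, 6, boundary = "periodic")
  with_seed_test(55, {
    a <- point_cloud(runif(10, 0, 6), runif(10, 0, 6), rep("M", 10),
                     mark = rep(0.3, 10), domain = d)
    bb <- point_cloud(runif(12, 0, 6), runif(12, 0, 6), rep("M", 12),
                      mark = rep(0.8, 12), domain = d)
  })
  b <- radial_binning(0.5, 6)
  # constant marks: reduces to the cross-PCF between the two clouds
  s2 <- wpcf_two_marks(a, bb, b, p1_grid = 0.3, p2_grid = 0.8)
  merged <- point_cloud(c(a$points$x, bb$points$x), c(a$points$y, bb$points$y),
                        c(rep("M", 10), rep("T", 12)), domain = d)
  g <- cross_pcf(merged, "M", "T", b)
  expect_equal(as.vector(s2$values[1, 1, ]), g$values, tolerance = 1e-12)

  # symmetry under swapping clouds and targets on a periodic domain
  with_seed_test(56, {
    am <- point_cloud(runif(9, 0, 6), runif(9, 0, 6), rep("M", 9),
                      mark = runif(9), domain = d)
    bm <- point_cloud(runif(11, 0, 6), runif(11, 0, 6), rep("M", 11),
                      mark = runif(11), domain = d)
  })
  pg1 <- c(0.2, 0.7)
  pg2 <- c(0.4, 0.9)
  f <- wpcf_two_marks(am, bm, b, pg1, pg2)
  r <- wpcf_two_marks(bm, am, b, pg2, pg1)
  expect_equal(f$values, aperm(r$values, c(2, 1, 3)), tolerance = 1e-12)

  # degenerate single-value second grid with indicator weights matches wpcf
  # on the matching subset
  with_seed_test(57, {
    marks_b <- sample(c(0.25, 0.75), 14, replace = TRUE)
    xa <- runif(8, 0, 6); ya <- runif(8, 0, 6)
    xb <- runif(14, 0, 6); yb <- runif(14, 0, 6)
  })
  a3 <- point_cloud(xa, ya, rep("M", 8), mark = runif(8), domain = d)
  b3 <- point_cloud(xb, yb, rep("M", 14), mark = marks_b, domain = d)
  s3 <- wpcf_two_marks(a3, b3, b, p1_grid = c(0, 0.5, 1), p2_grid = 0.75,
                       spec = weight_spec("indicator"))
  # oracle: brute force over the matching subset with indicator weights
  ora <- oracle_wpcf(
    point_cloud(c(xa, xb[marks_b == 0.75]), c(ya, yb[marks_b == 0.75]),
                c(rep("M", 8), rep("T", sum(marks_b == 0.75))),
                mark = c(a3$points$mark, rep(NA, sum(marks_b == 0.75))),
                domain = d),
    "T", b, c(0, 0.5, 1), weight_spec("indicator"))
  expect_equal(s3$values[, 1, ], ora, tolerance = 1e-12)

  expect_error(wpcf_two_marks(merged, merged), "marks")
})

test_that("CSR populations give mean correlation near one", {
  d <- pp_domain(0, 30, 0, 30, boundary = "periodic")
  b <- radial_binning(0.25, 40)
  means <- vapply(1:8, function(s) {
    cl <- make_csr(250, 250, d, seed = 100 + s)
    mean(cross_pcf(cl, "B", "M", b)$values)
  }, numeric(1))
  expect_gt(mean(means), 0.95)
  expect_lt(mean(means), 1.05)
})
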