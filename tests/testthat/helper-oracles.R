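# Independent reference implementations used as oracles. These deliberately
# mirror the definitions term by term (naive double loops), not the
# vectorised production code paths.

# Metric respecting the domain boundary mode.
oracle_dist <- function(x1, y1, x2, y2, domain) {
  dx <- x1 - x2
  dy <- y1 - y2
  if (domain$boundary == "periodic") {
    w <- domain$xmax - domain$xmin
    h <- domain$ymax - domain$ymin
    dx <- dx - w * round(dx / w)
    dy <- dy - h * round(dy / h)
  }
  sqrt(dx^2 + dy^2)
}

# Naive double-loop cross-PCF.
oracle_cross_pcf <- function(cloud, source, target, binning) {
  p <- cloud$points
  A <- cloud$domain$area
  si <- which(p$category == source)
  ti <- which(p$category == target)
  if (length(si) == 0 || length(ti) == 0) {
    return(rep(NA_real_, binning$n_bins))
  }
  vals <- numeric(binning$n_bins)
  for (k in seq_len(binning$n_bins)) {
    acc <- 0
    for (i in si) {
      a_ik <- annulus_area(c(p$x[i], p$y[i]), binning$r[k], binning$dr,
                           cloud$domain)
      for (j in ti) {
        if (i == j) next
        d <- oracle_dist(p$x[i], p$y[i], p$x[j], p$y[j], cloud$domain)
        if (d >= binning$r[k] && d < binning$r[k] + binning$dr) {
          acc <- acc + A / a_ik
        }
      }
    }
    vals[k] <- acc / (length(si) * length(ti))
  }
  vals
}

# Naive double-loop wPCF surface.
oracle_wpcf <- function(cloud, target, binning, p_grid, spec) {
  p <- cloud$points
  A <- cloud$domain$area
  ci <- which(!is.na(p$mark))
  ti <- which(p$category == target)
  vals <- matrix(NA_real_, length(p_grid), binning$n_bins)
  for (pi in seq_along(p_grid)) {
    w <- vapply(ci, function(i) mark_weight(spec, p_grid[pi], p$mark[i]),
                numeric(1))
    w_tot <- sum(w)
    if (w_tot == 0) next
    for (k in seq_len(binning$n_bins)) {
      acc <- 0
      for (ii in seq_along(ci)) {
        i <- ci[ii]
        a_ik <- annulus_area(c(p$x[i], p$y[i]), binning$r[k], binning$dr,
                             cloud$domain)
        for (j in ti) {
          if (i == j) next
          d <- oracle_dist(p$x[i], p$y[i], p$x[j], p$y[j], cloud$domain)
          if (d >= binning$r[k] && d < binning$r[k] + binning$dr) {
            acc <- acc + w[ii] * A / a_ik
          }
        }
      }
      vals[pi, k] <- acc / (w_tot * length(ti))
    }
  }
  vals
}

# Monte-Carlo annulus-in-rectangle area: sample uniformly inside the annulus
# and scale the hit fraction by the full annulus area.
oracle_annulus_area_mc <- function(center, r_k, dr, domain, n = 1e6) {
  theta <- stats::runif(n, 0, 2 * pi)
  rad <- sqrt(stats::runif(n, r_k^2, (r_k + dr)^2))
  px <- center[1] + rad * cos(theta)
  py <- center[2] + rad * sin(theta)
  hit <- px >= domain$xmin & px <= domain$xmax &
    py >= domain$ymin & py <= domain$ymax
  mean(hit) * pi * (2 * r_k + dr) * dr
}

# A small random labelled cloud for property tests.
random_cloud <- function(n, domain, seed, with_marks = TRUE,
                         categories = c("B", "M", "T")) {
  with_seed_test(seed, {
    cat_ <- sample(categories, n, replace = TRUE)
    mark <- rep(NA_real_, n)
    if (with_marks) {
      mk <- cat_ == "M"
      mark[mk] <- stats::runif(sum(mk))
    }
    point_cloud(stats::runif(n, domain$xmin, domain$xmax),
                stats::runif(n, domain$ymin, domain$ymax),
                cat_, mark = mark, domain = domain)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
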