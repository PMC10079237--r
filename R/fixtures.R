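# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Line-gradient validation pattern
#'
#' A deterministic construction with a known wPCF ridge, used to validate the
#' statistic: `n_crosses` reference points (category `B`, no mark) equally
#' spaced along the horizontal line `y = 1`, and `n_circles` points
#' (category `M`) placed uniformly at random in the square `[0, edge]^2`,
#' each marked by its distance to the line, `|1 - y|` (`variant = "linear"`),
#' or the squared distance `|1 - y|^2` (`variant = "quadratic"`). By
#' construction the wPCF towards `B` concentrates along the ridge `P = r`
#' (linear) or `P = r^2` (quadratic). Crosses are laid at
#' `x = (i - 1/2) * edge / n_crosses` so no endpoint is double-weighted.
#'
#' @param variant `"linear"` or `"quadratic"` mark formula.
#' @param n_crosses Number of reference points on the line (default 200).
#' @param n_circles Number of marked points (default 1000).
#' @param edge Square edge length (default 2).
#' @param seed RNG seed; the pattern is bit-identical per seed.
#' @return A [point_cloud()] on the clipped square.
#' @export
make_line_pattern <- function(variant = c("linear", "quadratic"),
                              n_crosses = 200, n_circles = 1000,
                              edge = 2, seed = 1) {
  variant <- match.arg(variant)
  stopifnot(n_crosses > 0, n_circles > 0, edge > 0)
  with_seed(seed, {
    cx <- (seq_len(n_crosses) - 0.5) * edge / n_crosses
    cy <- rep(1, n_crosses)
    px <- stats::runif(n_circles, 0, edge)
    py <- stats::runif(n_circles, 0, edge)
    m <- abs(1 - py)
    if (variant == "quadratic") m <- m^2
    point_cloud(
      x = c(cx, px), y = c(cy, py),
      category = c(rep("B", n_crosses), rep("M", n_circles)),
      mark = c(rep(NA_real_, n_crosses), pmin(m, 1)),
      domain = pp_domain(0, edge, 0, edge)
    )
  })
}

#' Completely spatially random two-population pattern
#'
#' Two independent uniform populations on the domain: the null model under
#' which every cross-PCF and wPCF value has expectation 1.
#'
#' @param n_a,n_b Population sizes (categories `categories[1]`, `categories[2]`).
#' @param domain A [pp_domain()].
#' @param seed RNG seed.
#' @param mark_sampler Optional function `n -> marks in [0,1]` applied to the
#'   second population (i.i.d. marks keep the wPCF expectation at 1).
#' @param categories Length-2 character vector of category labels.
#' @return A [point_cloud()].
#' @export
make_csr <- function(n_a, n_b, domain = pp_domain(), seed = 1,
                     mark_sampler = NULL, categories = c("B", "M")) {
  stopifnot(n_a >= 0, n_b >= 0, is_pp_domain(domain), length(categories) == 2)
  with_seed(seed, {
    n <- n_a + n_b
    x <- stats::runif(n, domain$xmin, domain$xmax)
    y <- stats::runif(n, domain$ymin, domain$ymax)
    mark <- rep(NA_real_, n)
    if (!is.null(mark_sampler) && n_b > 0) {
      mark[(n_a + 1):n] <- mark_sampler(n_b)
    }
    point_cloud(x, y,
                category = c(rep(categories[1], n_a), rep(categories[2], n_b)),
                mark = mark, domain = domain)
  })
}

#' Distance-banded pattern with a declared mark-distance law
#'
#' Generalises [make_line_pattern()]: marks are a caller-supplied function of
#' the distance to the reference line, plus bounded uniform noise, so the
#' expected wPCF ridge is known by construction and recovery can be tested
#' under controlled noise.
#'
#' @param band_fun Function mapping distance to mark (values clipped to `[0,1]`).
#' @param noise Half-width of the added uniform noise (0 = exact law).
#' @param n_crosses,n_circles,edge,seed As in [make_line_pattern()].
#' @param line_y Height of the reference line.
#' @return A [point_cloud()].
#' @export
make_banded <- function(band_fun = identity, noise = 0,
                        n_crosses = 200, n_circles = 1000,
                        edge = 2, seed = 1, line_y = 1) {
  stopifnot(is.function(band_fun), noise >= 0)
  with_seed(seed, {
    cx <- (seq_len(n_crosses) - 0.5) * edge / n_crosses
    px <- stats::runif(n_circles, 0, edge)
    py <- stats::runif(n_circles, 0, edge)
    m <- band_fun(abs(line_y - py))
    if (noise > 0) m <- m + stats::runif(n_circles, -noise, noise)
    m <- pmin(pmax(m, 0), 1)
    point_cloud(
      x = c(cx, px), y = c(rep(line_y, n_crosses), py),
      category = c(rep("B", n_crosses), rep("M", n_circles)),
      mark = c(rep(NA_real_, n_crosses), m),
      domain = pp_domain(0, edge, 0, edge)
    )
  })
}
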