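#' Automatic outcome label for a snapshot
#'
#' Rule-based stand-in for expert labelling of simulation endpoints, applied
#' in fixed order: `Elimination` if at most `elimination_max` tumour cells
#' remain (total or near-total clearance); otherwise `Escape` if any tumour
#' cell lies within `escape_radius` of a blood vessel (tumour reaching the
#' vasculature is taken as intravasation); otherwise `Equilibrium`.
#' Both thresholds are configuration, not biology: they encode how a human
#' rater would call the endpoint.
#'
#' @param cloud A [point_cloud()] containing vessel positions.
#' @param elimination_max Tumour-count threshold for `Elimination`.
#' @param escape_radius Tumour-to-vessel distance threshold (diameters).
#' @return One of `"Equilibrium"`, `"Escape"`, `"Elimination"`.
#' @export
auto_label <- function(cloud, elimination_max = 5, escape_radius = 1) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  tum <- p[p$category == "T", , drop = FALSE]
  if (nrow(tum) <= elimination_max) return("Elimination")
  ves <- p[p$category == "B", , drop = FALSE]
  if (nrow(ves) == 0) return("Equilibrium")
  d2 <- outer(tum$x, ves$x, "-")^2 + outer(tum$y, ves$y, "-")^2
  if (min(d2) <= escape_radius^2) "Escape" else "Equilibrium"
}

as_vector_matrix <- function(vectors) {
  if (inherits(vectors, "signature_vector")) vectors <- list(vectors)
  if (is.list(vectors) && !is.data.frame(vectors)) {
    lens <- vapply(vectors, function(v) length(v$values), integer(1))
    if (length(unique(lens)) != 1) {
      stop("signature vectors have mismatched lengths (different grids?)",
           call. = FALSE)
    }
    return(do.call(rbind, lapply(vectors, function(v) v$values)))
  }
  as.matrix(vectors)
}

#' Fit the PCA + SVM classification model
#'
#' Principal component analysis on the mean-centred signature vectors,
#' followed by a support vector machine with a radial basis function kernel
#' (library defaults) on the leading principal coordinates. The number of
#' components is capped at the rank the training set can support.
#'
#' @param vectors List of [vectorize_signature()] results (or a numeric
#'   matrix, one row per snapshot).
#' @param labels Outcome labels, one per vector (at least two distinct).
#' @param n_components Number of principal components fed to the SVM
#'   (default 100).
#' @return An object of class `signature_model`: PCA basis (`center`,
#'   `rotation`, `sdev`), training `scores` and `labels`, the fitted `svm`,
#'   and the signature `layout`.
#' @export
fit_reduced_model <- function(vectors, labels, n_components = 100) {
  layout <- if (is.list(vectors) && inherits(vectors[[1]], "signature_vector")) {
    vectors[[1]]$layout
  } else {
    NULL
  }
  x <- as_vector_matrix(vectors)
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels))
  if (nlevels(droplevels(labels)) < 2) {
    stop("training set must contain at least two classes", call. = FALSE)
  }
  k <- min(n_components, nrow(x) - 1, ncol(x))
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pca$x[, seq_len(k), drop = FALSE]
  fit <- e1071::svm(x = scores, y = droplevels(labels), kernel = "radial")
  structure(
    list(center = pca$center, rotation = pca$rotation[, seq_len(k), drop = FALSE],
         sdev = pca$sdev, n_components = k, scores = scores,
         labels = droplevels(labels), svm = fit, layout = layout),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(
    "signature model: %d training vectors, %d components, classes: %s\n",
    nrow(x$scores), x$n_components, paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' Project signature vectors into the fitted principal-component basis
#'
#' @param model A [fit_reduced_model()] result.
#' @param vectors Signature vector(s) (list, single object, or matrix).
#' @param k Number of leading coordinates to return
#'   (default all fitted components).
#' @return A matrix of projected coordinates, one row per vector.
#' @export
project_signature <- function(model, vectors, k = model$n_components) {
  stopifnot(inherits(model, "signature_model"), k <= model$n_components)
  x <- as_vector_matrix(vectors)
  if (ncol(x) != length(model$center)) {
    stop(sprintf("vector length %d does not match the model's %d (grid mismatch)",
                 ncol(x), length(model$center)), call. = FALSE)
  }
  sweep(x, 2, model$center) %*% model$rotation[, seq_len(k), drop = FALSE]
}

#' Class-centroid signature reconstructed from leading components
#'
#' Averages the projections of one class's vectors, truncates to the first
#' `k` components, maps the centroid back to signature space, and reshapes
#' it into the three-statistic layout so the "typical" wPCF surfaces and
#' cross-PCF of a class can be inspected and plotted.
#'
#' @param model A [fit_reduced_model()] result (must carry a layout).
#' @param vectors Signature vectors of a single class (non-empty).
#' @param k Number of components retained (default all fitted; at full rank
#'   the reconstruction is the exact class mean).
#' @return A `pcf_signature` (reconstructed, so masks are not meaningful).
#' @export
centroid_signature <- function(model, vectors, k = model$n_components) {
  stopifnot(!is.null(model$layout))
  proj <- project_signature(model, vectors, k)
  centroid <- colMeans(proj)
  flat <- as.vector(model$rotation[, seq_len(k), drop = FALSE] %*% centroid) +
    model$center
  reshape_signature(flat, model$layout)
}

#' Classify signature vectors
#'
#' Applies the fitted SVM to the leading principal coordinates of each
#' vector. Deterministic for a fitted model, and independent across vectors.
#'
#' @param model A [fit_reduced_model()] result.
#' @param vectors Signature vector(s).
#' @return Character vector of predicted labels.
#' @export
classify_signature <- function(model, vectors) {
  proj <- project_signature(model, vectors)
  as.character(stats::predict(model$svm, proj))
}

#' Project a snapshot series into principal-component space
#'
#' Computes the PCF signature of each snapshot (with the model's grids),
#' projects it onto the first `k` principal components, and returns the
#' time-indexed path. Simulations can drift between outcome regimes over
#' time, and the path makes these transitions visible; the per-snapshot
#' [auto_label()] is attached for convenience.
#'
#' @param model A [fit_reduced_model()] result (must carry a layout).
#' @param snapshots List of [point_cloud()] snapshots, oldest first.
#' @param k Number of leading coordinates (default 3).
#' @param spec A [weight_spec()].
#' @return A data frame with `time`, coordinates `PC1..PCk`, and `label`.
#' @export
signature_trajectory <- function(model, snapshots, k = 3,
                                 spec = weight_spec()) {
  stopifnot(inherits(model, "signature_model"), !is.null(model$layout))
  binning <- radial_binning(dr = model$layout$dr, n_bins = model$layout$n_bins)
  p_grid <- model$layout$p_grid
  rows <- lapply(snapshots, function(s) {
    vec <- vectorize_signature(compute_signature(s, binning, p_grid, spec))
    coords <- project_signature(model, vec, k)
    data.frame(time = if (is.null(s$time)) NA_real_ else s$time,
               coords, label = auto_label(s))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("time", paste0("PC", seq_len(k)), "label")
  rownames(out) <- NULL
  out
}
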