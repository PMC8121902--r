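#' @title Generalized Procrustes alignment with sliding semilandmarks
#' @name gpa
#' @description
#' Superimposition removes translation (centering), size (unit centroid
#' size) and orientation (least-squares rotation, reflections disallowed)
#' from each landmark configuration. When sliding is enabled, semilandmarks
#' are moved along the chord joining their two outline neighbours to the
#' point minimising squared distance to the corresponding consensus
#' landmark, interleaved with re-alignment until the consensus stabilises.
NULL

centroid_size <- function(x) {
  cx <- sweep(x, 2L, colMeans(x))
  sqrt(sum(cx^2))
}

center_scale <- function(x, id = "?") {
  cs <- centroid_size(x)
  if (cs < 1e-12) stop("degenerate configuration (zero centroid size): ", id)
  sweep(x, 2L, colMeans(x)) / cs
}

# Optimal rotation of centered x onto centered y, reflection disallowed.
rotation_to <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Ordinary (two-configuration) Procrustes fit
#'
#' Analytic least-squares superimposition of one configuration onto another:
#' both are centered, the moving configuration is optimally rotated (no
#' reflection) and, if `scale = TRUE`, optimally scaled. The reported
#' distance is the residual norm after the fit, with the target scaled to
#' unit centroid size, i.e. the full (or, with `scale = FALSE` and unit
#' pre-scaling, partial) Procrustes distance.
#'
#' @param x,y numeric k x 2 landmark matrices (x is fitted onto y).
#' @param scale optimise the scale of `x` as well (full Procrustes).
#' @return list with `rotation`, `beta` (scale), `fitted`, and `distance`.
#' @export
opa_fit <- function(x, y, scale = TRUE) {
  if (!all(dim(x) == dim(y))) stop("mismatched landmark dimensions")
  xc <- center_scale(x)
  yc <- center_scale(y)
  R <- rotation_to(xc, yc)
  xr <- xc %*% R
  beta <- if (scale) sum(xr * yc) else 1
  fitted <- beta * xr
  list(rotation = R, beta = beta, fitted = fitted,
       distance = sqrt(sum((fitted - yc)^2)))
}

#' Generalized Procrustes alignment
#'
#' @param shapes list of [landmark_config()] objects (or bare k x 2
#'   matrices), all with the same landmark count.
#' @param slide slide semilandmarks against the current consensus each
#'   iteration (chord projection criterion).
#' @param sliders optional slider matrix (point, before, after); defaults to
#'   the sliders implied by the configurations' curve structure.
#' @param max_iter,tol iteration cap and consensus root-mean-square change
#'   threshold for convergence of each alignment phase.
#' @param slide_passes number of sliding passes (each followed by
#'   re-alignment to convergence). Chord-line sliding iterated indefinitely
#'   against a moving consensus lets semilandmarks creep along the outline,
#'   so a small fixed number of passes is used, after which the alignment
#'   itself is run to convergence.
#' @return object of class `aligned_shapes`: list with `aligned` (named list
#'   of unit-size, origin-centered k x 2 matrices), `consensus`,
#'   `centroid_sizes`, `ids`, `iterations`, `converged` and the per-iteration
#'   `objective` (sum of squared distances to the consensus).
#' @export
gpa_align <- function(shapes, slide = FALSE, sliders = NULL,
                      max_iter = 100L, tol = 1e-7, slide_passes = 5L) {
  if (length(shapes) < 2L) stop("need at least two configurations")
  ids <- vapply(seq_along(shapes), function(i) {
    if (inherits(shapes[[i]], "landmark_config")) shapes[[i]]$specimen_id
    else paste0("specimen_", i)
  }, character(1))
  coords <- lapply(shapes, function(s)
    if (inherits(s, "landmark_config")) s$coords else as.matrix(s))
  k <- nrow(coords[[1L]])
  if (!all(vapply(coords, nrow, integer(1)) == k))
    stop("mismatched landmark counts across configurations")
  if (slide && is.null(sliders)) {
    first <- shapes[[1L]]
    if (inherits(first, "landmark_config") && length(first$curves))
      sliders <- sliders_from_curves(first$curves)
    if (is.null(sliders) || nrow(sliders) == 0L)
      stop("slide = TRUE but no sliders available")
  }

  sizes <- vapply(coords, centroid_size, numeric(1))
  X <- lapply(seq_along(coords), function(i) center_scale(coords[[i]], ids[i]))

  # plain GPA loop: rotate all to consensus, update consensus, repeat
  gpa_core <- function(X, consensus) {
    objective <- numeric(0)
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      X <- lapply(X, function(x) x %*% rotation_to(x, consensus))
      new_consensus <- center_scale(Reduce(`+`, X) / length(X))
      objective <- c(objective, sum(vapply(X, function(x)
        sum((x - new_consensus)^2), numeric(1))))
      delta <- sqrt(mean((new_consensus - consensus)^2))
      consensus <- new_consensus
      if (delta < tol) { converged <- TRUE; break }
    }
    list(X = X, consensus = consensus, objective = objective,
         converged = converged, iterations = iter)
  }

  fit <- gpa_core(X, X[[1L]])
  objective <- fit$objective
  iterations <- fit$iterations
  if (slide) {
    for (pass in seq_len(slide_passes)) {
      Xs <- lapply(fit$X, function(x)
        center_scale(slide_coords(x, sliders, fit$consensus)))
      fit <- gpa_core(Xs, fit$consensus)
      objective <- c(objective, fit$objective)
      iterations <- iterations + fit$iterations
    }
  }
  X <- lapply(fit$X, function(x) x %*% rotation_to(x, fit$consensus))
  names(X) <- ids
  structure(list(aligned = X, consensus = fit$consensus,
                 centroid_sizes = stats::setNames(sizes, ids), ids = ids,
                 iterations = iterations, converged = fit$converged,
                 objective = objective, sliders = sliders),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("aligned_shapes:", length(x$aligned), "configurations x",
      nrow(x$consensus), "landmarks;", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

# Slide one configuration's semilandmarks along their neighbour chords to
# the orthogonal projection of the corresponding reference landmark.
slide_coords <- function(x, sliders, reference) {
  for (r in seq_len(nrow(sliders))) {
    i <- sliders[r, 1L]; a <- sliders[r, 2L]; b <- sliders[r, 3L]
    u <- x[b, ] - x[a, ]
    len2 <- sum(u^2)
    if (len2 < 1e-24) {
      warning("zero-length chord at landmark ", i, "; left unmoved")
      next
    }
    t_opt <- sum((reference[i, ] - x[a, ]) * u) / len2
    x[i, ] <- x[a, ] + t_opt * u
  }
  x
}

#' Slide the semilandmarks of an aligned set against its consensus
#'
#' One sliding pass: each semilandmark moves along the chord joining its two
#' neighbours to the position minimising its squared distance to the
#' consensus landmark (closed-form orthogonal projection). The summed squared
#' chord criterion never increases. Configurations are re-centered and
#' re-scaled to unit centroid size afterwards; the consensus is recomputed.
#'
#' @param shapeset an `aligned_shapes` object.
#' @param sliders slider matrix (point, before, after); defaults to the one
#'   stored on the set.
#' @return updated `aligned_shapes`.
#' @export
slide_semilandmarks <- function(shapeset, sliders = NULL) {
  stopifnot(inherits(shapeset, "aligned_shapes"))
  if (is.null(sliders)) sliders <- shapeset$sliders
  if (is.null(sliders)) stop("no sliders available")
  ref <- shapeset$consensus
  shapeset$aligned <- lapply(shapeset$aligned, function(x)
    center_scale(slide_coords(x, sliders, ref)))
  shapeset$consensus <- center_scale(Reduce(`+`, shapeset$aligned) /
                                     length(shapeset$aligned))
  shapeset
}

#' Procrustes distance between two aligned configurations
#'
#' Plain Euclidean norm of the coordinate difference; the configurations are
#' assumed already superimposed (e.g. members of one [gpa_align()] result).
#'
#' @param a,b k x 2 coordinate matrices.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mismatched landmark dimensions")
  sqrt(sum((a - b)^2))
}

#' Flatten an aligned set to a specimen-by-coordinate matrix
#'
#' @param shapeset an `aligned_shapes` object.
#' @return numeric matrix, one row per specimen, columns x1, y1, x2, y2, ...
#' @export
aligned_matrix <- function(shapeset) {
  stopifnot(inherits(shapeset, "aligned_shapes"))
  out <- t(vapply(shapeset$aligned, function(x) as.numeric(t(x)),
                  numeric(2L * nrow(shapeset$consensus))))
  rownames(out) <- shapeset$ids
  k <- nrow(shapeset$consensus)
  colnames(out) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2L))
  out
}
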