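#' Principal component analysis of shape or functional data
#'
#' Mean-centred PCA. Functional data should arrive already z-scored (see
#' [z_standardize()]), making the decomposition correlation-equivalent;
#' aligned shape coordinates are centred only. Eigenvector signs are fixed
#' so the largest-magnitude loading of each axis is positive, for
#' reproducible plots.
#'
#' @param x numeric matrix (taxa/specimens as rows) with no missing cells.
#' @return object of class `ordination`: list with `scores`, `var_frac`
#'   (per-axis variance fractions), `sdev`, `loadings` (variable x axis),
#'   `center`, and `n`.
#' @export
pca_ordination <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells in ordination input")
  if (nrow(x) < 2L) stop("need at least two rows")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (max(p$sdev) < 1e-14) stop("rank-0 matrix: no variation to ordinate")
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2L, flip, `*`)
  p$x <- sweep(p$x, 2L, flip, `*`)
  ev <- p$sdev^2
  structure(list(scores = p$x, var_frac = ev / sum(ev), sdev = p$sdev,
                 loadings = p$rotation, center = p$center, n = nrow(x)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination:", x$n, "rows,", length(x$var_frac), "axes; first axes ",
      paste0(round(100 * utils::head(x$var_frac, 3), 1), "%", collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-variable contribution percentages to one axis
#'
#' Squared loadings normalised to percentages; sums to 100 per axis.
#'
#' @param ord an `ordination`.
#' @param axis axis index.
#' @return named numeric vector of percentages.
#' @export
pc_contributions <- function(ord, axis = 1L) {
  stopifnot(inherits(ord, "ordination"))
  if (axis < 1L || axis > ncol(ord$loadings)) stop("axis out of range")
  v <- ord$loadings[, axis]^2
  100 * v / sum(v)
}

#' Piecewise-linear interpolation of a variable over a 2D morphospace
#'
#' Triangulates the score points (Delaunay) and interpolates the variable
#' linearly within each triangle (barycentric weights) on a regular grid over
#' the occupied bounding box. Grid nodes outside the convex hull are `NA`.
#'
#' @param scores two-column matrix of ordination scores.
#' @param values numeric vector of the variable at each score point.
#' @param n grid resolution per axis (default 200).
#' @return list with vectors `x`, `y` and an `n x n` matrix `z`
#'   (rows indexed by `x`, columns by `y`).
#' @export
contour_interpolate <- function(scores, values, n = 200L) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L, length(values) == nrow(scores))
  if (nrow(scores) < 3L) stop("need at least three points")
  tri <- delaunay_triangulation(scores)
  if (nrow(tri) == 0L) stop("all points are collinear; cannot triangulate")
  gx <- seq(min(scores[, 1]), max(scores[, 1]), length.out = n)
  gy <- seq(min(scores[, 2]), max(scores[, 2]), length.out = n)
  grid <- cbind(rep(gx, times = n), rep(gy, each = n))
  z <- rep(NA_real_, nrow(grid))
  eps <- 1e-9 * max(diff(range(gx)), diff(range(gy)))
  for (t in seq_len(nrow(tri))) {
    a <- scores[tri[t, 1L], ]; b <- scores[tri[t, 2L], ]; c <- scores[tri[t, 3L], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-14) next
    w1 <- ((b[1] - grid[, 1]) * (c[2] - grid[, 2]) -
           (c[1] - grid[, 1]) * (b[2] - grid[, 2])) / det
    w2 <- ((c[1] - grid[, 1]) * (a[2] - grid[, 2]) -
           (a[1] - grid[, 1]) * (c[2] - grid[, 2])) / det
    w3 <- 1 - w1 - w2
    inside <- w1 >= -eps & w2 >= -eps & w3 >= -eps
    vals <- w1[inside] * values[tri[t, 1L]] + w2[inside] * values[tri[t, 2L]] +
      w3[inside] * values[tri[t, 3L]]
    z[inside] <- vals
  }
  list(x = gx, y = gy, z = matrix(z, nrow = n, ncol = n))
}

#' Delaunay triangulation of 2D points (Bowyer-Watson)
#'
#' @param pts two-column coordinate matrix.
#' @return integer matrix, one triangle per row (indices into `pts`); zero
#'   rows when all points are collinear.
#' @export
delaunay_triangulation <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) return(matrix(integer(), 0, 3))
  span <- max(apply(pts, 2L, function(v) diff(range(v))), 1e-12)
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  big <- 64 * span
  P <- rbind(pts,
             c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big))
  super <- n + 1:3
  tris <- list(super)

  circum <- function(tr) {
    a <- P[tr[1L], ]; b <- P[tr[2L], ]; c <- P[tr[3L], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
           (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
           (sum(c^2)) * (b[1] - a[1])) / d
    c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
  }
  cc <- lapply(tris, circum)

  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- which(vapply(cc, function(ce)
      (p[1] - ce[1])^2 + (p[2] - ce[2])^2 <= ce[3] * (1 + 1e-12), logical(1)))
    if (!length(bad)) next
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[-bad]; cc <- cc[-bad]
    for (e in seq_len(nrow(boundary))) {
      tr <- c(boundary[e, ], i)
      tris <- c(tris, list(tr))
      cc <- c(cc, list(circum(tr)))
    }
  }
  keep <- vapply(tris, function(tr) !any(tr %in% super), logical(1))
  out <- do.call(rbind, tris[keep])
  if (is.null(out)) out <- matrix(integer(), 0, 3)
  # drop degenerate (zero-area) triangles from collinear inputs
  if (nrow(out)) {
    area <- vapply(seq_len(nrow(out)), function(t) {
      a <- P[out[t, 1L], ]; b <- P[out[t, 2L], ]; c <- P[out[t, 3L], ]
      abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
    }, numeric(1))
    out <- out[area > 1e-14 * span^2, , drop = FALSE]
  }
  storage.mode(out) <- "integer"
  out
}
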