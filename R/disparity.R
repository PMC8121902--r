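#' Range-through bin membership
#'
#' A taxon is a member of every bin between and including its first and last
#' appearance bins.
#'
#' @param taxa taxon table with `taxon_id`, `clade`, `first_bin`, `last_bin`.
#' @param bins a `time_bins` scheme.
#' @param range_through if `FALSE`, taxa are placed only in their first and
#'   last bins (occurrence-style binning).
#' @return object of class `bin_membership`: long data frame (`bin`,
#'   `taxon_id`, `clade`) plus the scheme in attribute `"bins"`.
#' @export
bin_taxa <- function(taxa, bins, range_through = TRUE) {
  i1 <- bin_index(taxa$first_bin, bins)
  i2 <- bin_index(taxa$last_bin, bins)
  if (any(i1 > i2))
    stop("first_bin after last_bin for taxon: ",
         paste(taxa$taxon_id[i1 > i2], collapse = ", "))
  rows <- lapply(seq_len(nrow(taxa)), function(r) {
    span <- if (range_through) i1[r]:i2[r] else unique(c(i1[r], i2[r]))
    data.frame(bin = bins$bin[span], taxon_id = taxa$taxon_id[r],
               clade = taxa$clade[r], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bin <- factor(out$bin, levels = bins$bin)
  out <- out[order(out$bin, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bins") <- bins
  class(out) <- c("bin_membership", "data.frame")
  out
}

#' Mean pairwise distance disparity with bootstrap confidence interval
#'
#' MPD is the mean of all unordered pairwise distances among the members.
#' The bootstrap resamples members with replacement; pairs drawn from the
#' same resampled index are excluded from the resample's mean. Percentile
#' 2.5/97.5 bounds give the 95% interval.
#'
#' @param d a `distance_matrix` whose row names cover `members`.
#' @param members taxon ids.
#' @param B bootstrap replicates (default 1000; `B = 0` skips the CI).
#' @param seed RNG seed.
#' @return one-row data frame: `metric`, `estimate`, `ci_lo`, `ci_hi`, `n`,
#'   `n_boot`. Fewer than two members yields a missing estimate.
#' @export
disparity_mpd <- function(d, members, B = 1000L, seed = 1L) {
  dm <- as.matrix(d)
  if (!all(members %in% rownames(dm)))
    stop("members absent from distance matrix: ",
         paste(setdiff(members, rownames(dm)), collapse = ", "))
  n <- length(members)
  if (n < 2L) {
    message("disparity_mpd: fewer than two members; estimate is missing")
    return(data.frame(metric = "MPD", estimate = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, n = n, n_boot = 0L))
  }
  sub <- dm[members, members, drop = FALSE]
  est <- mean(sub[upper.tri(sub)])
  lo <- hi <- NA_real_
  if (B > 0L) {
    set.seed(seed)
    reps <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      m <- sub[idx, idx, drop = FALSE]
      same <- outer(idx, idx, `==`)
      vals <- m[upper.tri(m) & !same]
      if (length(vals)) mean(vals) else NA_real_
    }, numeric(1))
    qs <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
  }
  data.frame(metric = "MPD", estimate = est, ci_lo = lo, ci_hi = hi,
             n = n, n_boot = as.integer(B))
}

#' Variance-based disparity of a member set
#'
#' `sum_of_variances` is the trace of the member covariance matrix (n - 1
#' denominator); `procrustes_variance` is the mean squared distance of the
#' members to their mean (n denominator), the standard Procrustes-variance
#' form for aligned coordinates.
#'
#' @param x numeric matrix (aligned coordinates or characters), rows named
#'   by taxon.
#' @param members taxon ids.
#' @param metric `"sum_of_variances"` or `"procrustes_variance"`.
#' @return one-row data frame as in [disparity_mpd()] (no CI columns).
#' @export
variance_disparity <- function(x, members,
                               metric = c("sum_of_variances", "procrustes_variance")) {
  metric <- match.arg(metric)
  x <- unclass(as.matrix(x))
  if (!all(members %in% rownames(x)))
    stop("members absent from matrix: ",
         paste(setdiff(members, rownames(x)), collapse = ", "))
  n <- length(members)
  if (n < 2L)
    return(data.frame(metric = metric, estimate = NA_real_, n = n))
  xs <- x[members, , drop = FALSE]
  dev2 <- sum(sweep(xs, 2L, colMeans(xs))^2)
  est <- if (metric == "sum_of_variances") dev2 / (n - 1L) else dev2 / n
  data.frame(metric = metric, estimate = est, n = n)
}

#' Disparity curve over time bins
#'
#' Applies [disparity_mpd()] and/or [variance_disparity()] per bin and per
#' clade (plus the pooled fauna as clade `"all"`).
#'
#' @param membership a `bin_membership`.
#' @param d `distance_matrix` (needed for MPD).
#' @param x data matrix (needed for the variance metrics).
#' @param metrics subset of `c("MPD", "sum_of_variances", "procrustes_variance")`.
#' @param B,seed bootstrap controls for MPD.
#' @return data frame of class `disparity_curve`: `bin`, `clade`, `metric`,
#'   `estimate`, `ci_lo`, `ci_hi`, `n`.
#' @export
disparity_curve <- function(membership, d = NULL, x = NULL,
                            metrics = c("MPD", "sum_of_variances",
                                        "procrustes_variance"),
                            B = 1000L, seed = 1L) {
  stopifnot(inherits(membership, "bin_membership"))
  bins <- attr(membership, "bins")
  rows <- list()
  for (bn in bins$bin) {
    here <- membership[membership$bin == bn, , drop = FALSE]
    groups <- c(list(all = here$taxon_id),
                split(here$taxon_id, here$clade))
    for (g in names(groups)) {
      members <- unique(groups[[g]])
      for (met in metrics) {
        row <- if (met == "MPD") {
          if (is.null(d)) next
          if (length(members) < 2L)
            data.frame(metric = "MPD", estimate = NA_real_, ci_lo = NA_real_,
                       ci_hi = NA_real_, n = length(members), n_boot = 0L)
          else disparity_mpd(d, members, B = B,
                             seed = seed + match(bn, bins$bin))
        } else {
          if (is.null(x)) next
          cbind(variance_disparity(x, members, met),
                ci_lo = NA_real_, ci_hi = NA_real_, n_boot = 0L)[,
                  c("metric", "estimate", "ci_lo", "ci_hi", "n", "n_boot")]
        }
        rows[[length(rows) + 1L]] <- cbind(bin = bn, clade = g, row)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("disparity_curve", "data.frame")
  out
}

# Pseudo-F values for an n x P matrix of group labelings, from squared
# distances: SS_total = sum_{i<j} d2 / n, SS_within = sum_g (within-group
# pair sum of d2) / n_g, F = (SS_among/(a-1)) / (SS_within/(n-a)).
pseudo_f <- function(d2, labelings) {
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  apply(labelings, 2L, function(g) {
    a <- length(unique(g))
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  })
}

#' Permutational (non-parametric) MANOVA on a distance matrix
#'
#' One-way distance-based ANOVA partition: the pseudo-F compares
#' among-group to within-group sums of squared distances, and its null
#' distribution is obtained by permuting group labels. The p-value uses the
#' add-one estimator `(1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param d a `distance_matrix`.
#' @param groups group label per row of `d` (>= 2 groups of >= 2 members).
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed.
#' @return object of class `permanova`: list with `f`, `p`, `n_perm`,
#'   `groups`.
#' @export
npmanova <- function(d, groups, n_perm = 9999L, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("every group needs at least two members")
  d2 <- dm^2
  f_obs <- pseudo_f(d2, matrix(groups, ncol = 1L))
  set.seed(seed)
  # vectorised permutations: indicator algebra per group level
  perms <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  sst <- sum(d2[upper.tri(d2)]) / n
  a <- length(tab)
  ssw_perm <- numeric(n_perm)
  for (lev in names(tab)) {
    members <- which(groups == lev)
    Z <- matrix(0, n, n_perm)
    Z[cbind(as.vector(perms[members, ]), rep(seq_len(n_perm), each = length(members)))] <- 1
    ssw_perm <- ssw_perm + colSums(Z * (d2 %*% Z)) / (2 * length(members))
  }
  f_perm <- ((sst - ssw_perm) / (a - 1)) / (ssw_perm / (n - a))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  structure(list(f = unname(f_obs), p = p, n_perm = as.integer(n_perm),
                 groups = tab), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("NPMANOVA: pseudo-F =", signif(x$f, 5), " p =", signif(x$p, 4),
      "(", x$n_perm, "permutations,", length(x$groups), "groups )\n")
  invisible(x)
}

#' Pairwise NPMANOVA with Bonferroni correction
#'
#' Runs [npmanova()] on every pair of groups; adjusted p-values multiply the
#' raw p by the number of comparisons (capped at 1). Pairs with a group of
#' fewer than two members are skipped with a message.
#'
#' @inheritParams npmanova
#' @return data frame: `group_a`, `group_b`, `f`, `p`, `p_bonferroni`, `n`.
#' @export
pairwise_npmanova <- function(d, groups, n_perm = 9999L, seed = 1L) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  levs <- unique(groups)
  pairs <- utils::combn(levs, 2L)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    sel <- groups %in% c(g1, g2)
    if (sum(groups == g1) < 2L || sum(groups == g2) < 2L) {
      message("pairwise_npmanova: skipping ", g1, " vs ", g2,
              " (group with < 2 members)")
      next
    }
    fit <- npmanova(dm[sel, sel, drop = FALSE], groups[sel],
                    n_perm = n_perm, seed = seed + j)
    rows[[length(rows) + 1L]] <-
      data.frame(group_a = g1, group_b = g2, f = fit$f, p = fit$p,
                 n = sum(sel), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no valid group pairs")
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[, c("group_a", "group_b", "f", "p", "p_bonferroni", "n")]
}

#' Distance between clade centroids per time bin
#'
#' Euclidean distance between the mean vectors of two clades' members in
#' each bin of a membership table.
#'
#' @param x data matrix (scores, aligned coordinates or characters) with
#'   taxon row names.
#' @param membership a `bin_membership`.
#' @param clade_a,clade_b the two clades to compare.
#' @return data frame: `bin`, `clade_a`, `clade_b`, `distance` (NA where a
#'   clade is absent), `n_a`, `n_b`.
#' @export
centroid_divergence <- function(x, membership, clade_a, clade_b) {
  stopifnot(inherits(membership, "bin_membership"))
  x <- unclass(as.matrix(x))
  bins <- attr(membership, "bins")
  rows <- lapply(bins$bin, function(bn) {
    here <- membership[membership$bin == bn, , drop = FALSE]
    ma <- unique(here$taxon_id[here$clade == clade_a])
    mb <- unique(here$taxon_id[here$clade == clade_b])
    dd <- if (length(ma) && length(mb)) {
      ca <- colMeans(x[ma, , drop = FALSE])
      cb <- colMeans(x[mb, , drop = FALSE])
      sqrt(sum((ca - cb)^2))
    } else NA_real_
    data.frame(bin = bn, clade_a = clade_a, clade_b = clade_b, distance = dd,
               n_a = length(ma), n_b = length(mb), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Signed shoelace area of polygon vertices in order.
polygon_area <- function(v) {
  if (nrow(v) < 3L) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Convex-hull morphospace occupancy per bin and clade
#'
#' @param scores two-column score matrix (e.g. PC1-PC2) with taxon row
#'   names.
#' @param membership a `bin_membership`.
#' @return list with `hulls` (per bin/clade vertex data frame) and `areas`
#'   (data frame `bin`, `clade`, `n`, `area`; fewer than 3 distinct points
#'   gives a degenerate hull of area 0).
#' @export
timeslice_occupancy <- function(scores, membership) {
  stopifnot(inherits(membership, "bin_membership"))
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  bins <- attr(membership, "bins")
  hull_rows <- list(); area_rows <- list()
  for (bn in bins$bin) {
    here <- membership[membership$bin == bn, , drop = FALSE]
    for (cl in c("all", unique(here$clade))) {
      members <- if (cl == "all") unique(here$taxon_id)
                 else unique(here$taxon_id[here$clade == cl])
      if (!length(members)) next
      pts <- scores[members, , drop = FALSE]
      hidx <- grDevices::chull(pts[, 1], pts[, 2])
      verts <- pts[hidx, , drop = FALSE]
      area_rows[[length(area_rows) + 1L]] <-
        data.frame(bin = bn, clade = cl, n = length(members),
                   area = polygon_area(verts), stringsAsFactors = FALSE)
      hull_rows[[length(hull_rows) + 1L]] <-
        data.frame(bin = bn, clade = cl,
                   taxon_id = members[hidx], x = verts[, 1], y = verts[, 2],
                   stringsAsFactors = FALSE)
    }
  }
  list(hulls = do.call(rbind, hull_rows), areas = do.call(rbind, area_rows))
}
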