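#' Euclidean distance matrix of a taxon-by-character matrix
#'
#' @param x numeric matrix (e.g. an `sfmd`), taxa as rows; no missing cells.
#' @return full symmetric matrix of class `distance_matrix` with a `metric`
#'   attribute.
#' @export
euclidean_distance_matrix <- function(x) {
  x <- unclass(as.matrix(x))
  if (anyNA(x)) stop("missing cells in distance input")
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  structure(d, metric = "euclidean", class = c("distance_matrix", "matrix", "array"))
}

partition <- function(method, k, labels, objective, seed = NA_integer_,
                      extra = list()) {
  if (any(tabulate(labels, k) == 0L)) stop("empty cluster in partition")
  structure(c(list(method = method, k = as.integer(k),
                   labels = labels, objective = objective, seed = seed), extra),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("cluster_partition:", x$method, "k =", x$k, "n =", length(x$labels), "\n")
  invisible(x)
}

#' Agglomerative hierarchical clustering cut at k groups
#'
#' Ward linkage (`ward.D2`, i.e. Ward on squared Euclidean distances) by
#' default.
#'
#' @param d a `distance_matrix` (or any symmetric matrix / `dist`).
#' @param k number of clusters, `2 <= k <= n` (`k = n` gives singletons).
#' @param linkage linkage passed to [stats::hclust()].
#' @return `cluster_partition` with the merge heights as objective and the
#'   `hclust` tree in `$tree`.
#' @export
hierarchical_cluster <- function(d, k, linkage = "ward.D2") {
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  if (k < 2L || k > n) stop("k out of range [2, ", n, "]")
  tree <- stats::hclust(dd, method = linkage)
  labels <- stats::cutree(tree, k = k)
  partition("hierarchical", k, labels, objective = tree$height,
            extra = list(tree = tree, linkage = linkage))
}

#' K-means clustering (best of several random starts)
#'
#' @param x numeric matrix, observations as rows.
#' @param k number of clusters.
#' @param seed RNG seed (the run is deterministic given the seed).
#' @param n_starts random initialisations; the lowest within-cluster
#'   sum-of-squares solution is kept.
#' @return `cluster_partition` with the total within-cluster SS as objective
#'   and `$centers`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, n_starts = 25L) {
  x <- unclass(as.matrix(x))
  if (k < 1L || k > nrow(x)) stop("k out of range [1, ", nrow(x), "]")
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = n_starts, iter.max = 100L)
  labels <- stats::setNames(km$cluster, rownames(x))
  partition("kmeans", k, labels, objective = km$tot.withinss, seed = seed,
            extra = list(centers = km$centers))
}

#' Partitioning around medoids
#'
#' BUILD + SWAP (via [cluster::pam()]); medoids are input points; the
#' objective is the total dissimilarity of points to their assigned medoids.
#'
#' @param d a `distance_matrix` (or `dist`).
#' @param k number of clusters.
#' @param seed recorded for provenance (PAM on a dissimilarity is
#'   deterministic).
#' @return `cluster_partition` with `$medoids` (indices into the input).
#' @export
pam_cluster <- function(d, k, seed = 1L) {
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  if (k < 2L || k > n) stop("k out of range [2, ", n, "]")
  fit <- cluster::pam(dd, k = k, diss = TRUE)
  labels <- fit$clustering
  if (!is.null(rownames(as.matrix(d)))) names(labels) <- rownames(as.matrix(d))
  partition("pam", k, labels, objective = fit$objective[["swap"]] * n,
            seed = seed, extra = list(medoids = as.integer(fit$id.med)))
}

# Pooled within-cluster dispersion W_k: for Euclidean data this is the total
# within-cluster sum of squared deviations from cluster centroids, equal to
# sum_r (sum of squared pairwise distances in r) / (2 n_r).
within_dispersion <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2L, colMeans(xs))^2)
  }, numeric(1)))
}

cluster_labels_for <- function(x, method, k, linkage, n_starts, seed) {
  switch(method,
    hierarchical = stats::cutree(stats::hclust(stats::dist(x), method = linkage), k),
    kmeans = stats::kmeans(x, centers = k, nstart = n_starts, iter.max = 100L)$cluster,
    pam = cluster::pam(stats::dist(x), k = k, diss = TRUE)$clustering,
    stop("unknown clustering method: ", method))
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares the log pooled within-cluster dispersion of the data with its
#' expectation under `B` reference data sets drawn uniformly within the
#' principal-axis-aligned bounding box of the data.
#' `Gap(k) = mean_b log W*_kb - log W_k`, with standard error
#' `s_k = sd_b(log W*_kb) sqrt(1 + 1/B)`. The number of clusters is chosen
#' by the 1-SE rule: the smallest k in range with
#' `Gap(k) >= Gap(k+1) - s_{k+1}`, falling back to the arg-max of the gap
#' when the rule never fires.
#'
#' @param x numeric matrix, observations as rows.
#' @param method clustering method applied to data and references.
#' @param k_range candidate cluster counts (default 4:10).
#' @param B number of reference (bootstrap) data sets.
#' @param seed RNG seed.
#' @param linkage,n_starts method parameters.
#' @return object of class `gap_curve`: data frame columns `k`, `logW`,
#'   `ElogW`, `gap`, `se`, plus attributes `chosen_k`, `B`, `rule`.
#' @export
gap_statistic <- function(x, method = c("kmeans", "hierarchical", "pam"),
                          k_range = 4:10, B = 100L, seed = 1L,
                          linkage = "ward.D2", n_starts = 5L) {
  method <- match.arg(method)
  x <- unclass(as.matrix(x))
  n <- nrow(x)
  if (B < 1L) stop("B must be >= 1")
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("k_range must lie within 2 .. n-1")
  if (all(stats::dist(x) < 1e-12)) stop("degenerate data: all points identical")
  set.seed(seed)

  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  V <- svd(xc, nu = 0)$v
  xr <- xc %*% V
  lo <- apply(xr, 2L, min); hi <- apply(xr, 2L, max)

  logW <- vapply(k_range, function(k)
    log(within_dispersion(x, cluster_labels_for(x, method, k, linkage, n_starts,
                                                seed))), numeric(1))
  logWstar <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    z <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
    ref <- sweep(z %*% t(V), 2L, ctr, `+`)
    logWstar[b, ] <- vapply(k_range, function(k)
      log(within_dispersion(ref, cluster_labels_for(ref, method, k, linkage,
                                                    n_starts, seed))), numeric(1))
  }
  gap <- colMeans(logWstar) - logW
  se <- apply(logWstar, 2L, stats::sd) * sqrt(1 + 1 / B)

  chosen <- NA_integer_; rule <- "argmax"
  for (i in seq_along(k_range)[-length(k_range)]) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) {
      chosen <- k_range[i]; rule <- "firstSEmax"; break
    }
  }
  if (is.na(chosen)) chosen <- k_range[which.max(gap)]
  out <- data.frame(k = k_range, logW = logW, ElogW = colMeans(logWstar),
                    gap = gap, se = se)
  structure(out, chosen_k = chosen, B = B, rule = rule, method = method,
            class = c("gap_curve", "data.frame"))
}

#' @export
print.gap_curve <- function(x, ...) {
  cat("gap_curve (", attr(x, "method"), ", B = ", attr(x, "B"),
      "): chosen k = ", attr(x, "chosen_k"), " by ", attr(x, "rule"), "\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Silhouette widths of a partition
#'
#' `s(i) = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean distance of i to
#' its own cluster's other members and `b_i` the smallest mean distance to
#' another cluster. Members of singleton clusters score 0.
#'
#' @param d a `distance_matrix`.
#' @param p a `cluster_partition` (or bare label vector).
#' @return list with `widths` (per point), `cluster_means`, `overall`.
#' @export
silhouette_widths <- function(d, p) {
  labels <- if (inherits(p, "cluster_partition")) p$labels else p
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette undefined for a single cluster")
  idx <- split(seq_len(n), labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- idx[[as.character(labels[i])]]
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(ks[ks != labels[i]], function(g)
      mean(d[i, idx[[as.character(g)]]]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  cl_means <- vapply(idx, function(ii) mean(s[ii]), numeric(1))
  list(widths = stats::setNames(s, rownames(d)), cluster_means = cl_means,
       overall = mean(s))
}

#' External validation of a partition against reference labels
#'
#' Adjusted Rand index (chance-corrected pair agreement) and variation of
#' information (in nats) from the contingency table of the two labelings.
#'
#' @param p a `cluster_partition` or label vector.
#' @param reference reference labels over the same items, in the same order
#'   (e.g. taxonomic groups).
#' @return list with `adjusted_rand` and `vi`.
#' @export
external_validation <- function(p, reference) {
  a <- if (inherits(p, "cluster_partition")) p$labels else p
  if (length(a) != length(reference))
    stop("labelings cover different numbers of items")
  if (!is.null(names(a)) && !is.null(names(reference))) {
    if (!setequal(names(a), names(reference)))
      stop("labelings cover different item sets")
    reference <- reference[names(a)]
  }
  tab <- table(a, reference)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  ari <- if (abs(max_index - expected) < 1e-300) 1
         else (sum_ij - expected) / (max_index - expected)
  pij <- tab / n
  pi_ <- rowSums(pij); pj <- colSums(pij)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- sum(pij[pij > 0] * log(pij[pij > 0] /
                               (pi_[row(pij)[pij > 0]] * pj[col(pij)[pij > 0]])))
  list(adjusted_rand = ari, vi = max(0, h(pi_) + h(pj) - 2 * mi))
}

# Match the labels of partition `b` onto reference labels of `a` by maximum
# overlap on the contingency table: greedy by default, exact (all label
# permutations) when exact = TRUE and k <= 8.
match_labels <- function(a, b, exact = FALSE) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  tab <- table(factor(b, levels = lb), factor(a, levels = la))
  if (exact && length(lb) == length(la)) {
    if (length(lb) > 8L) stop("exact matching limited to k <= 8")
    perms <- permutations_of(seq_along(la))
    scores <- vapply(seq_len(nrow(perms)), function(r)
      sum(tab[cbind(seq_along(lb), perms[r, ])]), numeric(1))
    best <- perms[which.max(scores), ]
    map <- stats::setNames(la[best], lb)
  } else {
    map_idx <- rep(NA_integer_, length(lb))
    t2 <- tab
    while (any(!is.na(t2)) && anyNA(map_idx)) {
      pos <- which(t2 == max(t2, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      map_idx[pos[1L]] <- pos[2L]
      t2[pos[1L], ] <- NA; t2[, pos[2L]] <- NA
    }
    left <- which(is.na(map_idx))
    unused <- setdiff(seq_along(la), map_idx)
    for (i in seq_along(left))
      map_idx[left[i]] <- if (i <= length(unused)) unused[i] else 1L
    map <- stats::setNames(la[map_idx], lb)
  }
  unname(map[as.character(b)])
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], permutations_of(v[-i]))))
}

#' Consensus functional feeding groups across three clusterings
#'
#' Labels of the k-means and PAM partitions are matched onto the
#' hierarchical labels by maximum contingency overlap; taxa on which all
#' three matched labelings agree form the core groups, disagreeing taxa are
#' flagged inconsistent. When a distance matrix is supplied, each
#' inconsistent taxon is attached (flag retained) to the group of its
#' nearest consistent neighbour for reporting.
#'
#' @param partitions list of three `cluster_partition`s over the same taxa.
#' @param d optional `distance_matrix` for nearest-core attachment.
#' @param guild_names optional character vector naming groups 1..k.
#' @param exact use exact (permutation) label matching instead of greedy.
#' @return data frame of class `consensus_guilds`: `taxon_id`, `ffg`,
#'   `ffsg` (NA until [subcluster_guild()]), `consistent`.
#' @export
build_consensus_guilds <- function(partitions, d = NULL, guild_names = NULL,
                                   exact = FALSE) {
  if (length(partitions) < 3L) stop("need three partitions for a consensus")
  labs <- lapply(partitions, function(p)
    if (inherits(p, "cluster_partition")) p$labels else p)
  n <- length(labs[[1L]])
  if (!all(vapply(labs, length, integer(1)) == n))
    stop("partitions cover different taxon sets")
  ids <- names(labs[[1L]])
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  ref <- labs[[1L]]
  matched <- lapply(labs[-1L], function(b) match_labels(ref, b, exact = exact))
  agree <- Reduce(`&`, lapply(matched, function(m) m == ref))
  if (!any(agree)) stop("no taxon consistent across the three methods")
  ffg <- as.character(ref)
  consistent <- agree
  if (!is.null(d) && any(!agree)) {
    dm <- as.matrix(d)
    core <- which(agree)
    for (i in which(!agree)) {
      nn <- core[which.min(dm[i, core])]
      ffg[i] <- as.character(ref[nn])
    }
  }
  if (!is.null(guild_names)) {
    lev <- sort(unique(as.character(ref)))
    if (length(guild_names) < length(lev))
      stop("fewer guild names than groups")
    ffg <- guild_names[match(ffg, lev)]
  }
  out <- data.frame(taxon_id = ids, ffg = ffg, ffsg = NA_character_,
                    consistent = consistent, stringsAsFactors = FALSE)
  class(out) <- c("consensus_guilds", "data.frame")
  out
}

#' Run the full guild-definition pipeline on a character matrix
#'
#' Euclidean distances, gap-statistic choice of k, the three clusterings at
#' that k, and the consensus.
#'
#' @param x numeric matrix (typically an `sfmd`).
#' @param k_range candidate cluster counts.
#' @param B gap-statistic reference sets.
#' @param seed RNG seed.
#' @param gap_method method used inside the gap statistic.
#' @param guild_names optional names for the consensus groups.
#' @param linkage,n_starts method parameters.
#' @return list with `guilds`, `gap`, `partitions`, `d`, `k`.
#' @export
consensus_pipeline <- function(x, k_range = 4:10, B = 100L, seed = 1L,
                               gap_method = "kmeans", guild_names = NULL,
                               linkage = "ward.D2", n_starts = 25L) {
  x <- unclass(as.matrix(x))
  d <- euclidean_distance_matrix(x)
  gap <- gap_statistic(x, method = gap_method, k_range = k_range, B = B,
                       seed = seed, linkage = linkage)
  k <- attr(gap, "chosen_k")
  parts <- list(hierarchical_cluster(d, k, linkage = linkage),
                kmeans_cluster(x, k, seed = seed + 1L, n_starts = n_starts),
                pam_cluster(d, k, seed = seed + 2L))
  guilds <- build_consensus_guilds(parts, d = d, guild_names = guild_names)
  list(guilds = guilds, gap = gap, partitions = parts, d = d, k = k)
}

#' Sub-cluster one guild into functional feeding subgroups
#'
#' Re-runs the full pipeline (distances, gap statistic, three clusterings,
#' consensus) on the members of one guild and writes subgroup labels into
#' the `ffsg` column for those taxa only.
#'
#' @param guilds a `consensus_guilds` table.
#' @param guild the guild (ffg label) to refine.
#' @param x the full character matrix (rows named by taxon).
#' @param k_range candidate subgroup counts (default 2:6).
#' @param B,seed,gap_method,subgroup_names,linkage,n_starts as in
#'   [consensus_pipeline()].
#' @return the updated `consensus_guilds` (sub-pipeline in attribute
#'   `"sub_pipeline"`).
#' @export
subcluster_guild <- function(guilds, guild, x, k_range = 2:6, B = 100L,
                             seed = 1L, gap_method = "kmeans",
                             subgroup_names = NULL, linkage = "ward.D2",
                             n_starts = 25L) {
  stopifnot(inherits(guilds, "consensus_guilds"))
  members <- guilds$taxon_id[guilds$ffg == guild]
  if (length(members) < max(k_range) + 1L)
    stop("guild '", guild, "' too small to sub-cluster (", length(members),
         " members, need > ", max(k_range), ")")
  x <- unclass(as.matrix(x))
  xs <- x[match(members, rownames(x)), , drop = FALSE]
  if (anyNA(xs)) stop("guild members missing from the character matrix")
  sub <- consensus_pipeline(xs, k_range = k_range, B = B, seed = seed,
                            gap_method = gap_method,
                            guild_names = subgroup_names,
                            linkage = linkage, n_starts = n_starts)
  sub_labels <- sub$guilds$ffg
  # default subgroup labels are namespaced by their parent guild so that
  # FFsG-resolution labels never collide with other guilds' FFG labels
  if (is.null(subgroup_names)) sub_labels <- paste0(guild, "/", sub_labels)
  guilds$ffsg[match(members, guilds$taxon_id)] <- sub_labels
  attr(guilds, "sub_pipeline") <- sub
  guilds
}

#' Majority functional feeding group of each clade
#'
#' Each clade is assigned the group holding the plurality of its consistent
#' taxa; ties (or clades with no consistent taxa) are reported as
#' `"unresolved"` rather than broken silently.
#'
#' @param guilds a `consensus_guilds` table.
#' @param clades named character vector (or data frame with `taxon_id`,
#'   `clade`) mapping each taxon to its clade.
#' @return named character vector, clade -> guild label or `"unresolved"`.
#' @export
assign_clade_guilds <- function(guilds, clades) {
  stopifnot(inherits(guilds, "consensus_guilds"))
  if (is.data.frame(clades))
    clades <- stats::setNames(clades$clade, clades$taxon_id)
  if (!all(guilds$taxon_id %in% names(clades)))
    stop("clade missing for some taxa")
  cl <- clades[guilds$taxon_id]
  out <- vapply(unique(cl), function(cc) {
    sel <- guilds$consistent & cl == cc
    if (!any(sel)) return("unresolved")
    tab <- sort(table(guilds$ffg[sel]), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) "unresolved" else names(tab)[1L]
  }, character(1))
  stats::setNames(out, unique(cl))
}
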