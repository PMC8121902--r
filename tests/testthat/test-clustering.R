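test_that("euclidean distances match trivial cases and a brute-force loop", {
  x <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- euclidean_distance_matrix(x)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
  expect_equal(diag(d), setNames(rep(0, 3), rownames(x)))

  set.seed(1)
  y <- matrix(rnorm(48), 6, 8)
  rownames(y) <- letters[1:6]
  d6 <- euclidean_distance_matrix(y)
  for (i in 1:6) for (j in 1:6)
    expect_equal(d6[i, j], sqrt(sum((y[i, ] - y[j, ])^2)))
  expect_equal(unclass(d6), t(unclass(d6)), tolerance = 1e-12)
})

test_that("hierarchical clustering recovers separated pairs and singletons", {
  x <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(10, 10), d = c(10.1, 10))
  d <- euclidean_distance_matrix(x)
  p2 <- hierarchical_cluster(d, 2)
  expect_equal(unname(p2$labels[c("a", "b")][1]), unname(p2$labels[["b"]]))
  expect_true(p2$labels[["a"]] != p2$labels[["c"]])
  pn <- hierarchical_cluster(d, 4)
  expect_equal(sort(unname(pn$labels)), 1:4)
  expect_error(hierarchical_cluster(d, 1), "range")
  expect_error(hierarchical_cluster(d, 9), "range")
  # merge heights monotone
  expect_true(all(diff(p2$tree$height) >= -1e-12))
})

test_that("hierarchical merges equal brute-force Ward agglomeration (n = 5)", {
  set.seed(2)
  x <- matrix(rnorm(10), 5, 2)
  d <- euclidean_distance_matrix(x)
  # independent naive agglomeration with the Lance-Williams Ward update on
  # squared distances; heights reported on the distance scale (ward.D2)
  D2 <- unclass(d)^2
  sizes <- rep(1, 5)
  active <- 1:5
  heights <- numeric(0)
  merged <- list()
  groups <- as.list(1:5)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in active) for (j in active) if (i < j && D2[i, j] < bestv) {
      bestv <- D2[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    merged[[length(merged) + 1]] <- sort(c(groups[[i]], groups[[j]]))
    for (k in setdiff(active, best)) {
      D2[i, k] <- D2[k, i] <-
        ((sizes[i] + sizes[k]) * D2[i, k] + (sizes[j] + sizes[k]) * D2[j, k] -
           sizes[k] * D2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    sizes[i] <- sizes[i] + sizes[j]
    groups[[i]] <- c(groups[[i]], groups[[j]])
    active <- setdiff(active, j)
  }
  tree <- hierarchical_cluster(d, 2)$tree
  expect_equal(tree$height, heights, tolerance = 1e-10)
  # same grouping sequence (compare the sets formed at each merge)
  hc_groups <- lapply(seq_len(nrow(tree$merge)), function(m) {
    unpack <- function(v) unlist(lapply(v, function(e)
      if (e < 0) -e else unpack(tree$merge[e, ])))
    sort(unpack(tree$merge[m, ]))
  })
  expect_equal(hc_groups, merged)
})

test_that("k-means descends, is seeded, and recovers separated blobs", {
  blobs <- make_blobs(10, rbind(c(0, 0), c(100, 100)), sd = 1, seed = 3)
  p <- kmeans_cluster(blobs$x, 2, seed = 42)
  expect_equal(external_validation(p, blobs$labels)$adjusted_rand, 1)
  # determinism given seed
  p2 <- kmeans_cluster(blobs$x, 2, seed = 42)
  expect_identical(p$labels, p2$labels)
  expect_identical(p$objective, p2$objective)
  # k = 1: centroid is the grand mean
  p1 <- kmeans_cluster(blobs$x, 1, seed = 1)
  expect_equal(as.numeric(p1$centers), colMeans(blobs$x), ignore_attr = TRUE)
  # returned objective consistent with its labels and no worse than random
  # label assignments (descent from any start)
  w <- guildspace:::within_dispersion(blobs$x, p$labels)
  expect_equal(w, p$objective, tolerance = 1e-8)
  set.seed(5)
  for (i in 1:50) {
    rand <- sample(1:2, nrow(blobs$x), replace = TRUE)
    if (length(unique(rand)) < 2) next
    expect_lte(p$objective,
               guildspace:::within_dispersion(blobs$x, rand) + 1e-8)
  }
})

test_that("pam equals exhaustive medoid search on small instances", {
  x <- rbind(a = c(0, 0), b = c(0.4, 0), c = c(9, 9), d = c(9.4, 9))
  d <- euclidean_distance_matrix(x)
  p <- pam_cluster(d, 2)
  # brute force over all C(4,2) medoid pairs
  dm <- unclass(d)
  combos <- combn(4, 2)
  costs <- apply(combos, 2, function(med) sum(pmin(dm[, med[1]], dm[, med[2]])))
  # the returned medoid set attains the brute-force optimum (ties possible
  # between near-coincident points, so compare costs, not indices)
  expect_equal(p$objective, min(costs), tolerance = 1e-10)
  expect_true(all(p$medoids %in% seq_len(nrow(x))))
  expect_equal(sum(pmin(dm[, p$medoids[1]], dm[, p$medoids[2]])),
               min(costs), tolerance = 1e-10)

  # an outlier does not drag the k = 2 medoids out of the blobs
  blobs <- make_blobs(6, rbind(c(0, 0), c(12, 0)), sd = 0.5, seed = 6)
  x2 <- rbind(blobs$x, outlier = c(6, 30))
  d2 <- euclidean_distance_matrix(x2)
  p2 <- pam_cluster(d2, 2)
  dm2 <- unclass(d2)
  combos2 <- combn(nrow(x2), 2)
  costs2 <- apply(combos2, 2, function(med)
    sum(pmin(dm2[, med[1]], dm2[, med[2]])))
  expect_equal(p2$objective, min(costs2), tolerance = 1e-10)
  expect_true(all(p2$medoids <= 12))  # both medoids inside the blobs
})

test_that("pam objective beats random medoid sets", {
  set.seed(7)
  x <- matrix(rnorm(60), 20, 3)
  d <- euclidean_distance_matrix(x)
  p <- pam_cluster(d, 4)
  dm <- unclass(d)
  for (i in 1:100) {
    med <- sample(20, 4)
    cost <- sum(apply(dm[, med, drop = FALSE], 1, min))
    expect_lte(p$objective, cost + 1e-9)
  }
})

test_that("gap statistic picks the planted k and falls to the range floor on noise", {
  centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0))
  hits <- 0
  for (s in 1:5) {
    blobs <- make_blobs(12, centers, sd = 1, seed = 100 + s)
    gc <- gap_statistic(blobs$x, method = "kmeans", k_range = 2:6, B = 60,
                        seed = s)
    expect_true(all(is.finite(gc$gap)))
    expect_true(all(gc$se > 0))
    if (attr(gc, "chosen_k") == 3) hits <- hits + 1
  }
  expect_gte(hits, 4)

  set.seed(9)
  noise <- matrix(rnorm(40 * 3), 40, 3)
  gc0 <- gap_statistic(noise, method = "kmeans", k_range = 2:6, B = 60, seed = 2)
  expect_equal(attr(gc0, "chosen_k"), 2L)
  expect_error(gap_statistic(matrix(1, 10, 2), k_range = 2:4), "degenerate")
})

test_that("gap dispersion agrees with pair-sum brute force and clusGap", {
  set.seed(10)
  x <- matrix(rnorm(24), 12, 2)
  labels <- rep(1:3, each = 4)
  # W via sum of within-cluster pairwise squared distances / (2 n_r)
  dm <- as.matrix(dist(x))^2
  brute <- sum(vapply(split(1:12, labels), function(idx)
    sum(dm[idx, idx]) / (2 * length(idx)), numeric(1)))
  expect_equal(guildspace:::within_dispersion(x, labels), brute,
               tolerance = 1e-10)
  # logW against cluster::clusGap with the same deterministic clusterer
  hfun <- function(x, k)
    list(cluster = cutree(hclust(dist(x), method = "ward.D2"), k))
  cg <- cluster::clusGap(x, FUNcluster = hfun, K.max = 4, B = 5,
                         d.power = 2, verbose = FALSE)
  # clusGap's W carries an extra factor 1/2 relative to the pooled
  # within-cluster sum of squares; identical up to that constant
  mine <- gap_statistic(x, method = "hierarchical", k_range = 2:4, B = 5,
                        seed = 1)
  expect_equal(mine$logW, unname(cg$Tab[2:4, "logW"]) + log(2),
               tolerance = 1e-8)
})

test_that("silhouettes match brute force, cluster::silhouette, and behave", {
  blobs <- make_blobs(6, rbind(c(0, 0), c(20, 0)), sd = 0.5, seed = 11)
  d <- euclidean_distance_matrix(blobs$x)
  sil <- silhouette_widths(d, blobs$labels)
  expect_true(all(sil$widths >= -1 & sil$widths <= 1))
  expect_gt(sil$overall, 0.9)
  # brute force per point
  dm <- unclass(d)
  for (i in seq_len(nrow(dm))) {
    own <- setdiff(which(blobs$labels == blobs$labels[i]), i)
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(unique(blobs$labels), blobs$labels[i]),
                    function(g) mean(dm[i, blobs$labels == g]), numeric(1)))
    expect_equal(unname(sil$widths[i]), (b - a) / max(a, b), tolerance = 1e-12)
  }
  ref <- cluster::silhouette(blobs$labels, dist(blobs$x))
  expect_equal(unname(sil$widths), unname(ref[, "sil_width"]), tolerance = 1e-10)
  # a mislabelled point gets a negative width
  wrong <- blobs$labels
  wrong[1] <- 2
  silw <- silhouette_widths(d, wrong)
  expect_lt(silw$widths[1], 0)
  expect_error(silhouette_widths(d, rep(1, 12)), "single")
})

test_that("external validation matches the closed-form ARI and VI", {
  a <- c(1, 1, 1, 2, 2, 2, 3, 3)
  expect_equal(external_validation(a, a), list(adjusted_rand = 1, vi = 0))
  # label-permutation invariance
  b <- c(2, 2, 2, 3, 3, 3, 1, 1)
  expect_equal(external_validation(a, b)$adjusted_rand, 1)
  # fixed 3x2 contingency toy, closed form evaluated independently:
  # clusters a = (1,1,2,2,2,3,3,3), reference = (1,1,1,2,2,2,1,2)
  x <- c(1, 1, 2, 2, 2, 3, 3, 3)
  y <- c(1, 1, 1, 2, 2, 2, 1, 2)
  ch2 <- function(n) n * (n - 1) / 2
  tab <- table(x, y)
  sum_ij <- sum(ch2(tab)); sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(8)
  ari_hand <- (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
  got <- external_validation(x, y)
  expect_equal(got$adjusted_rand, ari_hand, tolerance = 1e-12)
  expect_equal(got$adjusted_rand, mclust::adjustedRandIndex(x, y),
               tolerance = 1e-12)
  # VI from entropies, by hand
  p <- tab / 8
  H <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  mi <- H(rowSums(p)) + H(colSums(p)) - H(as.numeric(p))
  expect_equal(got$vi, H(rowSums(p)) + H(colSums(p)) - 2 * mi,
               tolerance = 1e-12)
  expect_error(external_validation(a, c(1, 2)), "different")
})

test_that("consensus of identical partitions is that partition; single moves flag", {
  labels <- setNames(rep(1:3, each = 4), sprintf("t%02d", 1:12))
  parts <- list(labels, labels, labels)
  g <- build_consensus_guilds(parts)
  expect_true(all(g$consistent))
  expect_equal(external_validation(setNames(g$ffg, g$taxon_id),
                                   labels)$adjusted_rand, 1)
  # move one taxon in exactly one method
  moved <- labels
  moved["t01"] <- 2
  g2 <- build_consensus_guilds(list(labels, moved, labels))
  expect_false(g2$consistent[g2$taxon_id == "t01"])
  expect_true(all(g2$consistent[g2$taxon_id != "t01"]))
  expect_error(build_consensus_guilds(parts[1:2]), "three")
})

test_that("greedy and exact label matching agree on clean relabelings", {
  labels <- rep(1:4, each = 5)
  shuffled <- c(3, 1, 4, 2)[labels]
  expect_true(all(guildspace:::match_labels(labels, shuffled) == labels))
  expect_true(all(guildspace:::match_labels(labels, shuffled, exact = TRUE) ==
                    labels))
})

test_that("consensus pipeline recovers planted guilds", {
  cfg <- synthetic_config(seed = 21, n_taxa = 136, n_guilds = 5, separation = 6)
  fun <- suppressMessages(generate_functional_table(cfg))
  sfmd <- z_standardize(fun$characters)
  fit <- consensus_pipeline(sfmd, k_range = 4:7, B = 50, seed = 21)
  truth <- setNames(fun$truth$guild, fun$truth$taxon_id)
  # FFGs are defined on the consistent core (disagreeing taxa are flagged,
  # not part of the group definition)
  core <- fit$guilds$consistent
  expect_gte(external_validation(
    setNames(fit$guilds$ffg[core], fit$guilds$taxon_id[core]),
    truth[fit$guilds$taxon_id[core]])$adjusted_rand, 0.9)
  # at wider separation recovery is near perfect
  cfg8 <- synthetic_config(seed = 22, n_taxa = 136, n_guilds = 5,
                           separation = 8)
  fun8 <- suppressMessages(generate_functional_table(cfg8))
  fit8 <- consensus_pipeline(z_standardize(fun8$characters), k_range = 4:7,
                             B = 50, seed = 22)
  expect_gte(external_validation(setNames(fit8$guilds$ffg, fit8$guilds$taxon_id),
                                 setNames(fun8$truth$guild,
                                          fun8$truth$taxon_id))$adjusted_rand,
             0.95)
  # inconsistent taxa are attached to a neighbour's guild but stay flagged
  expect_true(all(!is.na(fit$guilds$ffg)))
  # determinism of the full pipeline under a fixed seed
  fit2 <- consensus_pipeline(sfmd, k_range = 4:7, B = 50, seed = 21)
  expect_identical(fit$guilds, fit2$guilds)
})

test_that("named guilds use the supplied label set", {
  labels <- setNames(rep(1:5, each = 3), sprintf("t%02d", 1:15))
  names5 <- c("ingestion generalist", "prehension specialist",
              "durophagous specialist", "shearing pulper",
              "heavy oral processor")
  g <- build_consensus_guilds(list(labels, labels, labels),
                              guild_names = names5)
  expect_setequal(unique(g$ffg), names5)
})

test_that("sub-clustering recovers planted subgroups and leaves others NA", {
  # one big guild with 3 planted subclusters + one far-away small guild
  sub_centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0))
  blobs <- make_blobs(10, sub_centers, sd = 1, seed = 31)
  far <- matrix(rnorm(4 * 3, 100), 4, 3)
  rownames(far) <- sprintf("f%02d", 1:4)
  x <- rbind(blobs$x, far)
  labels <- setNames(c(rep("big", 30), rep("small", 4)), rownames(x))
  parts <- list(labels, labels, labels)
  g <- build_consensus_guilds(parts)
  g2 <- subcluster_guild(g, "big", x, k_range = 2:4, B = 40, seed = 31)
  expect_true(all(is.na(g2$ffsg[g2$ffg == "small"])))
  sub <- g2$ffsg[match(rownames(blobs$x), g2$taxon_id)]
  expect_equal(length(unique(sub)), 3L)
  expect_gte(external_validation(setNames(sub, rownames(blobs$x)),
                                 setNames(blobs$labels, rownames(blobs$x)))$adjusted_rand,
             0.95)
  # subgroup labels never collide with other guilds' labels
  expect_length(intersect(unique(na.omit(g2$ffsg)), unique(g2$ffg)), 0)
  expect_error(subcluster_guild(g, "small", x, k_range = 2:4), "too small")
  # subsetting preserves pairwise distances
  d_full <- euclidean_distance_matrix(x)
  d_sub <- euclidean_distance_matrix(blobs$x)
  expect_equal(d_full[rownames(blobs$x), rownames(blobs$x)],
               unclass(d_sub), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("clade guild assignment takes pluralities and reports ties", {
  g <- build_consensus_guilds(list(
    setNames(c(1, 1, 1, 2, 1, 2, 1, 2), letters[1:8]),
    setNames(c(1, 1, 1, 2, 1, 2, 1, 2), letters[1:8]),
    setNames(c(1, 1, 1, 2, 1, 2, 1, 2), letters[1:8])))
  clades <- setNames(c("A", "A", "A", "A", "B", "B", "C", "C"), letters[1:8])
  map <- assign_clade_guilds(g, clades)
  expect_equal(unname(map["A"]), "1")     # 3 of 4 in guild 1
  expect_equal(unname(map["B"]), "unresolved")  # 1-1 tie
  expect_equal(unname(map["C"]), "unresolved")  # 1-1 tie
  # planted clade->guild map at full fidelity
  cfg <- synthetic_config(seed = 41, n_taxa = 44, guild_fidelity = 1)
  fun <- suppressMessages(generate_functional_table(cfg))
  g2 <- build_consensus_guilds(list(
    setNames(fun$truth$guild, fun$truth$taxon_id),
    setNames(fun$truth$guild, fun$truth$taxon_id),
    setNames(fun$truth$guild, fun$truth$taxon_id)))
  map2 <- assign_clade_guilds(g2, setNames(fun$truth$subclade,
                                           fun$truth$taxon_id))
  home <- vapply(split(fun$truth$guild, fun$truth$subclade),
                 function(v) as.character(v[1]), character(1))
  expect_equal(unname(map2[names(home)]), unname(home))
})
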