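test_that("range-through binning spans first to last appearance", {
  bins <- default_time_bins()
  taxa <- data.frame(taxon_id = "x", clade = "A",
                     first_bin = "Induan", last_bin = "Anisian",
                     diet = "herbivore")
  mb <- bin_taxa(taxa, bins)
  expect_equal(as.character(mb$bin), c("Induan", "Olenekian", "Anisian"))
  # single-bin range
  taxa$last_bin <- "Induan"
  expect_equal(nrow(bin_taxa(taxa, bins)), 1L)
  # occurrence-only binning keeps endpoints only
  taxa$last_bin <- "Anisian"
  mb2 <- bin_taxa(taxa, bins, range_through = FALSE)
  expect_equal(as.character(mb2$bin), c("Induan", "Anisian"))
  taxa$first_bin <- "Rhaetian"
  expect_error(bin_taxa(taxa, bins), "first_bin after last_bin")
  taxa$first_bin <- "Wuchiapingian"
  expect_error(bin_taxa(taxa, bins), "unknown")
})

test_that("a 10-taxon membership table equals hand enumeration", {
  bins <- as_time_bins(data.frame(bin = c("b1", "b2", "b3", "b4"),
                                  start_ma = 4:1, end_ma = 3:0))
  set.seed(12)
  first <- sample(1:4, 10, replace = TRUE)
  last <- pmin(first + sample(0:2, 10, replace = TRUE), 4)
  taxa <- data.frame(taxon_id = sprintf("t%02d", 1:10), clade = "A",
                     first_bin = bins$bin[first], last_bin = bins$bin[last])
  mb <- bin_taxa(taxa, bins)
  hand <- do.call(rbind, lapply(1:10, function(i)
    data.frame(bin = bins$bin[first[i]:last[i]],
               taxon_id = sprintf("t%02d", i))))
  got <- as.data.frame(mb)[, c("bin", "taxon_id")]
  got$bin <- as.character(got$bin)
  hand <- hand[order(match(hand$bin, bins$bin), hand$taxon_id), ]
  rownames(hand) <- rownames(got) <- NULL
  expect_equal(got, hand)
})

test_that("MPD matches trivial geometry and a brute-force double loop", {
  x <- rbind(a = c(0, 0), b = c(2, 0))
  d <- euclidean_distance_matrix(x)
  expect_equal(disparity_mpd(d, c("a", "b"), B = 0)$estimate, 2)
  # equilateral triangle, side s
  s <- 1.7
  tri <- rbind(a = c(0, 0), b = c(s, 0), c = c(s / 2, s * sqrt(3) / 2))
  expect_equal(disparity_mpd(euclidean_distance_matrix(tri),
                             c("a", "b", "c"), B = 0)$estimate, s)
  # 6-taxon brute force
  set.seed(13)
  y <- matrix(rnorm(36), 6, 6)
  rownames(y) <- letters[1:6]
  dy <- euclidean_distance_matrix(y)
  acc <- 0; np <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    acc <- acc + sqrt(sum((y[i, ] - y[j, ])^2)); np <- np + 1
  }
  row <- disparity_mpd(dy, letters[1:6], B = 500, seed = 1)
  expect_equal(row$estimate, acc / np, tolerance = 1e-12)
  expect_true(row$ci_lo <= row$estimate && row$estimate <= row$ci_hi)
  # MPD invariant to member order and to isometry
  expect_equal(disparity_mpd(dy, rev(letters[1:6]), B = 0)$estimate,
               row$estimate)
  y_iso <- sweep(y, 2, rnorm(6), `+`)
  expect_equal(disparity_mpd(euclidean_distance_matrix(y_iso),
                             letters[1:6], B = 0)$estimate, row$estimate,
               tolerance = 1e-10)
})

test_that("bootstrap CIs stabilise across seeds at large B", {
  set.seed(14)
  y <- matrix(rnorm(40), 10, 4)
  rownames(y) <- sprintf("t%02d", 1:10)
  d <- euclidean_distance_matrix(y)
  r1 <- disparity_mpd(d, rownames(y), B = 10000, seed = 1)
  r2 <- disparity_mpd(d, rownames(y), B = 10000, seed = 2)
  expect_lt(abs(r1$ci_lo - r2$ci_lo) / r1$estimate, 0.02)
  expect_lt(abs(r1$ci_hi - r2$ci_hi) / r1$estimate, 0.02)
  # single member: missing estimate
  expect_true(is.na(suppressMessages(disparity_mpd(d, "t01"))$estimate))
})

test_that("variance disparity matches closed forms and is translation invariant", {
  x <- rbind(a = c(1, 1), b = c(1, 1), c = c(1, 1))
  expect_equal(variance_disparity(x, rownames(x), "sum_of_variances")$estimate, 0)
  # two points: sum of variances is half the squared distance
  y <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(variance_disparity(y, c("a", "b"), "sum_of_variances")$estimate,
               25 / 2)
  # procrustes variance: mean squared distance to the mean (n denominator)
  expect_equal(variance_disparity(y, c("a", "b"), "procrustes_variance")$estimate,
               2 * (2.5^2) / 2)
  set.seed(15)
  z <- matrix(rnorm(30), 6, 5)
  rownames(z) <- letters[1:6]
  shift <- sweep(z, 2, runif(5), `+`)
  for (m in c("sum_of_variances", "procrustes_variance"))
    expect_equal(variance_disparity(z, letters[1:6], m)$estimate,
                 variance_disparity(shift, letters[1:6], m)$estimate,
                 tolerance = 1e-10)
})

test_that("npmanova p saturates under huge separation and matches adonis2 F", {
  blobs <- make_blobs(8, rbind(c(0, 0, 0), c(40, 0, 0)), sd = 1, seed = 16)
  d <- euclidean_distance_matrix(blobs$x)
  fit <- npmanova(d, blobs$labels, n_perm = 199, seed = 1)
  expect_equal(fit$p, 1 / 200)
  # pseudo-F equals vegan::adonis2 on the same distances
  ad <- vegan::adonis2(dist(blobs$x) ~ g,
                       data = data.frame(g = factor(blobs$labels)),
                       permutations = 2)
  expect_equal(fit$f, ad$F[1], tolerance = 1e-8)
  # duplicating every row (and its group) leaves the pseudo-F structure valid:
  # equal groups from one distribution give F near 1
  expect_error(npmanova(d, rep(1, 16)), "two groups")
  expect_error(npmanova(d, c(1, rep(2, 15))), "at least two members")
})

test_that("duplicating the points leaves the pseudo-F numerator/denominator ratio stable", {
  set.seed(17)
  x <- matrix(rnorm(24), 8, 3)
  g <- rep(1:2, each = 4)
  f1 <- npmanova(euclidean_distance_matrix(x), g, n_perm = 9, seed = 1)$f
  x2 <- rbind(x, x)
  f2 <- npmanova(euclidean_distance_matrix(x2), c(g, g), n_perm = 9, seed = 1)$f
  # among/within mean squares both scale; F changes only through the
  # degrees of freedom ratio, recomputed here independently
  d2 <- as.matrix(dist(x))^2
  sst <- sum(d2[upper.tri(d2)]) / 8
  ssw <- sum(d2[1:4, 1:4]) / 8 + sum(d2[5:8, 5:8]) / 8
  expect_equal(f1, ((sst - ssw) / 1) / (ssw / 6), tolerance = 1e-10)
  d2b <- as.matrix(dist(x2))^2
  sstb <- sum(d2b[upper.tri(d2b)]) / 16
  iw <- c(1:4, 9:12)
  sswb <- sum(d2b[iw, iw]) / 16 + sum(d2b[-iw, -iw]) / 16
  expect_equal(f2, ((sstb - sswb) / 1) / (sswb / 14), tolerance = 1e-10)
})

test_that("pairwise npmanova applies Bonferroni and skips tiny groups", {
  blobs <- make_blobs(5, rbind(c(0, 0), c(30, 0), c(0, 30)), sd = 1, seed = 18)
  d <- euclidean_distance_matrix(blobs$x)
  pw <- pairwise_npmanova(d, blobs$labels, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_bonferroni, pmin(1, pw$p * 3))
  labs <- blobs$labels
  labs[labs == 3] <- c(3, 4, 4, 4, 4)[seq_len(sum(labs == 3))]
  expect_message(pw2 <- pairwise_npmanova(d, labs, n_perm = 49, seed = 1),
                 "skipping")
})

test_that("centroid divergence matches hand-computed means", {
  bins <- as_time_bins(data.frame(bin = c("b1", "b2"), start_ma = 2:1,
                                  end_ma = 1:0))
  taxa <- data.frame(taxon_id = c("a1", "a2", "b1", "b2"),
                     clade = c("A", "A", "B", "B"),
                     first_bin = c("b1", "b1", "b1", "b2"),
                     last_bin = c("b2", "b2", "b2", "b2"))
  mb <- bin_taxa(taxa, bins)
  x <- rbind(a1 = c(0, 0), a2 = c(2, 0), b1 = c(5, 4), b2 = c(7, 4))
  cd <- centroid_divergence(x, mb, "A", "B")
  # bin b1: A mean (1,0), B mean (5,4): distance sqrt(32)
  expect_equal(cd$distance[1], sqrt(32))
  # bin b2: A mean (1,0), B mean (6,4): distance sqrt(41)
  expect_equal(cd$distance[2], sqrt(41))
  # identical clade distributions give zero
  cd0 <- centroid_divergence(rbind(x[1:2, ], b1 = x[1, ], b2 = x[2, ]), mb,
                             "A", "B")
  expect_equal(cd0$distance[2], 0)
  # clade B = clade A translated by v gives |v| in the shared bin
  v <- c(3, -4)
  xt <- x
  xt[3:4, ] <- rbind(x[1, ] + v, x[2, ] + v)
  cdt <- centroid_divergence(xt, mb, "A", "B")
  expect_equal(cdt$distance[2], 5)
  # a clade absent from a bin yields a missing cell
  taxa2 <- taxa
  taxa2$first_bin[3:4] <- "b2"
  cd2 <- centroid_divergence(x, bin_taxa(taxa2, bins), "A", "B")
  expect_true(is.na(cd2$distance[1]))
})

test_that("time-slice hulls match brute-force hulls and known areas", {
  bins <- as_time_bins(data.frame(bin = "b1", start_ma = 1, end_ma = 0))
  sq <- rbind(t1 = c(0, 0), t2 = c(1, 0), t3 = c(1, 1), t4 = c(0, 1))
  taxa <- data.frame(taxon_id = rownames(sq), clade = "A",
                     first_bin = "b1", last_bin = "b1")
  mb <- bin_taxa(taxa, bins)
  occ <- timeslice_occupancy(sq, mb)
  expect_equal(occ$areas$area[occ$areas$clade == "A"], 1)
  # collinear points: zero area
  ln <- rbind(t1 = c(0, 0), t2 = c(1, 1), t3 = c(2, 2), t4 = c(3, 3))
  occ2 <- timeslice_occupancy(ln, mb)
  expect_equal(occ2$areas$area, c(0, 0))
  # random 10-point set: hull vertex set equals gift wrapping
  set.seed(19)
  pts <- matrix(runif(20), 10, 2)
  rownames(pts) <- sprintf("t%02d", 1:10)
  taxa10 <- data.frame(taxon_id = rownames(pts), clade = "A",
                       first_bin = "b1", last_bin = "b1")
  occ3 <- timeslice_occupancy(pts, bin_taxa(taxa10, bins))
  got <- sort(unique(occ3$hulls$taxon_id[occ3$hulls$clade == "A"]))
  # gift-wrapping oracle
  wrap <- function(p) {
    start <- which.min(p[, 1])
    hull <- start; current <- start
    repeat {
      cand <- setdiff(seq_len(nrow(p)), current)
      nxt <- cand[1]
      for (c2 in cand) {
        cr <- (p[nxt, 1] - p[current, 1]) * (p[c2, 2] - p[current, 2]) -
          (p[nxt, 2] - p[current, 2]) * (p[c2, 1] - p[current, 1])
        if (cr < 0) nxt <- c2
      }
      if (nxt == start) break
      hull <- c(hull, nxt); current <- nxt
    }
    hull
  }
  expect_equal(got, sort(rownames(pts)[wrap(pts)]))
  # hull area monotone under adding members
  a_first5 <- guildspace:::polygon_area(pts[1:5, ][chull(pts[1:5, ]), ])
  a_all <- occ3$areas$area[occ3$areas$clade == "A"]
  expect_gte(a_all, a_first5)
})
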