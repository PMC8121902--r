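#!/usr/bin/env Rscript
# Stage 6: disparity through time (MPD with bootstrap CIs, sum of
# variances, Procrustes variance) per clade and for the pooled fauna,
# NPMANOVA between epoch-level bin groups, clade centroid divergence, and
# morphospace time-slice hulls.

library(guildspace)

seed <- 2026L
taxa <- read_table("results/data/taxa.csv", "taxa")
bins <- read_table("results/data/bins.csv", "bins")
aligned <- read_results("results/aligned_coordinates.csv")
shape_mat <- as.matrix(aligned[, -1]); rownames(shape_mat) <- aligned[[1]]
sfmd_tab <- read_results("results/sfmd.csv")
sfmd <- as.matrix(sfmd_tab[, -1]); rownames(sfmd) <- sfmd_tab[[1]]
scores <- read_results("results/shape_scores.csv")
sc2 <- as.matrix(scores[, c("PC1", "PC2")]); rownames(sc2) <- scores[[1]]

herb <- taxa[taxa$diet == "herbivore", ]
membership <- bin_taxa(herb, bins)

d_shape <- euclidean_distance_matrix(shape_mat)
d_func <- euclidean_distance_matrix(sfmd)
message("computing disparity curves (B = 1000 bootstrap replicates)")
disp_shape <- disparity_curve(membership, d = d_shape, x = shape_mat,
                              metrics = c("MPD", "procrustes_variance"),
                              B = 1000L, seed = seed)
disp_func <- disparity_curve(membership, d = d_func, x = sfmd,
                             metrics = c("MPD", "sum_of_variances"),
                             B = 1000L, seed = seed + 1L)
write_results(disp_shape, "results/disparity_shape.csv")
write_results(disp_func, "results/disparity_function.csv")

epoch <- guildspace:::epoch_of_bin(
  herb$first_bin[match(rownames(sfmd), herb$taxon_id)], bins)
ok <- length(unique(epoch)) >= 2 && all(table(epoch) >= 2)
if (ok) {
  fit_s <- npmanova(d_shape, epoch, n_perm = 9999L, seed = seed)
  fit_f <- npmanova(d_func, epoch, n_perm = 9999L, seed = seed + 1L)
  message("epoch NPMANOVA: shape p = ", signif(fit_s$p, 3),
          ", function p = ", signif(fit_f$p, 3))
  pw <- pairwise_npmanova(d_func, epoch, n_perm = 999L, seed = seed + 2L)
  write_results(rbind(
    data.frame(space = "shape", f = fit_s$f, p = fit_s$p,
               n_perm = fit_s$n_perm),
    data.frame(space = "function", f = fit_f$f, p = fit_f$p,
               n_perm = fit_f$n_perm)), "results/npmanova_epoch.csv")
  write_results(pw, "results/npmanova_pairwise_function.csv")
} else message("NPMANOVA skipped: fewer than two epoch groups of size >= 2")

clades <- unique(herb$clade)
if (length(clades) >= 2) {
  cd <- centroid_divergence(sfmd, membership, clades[1], clades[2])
  write_results(cd, "results/centroid_divergence.csv")
  message("centroid divergence written for ", clades[1], " vs ", clades[2])
}

occ <- timeslice_occupancy(sc2, membership)
write_results(occ$areas, "results/timeslice_areas.csv")
write_results(occ$hulls, "results/timeslice_hulls.csv")
message("wrote disparity curves, NPMANOVA tables, divergence and hulls")
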