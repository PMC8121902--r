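#!/usr/bin/env Rscript
# Stage 4: shape and functional morphospaces by PCA, per-character axis
# contributions, and linear contour interpolation of each functional
# character over the shape morphospace.

library(guildspace)

aligned <- read_results("results/aligned_coordinates.csv")
shape_mat <- as.matrix(aligned[, -1]); rownames(shape_mat) <- aligned[[1]]
sfmd_tab <- read_results("results/sfmd.csv")
sfmd <- as.matrix(sfmd_tab[, -1]); rownames(sfmd) <- sfmd_tab[[1]]
chars <- read_results("results/functional_characters.csv")

shape_ord <- pca_ordination(shape_mat)
func_ord <- pca_ordination(sfmd)
message("shape PC1/PC2: ",
        paste(round(100 * shape_ord$var_frac[1:2], 1), collapse = "% / "),
        "%;  functional PC1/PC2: ",
        paste(round(100 * func_ord$var_frac[1:2], 1), collapse = "% / "), "%")

write_results(cbind(taxon_id = rownames(shape_ord$scores),
                    as.data.frame(shape_ord$scores[, 1:4])),
              "results/shape_scores.csv")
write_results(cbind(taxon_id = rownames(func_ord$scores),
                    as.data.frame(func_ord$scores[, 1:4])),
              "results/function_scores.csv")
write_results(data.frame(axis = seq_along(shape_ord$var_frac),
                         shape = shape_ord$var_frac,
                         func = c(func_ord$var_frac,
                                  rep(NA, length(shape_ord$var_frac) -
                                        length(func_ord$var_frac)))),
              "results/variance_fractions.csv")
contrib <- t(vapply(1:2, function(a) pc_contributions(func_ord, a),
                    numeric(ncol(sfmd))))
write_results(cbind(axis = 1:2, as.data.frame(contrib)),
              "results/fpc_contributions.csv")
message("fPC1 top contributors: ",
        paste(names(sort(pc_contributions(func_ord, 1),
                         decreasing = TRUE))[1:3], collapse = ", "))

# contour grids of each character over shape PC1-PC2
grid_dir <- "results/contours"
dir.create(grid_dir, showWarnings = FALSE, recursive = TRUE)
scores2 <- shape_ord$scores[, 1:2]
for (v in functional_character_names()) {
  vals <- chars[[v]][match(rownames(scores2), chars$taxon_id)]
  ci <- contour_interpolate(scores2, vals, n = 100L)
  grid <- expand.grid(pc1 = ci$x, pc2 = ci$y)
  grid[[v]] <- as.numeric(ci$z)
  write_results(grid, file.path(grid_dir, paste0("contour_", v, ".csv")))
}
message("wrote scores, variance fractions, contributions and 8 contour grids")
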