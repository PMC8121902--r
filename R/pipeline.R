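#' Run the full synthetic study end to end and write its outputs
#'
#' Generates a complete synthetic data set from one configuration, runs
#' every stage of the pipeline — Procrustes alignment with sliding
#' semilandmarks, functional characters from back-solved measurements,
#' shape and functional ordinations, consensus guild clustering with
#' sub-clustering of the largest guild, disparity through time, NPMANOVA
#' between epoch-scale bin groups, and assemblage conflict counts — and
#' writes every product as CSV under `out_dir`. Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param B_gap gap-statistic reference sets.
#' @param B_boot bootstrap replicates for MPD confidence intervals.
#' @param n_perm NPMANOVA permutations.
#' @return (invisibly) list with every intermediate product.
#' @export
run_synthetic_study <- function(cfg = synthetic_config(), out_dir = NULL,
                                B_gap = 100L, B_boot = 200L, n_perm = 999L) {
  fun <- generate_functional_table(cfg)
  shp <- generate_shape_set(cfg)
  eco <- generate_ranges_and_assemblages(cfg, truth = fun$truth,
                                         planted_conflicts = 2L)

  chars <- compute_functional_characters(fun$measurements)
  sfmd <- z_standardize(chars)

  gpa <- gpa_align(shp$shapes, slide = TRUE)
  shape_mat <- aligned_matrix(gpa)
  shape_ord <- pca_ordination(shape_mat)
  func_ord <- pca_ordination(sfmd)

  guild_fit <- consensus_pipeline(sfmd, k_range = 4:10, B = B_gap,
                                  seed = cfg$seed + 10L)
  guilds <- guild_fit$guilds
  main_guild <- names(which.max(table(guilds$ffg)))
  guilds <- tryCatch(
    subcluster_guild(guilds, main_guild, sfmd, k_range = 2:6, B = B_gap,
                     seed = cfg$seed + 11L),
    error = function(e) {
      message("sub-clustering skipped: ", conditionMessage(e))
      guilds
    })
  clade_map <- assign_clade_guilds(guilds,
                                   stats::setNames(fun$truth$subclade,
                                                   fun$truth$taxon_id))

  membership <- bin_taxa(eco$taxa[eco$taxa$diet == "herbivore", ], cfg$bins)
  d_shape <- euclidean_distance_matrix(shape_mat)
  disp_shape <- disparity_curve(membership, d = d_shape, x = shape_mat,
                                metrics = c("MPD", "procrustes_variance"),
                                B = B_boot, seed = cfg$seed + 20L)
  disp_func <- disparity_curve(membership, d = guild_fit$d, x = unclass(sfmd),
                               metrics = c("MPD", "sum_of_variances"),
                               B = B_boot, seed = cfg$seed + 21L)

  epoch <- epoch_of_bin(membership$bin, cfg$bins)
  first_bin_epoch <- epoch[match(rownames(sfmd),
                                 membership$taxon_id)]
  perm <- if (length(unique(first_bin_epoch)) >= 2L &&
              all(table(first_bin_epoch) >= 2L))
    npmanova(guild_fit$d, first_bin_epoch, n_perm = n_perm,
             seed = cfg$seed + 30L) else NULL

  conflicts_ffg <- conflict_table(eco$assemblages, guilds, eco$taxa,
                                  resolution = "FFG", clade_map = clade_map)
  conflicts_ffsg <- conflict_table(eco$assemblages, guilds, eco$taxa,
                                   resolution = "FFsG", clade_map = clade_map)

  out <- list(cfg = cfg, functional = fun, shapes = shp, ecology = eco,
              characters = chars, sfmd = sfmd, gpa = gpa,
              shape_ord = shape_ord, func_ord = func_ord,
              guild_fit = guild_fit, guilds = guilds, clade_map = clade_map,
              membership = membership, disparity_shape = disp_shape,
              disparity_function = disp_func, npmanova = perm,
              conflicts_ffg = conflicts_ffg, conflicts_ffsg = conflicts_ffsg)
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  invisible(out)
}

# Coarse epoch labels for the default bin scheme (by bin midpoint age).
epoch_of_bin <- function(bin, bins) {
  mid <- bins$mid_ma[bin_index(as.character(bin), bins)]
  ifelse(mid > 251.902, "Lopingian",
    ifelse(mid > 247.2, "Early Triassic",
      ifelse(mid > 237, "Middle Triassic",
        ifelse(mid > 201.3, "Late Triassic", "Early Jurassic"))))
}

write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(obj, name) write_results(obj, file.path(out_dir, name))
  w(res$characters, "functional_characters.csv")
  w(cbind(taxon_id = rownames(res$sfmd), as.data.frame(unclass(res$sfmd))),
    "sfmd.csv")
  w(cbind(taxon_id = rownames(aligned_matrix(res$gpa)),
          as.data.frame(aligned_matrix(res$gpa))), "aligned_coordinates.csv")
  w(data.frame(axis = seq_along(res$shape_ord$var_frac),
               shape_var_frac = res$shape_ord$var_frac), "shape_variance.csv")
  w(data.frame(axis = seq_along(res$func_ord$var_frac),
               func_var_frac = res$func_ord$var_frac), "function_variance.csv")
  w(cbind(taxon_id = rownames(res$func_ord$scores),
          as.data.frame(res$func_ord$scores[, 1:2])), "function_scores.csv")
  w(as.data.frame(res$guild_fit$gap), "gap_curve.csv")
  w(as.data.frame(res$guilds), "consensus_guilds.csv")
  w(data.frame(clade = names(res$clade_map), ffg = unname(res$clade_map)),
    "clade_guilds.csv")
  w(res$disparity_shape, "disparity_shape.csv")
  w(res$disparity_function, "disparity_function.csv")
  if (!is.null(res$npmanova))
    w(data.frame(pseudo_f = res$npmanova$f, p = res$npmanova$p,
                 n_perm = res$npmanova$n_perm), "npmanova.csv")
  w(res$conflicts_ffg, "conflicts_ffg.csv")
  w(res$conflicts_ffsg, "conflicts_ffsg.csv")
  invisible(out_dir)
}
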