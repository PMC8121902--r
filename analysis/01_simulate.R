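#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs at the default study scale
# (136 herbivore taxa, 8 functional characters with 5 planted guilds,
# 59-landmark jaws, Changhsingian-Toarcian bins, locality assemblages) and
# write them in the interchange formats the pipeline reads back (TPS + CSV).

library(guildspace)

seed <- 2026L
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
message("generating functional table / measurements (n = ", cfg$n_taxa, ")")
fun <- generate_functional_table(cfg)
message("generating landmark sets (59 landmarks, 4 fixed, 4 curves)")
shp <- generate_shape_set(cfg)
message("generating ranges and assemblages (", cfg$n_assemblages,
        " localities, 2 planted same-guild pairs)")
eco <- generate_ranges_and_assemblages(cfg, truth = fun$truth,
                                       planted_conflicts = 2L)

write_tps(shp$shapes, file.path(data_dir, "jaws.tps"))
write_results(fun$measurements, file.path(data_dir, "measurements.csv"))
write_results(eco$taxa, file.path(data_dir, "taxa.csv"))
write_results(eco$assemblages, file.path(data_dir, "assemblages.csv"))
write_results(as.data.frame(cfg$bins), file.path(data_dir, "bins.csv"))
write_results(fun$truth, file.path(data_dir, "truth_guilds.csv"))
write_results(shp$truth, file.path(data_dir, "truth_shape_groups.csv"))

message("inputs written under ", data_dir,
        ": jaws.tps, measurements.csv, taxa.csv, assemblages.csv, bins.csv ",
        "(+ truth tables for validation)")
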