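#!/usr/bin/env Rscript
# Stage 5: functional feeding groups by consensus across hierarchical,
# k-means and PAM clustering of the SFMD distance structure, with
# gap-statistic model selection (K range 4-10), silhouette and taxonomic
# validation, sub-clustering of the dominant guild, and clade-majority
# assignment.

library(guildspace)

seed <- 2026L
sfmd_tab <- read_results("results/sfmd.csv")
sfmd <- as.matrix(sfmd_tab[, -1]); rownames(sfmd) <- sfmd_tab[[1]]
taxa <- read_table("results/data/taxa.csv", "taxa")

fit <- consensus_pipeline(sfmd, k_range = 4:10, B = 100L, seed = seed)
message("gap statistic chose k = ", fit$k, " (",
        attr(fit$gap, "rule"), " rule)")
write_results(as.data.frame(fit$gap), "results/gap_curve.csv")
write_results(do.call(rbind, lapply(fit$partitions, function(p)
  data.frame(taxon_id = names(p$labels), method = p$method, k = p$k,
             label = unname(p$labels)))), "results/partitions.csv")

sil <- vapply(fit$partitions, function(p)
  silhouette_widths(fit$d, p)$overall, numeric(1))
message("overall silhouette widths: ",
        paste(sprintf("%s %.3f", vapply(fit$partitions, `[[`, "", "method"),
                      sil), collapse = ", "))

subclades <- setNames(taxa$subclade, taxa$taxon_id)[rownames(sfmd)]
val <- do.call(rbind, lapply(fit$partitions, function(p) {
  v <- external_validation(p, subclades)
  data.frame(method = p$method, reference = "subclade",
             adjusted_rand = v$adjusted_rand, vi = v$vi)
}))
write_results(val, "results/external_validation.csv")

guilds <- fit$guilds
message(length(unique(guilds$ffg)), " consensus FFGs; ",
        sum(!guilds$consistent), " taxa flagged inconsistent")
main_guild <- names(which.max(table(guilds$ffg)))
message("sub-clustering dominant guild '", main_guild, "' (",
        sum(guilds$ffg == main_guild), " taxa)")
guilds <- tryCatch(
  subcluster_guild(guilds, main_guild, sfmd, k_range = 2:6, B = 100L,
                   seed = seed + 1L),
  error = function(e) { message("sub-clustering skipped: ",
                                conditionMessage(e)); guilds })
write_results(as.data.frame(guilds), "results/consensus_guilds.csv")

clade_map <- assign_clade_guilds(guilds, setNames(taxa$subclade,
                                                  taxa$taxon_id))
write_results(data.frame(clade = names(clade_map), ffg = unname(clade_map)),
              "results/clade_guilds.csv")
message("wrote gap curve, partitions, validation metrics, guild table and ",
        "clade-majority map")
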