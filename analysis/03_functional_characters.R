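#!/usr/bin/env Rscript
# Stage 3: the eight biomechanical jaw characters from the linear
# measurements, and their z-standardisation (SFMD) for ordination,
# distances and clustering.

library(guildspace)

m <- read_table("results/data/measurements.csv", "measurements")
chars <- compute_functional_characters(m)
message("computed ", length(functional_character_names()),
        " characters for ", nrow(chars), " taxa")

sfmd <- z_standardize(chars)
write_results(as.data.frame(chars), "results/functional_characters.csv")
write_results(cbind(taxon_id = rownames(sfmd), as.data.frame(unclass(sfmd))),
              "results/sfmd.csv")
write_results(data.frame(character = colnames(sfmd),
                         center = attr(sfmd, "center"),
                         scale = attr(sfmd, "scale")),
              "results/sfmd_parameters.csv")
message("wrote results/functional_characters.csv, results/sfmd.csv ",
        "and the standardisation parameters")
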