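#!/usr/bin/env Rscript
# Stage 2: generalized Procrustes superimposition of the jaw landmark sets
# with chord-projection sliding semilandmarks; writes the aligned
# coordinates and the consensus shape.

library(guildspace)

shapes <- read_tps("results/data/jaws.tps")
message("read ", length(shapes), " configurations of ",
        nrow(shapes[[1]]$coords), " landmarks")

gpa <- gpa_align(shapes, slide = TRUE)
message("alignment: ", gpa$iterations, " iterations, converged = ",
        gpa$converged, "; final objective = ",
        signif(tail(gpa$objective, 1), 5))

m <- aligned_matrix(gpa)
write_results(cbind(taxon_id = rownames(m), as.data.frame(m)),
              "results/aligned_coordinates.csv")
cons <- as.data.frame(gpa$consensus)
names(cons) <- c("x", "y")
write_results(cbind(landmark = seq_len(nrow(cons)), cons),
              "results/consensus_shape.csv")
message("wrote results/aligned_coordinates.csv and results/consensus_shape.csv")
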