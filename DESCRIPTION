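Package: guildspace
Title: Jaw Ecomorphology, Functional Feeding Guilds and Disparity Through Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for jaw-based ecomorphology of fossil
    herbivore faunas. Reads 2D landmark configurations (TPS) and linear
    measurement tables, performs generalized Procrustes superimposition with
    chord-projection sliding semilandmarks, computes eight biomechanical jaw
    characters (mechanical advantage variants, aspect ratio, symphyseal and
    articulation geometry), builds shape and functional morphospaces by
    principal component analysis with contour interpolation, derives
    functional feeding groups by consensus across hierarchical, k-means and
    PAM clustering with gap-statistic model selection and silhouette and
    taxonomic validation, quantifies disparity through time (mean pairwise
    distance with bootstrap confidence intervals, sum of variances,
    Procrustes variance), tests morphospace shifts by permutational MANOVA,
    and counts trophic-guild conflicts within fossil assemblages. A
    synthetic-data module generates landmark sets, guild-structured
    functional tables, stratigraphic ranges and assemblages with planted
    structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
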