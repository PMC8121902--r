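#' Assemblage summaries: richness by clade, abundance by diet
#'
#' Relative species richness per clade and relative abundance per diet class
#' for one locality. Abundance uses specimen counts where present; when any
#' count is missing every member is weighted equally and the downgrade is
#' reported with a message.
#'
#' @param assemblage data frame for one locality: `taxon_id`, optional
#'   `count`.
#' @param taxa taxon table supplying `clade` and `diet` per taxon.
#' @return list with data frames `richness` (`clade`, `n`, `proportion`) and
#'   `abundance` (`diet`, `weight`, `proportion`); proportions sum to 1.
#' @export
assemblage_summaries <- function(assemblage, taxa) {
  if (!nrow(assemblage)) stop("empty assemblage")
  idx <- match(assemblage$taxon_id, taxa$taxon_id)
  if (anyNA(idx))
    stop("assemblage members absent from taxon table: ",
         paste(assemblage$taxon_id[is.na(idx)], collapse = ", "))
  clade <- taxa$clade[idx]
  diet <- taxa$diet[idx]
  counts <- if ("count" %in% names(assemblage)) assemblage$count
            else rep(NA_real_, nrow(assemblage))
  if (anyNA(counts)) {
    if (!all(is.na(counts)))
      message("assemblage_summaries: incomplete counts; using equal weights")
    counts <- rep(1, nrow(assemblage))
  }
  rich <- as.data.frame(table(clade), stringsAsFactors = FALSE)
  names(rich) <- c("clade", "n")
  rich$proportion <- rich$n / sum(rich$n)
  ab <- stats::aggregate(list(weight = counts), by = list(diet = diet), FUN = sum)
  ab$proportion <- ab$weight / sum(ab$weight)
  list(richness = rich, abundance = ab)
}

#' Count trophic-guild conflicts within an assemblage
#'
#' A conflict is an unordered pair of co-occurring herbivores sharing the
#' same guild label at the requested resolution (FFG, or the finer FFsG
#' where subgroup labels replace the split guild). Taxa absent from the
#' guild table inherit their clade's majority guild when a clade map is
#' supplied; herbivores that still lack a label are excluded with a message.
#' A taxon-level count (number of herbivores involved in any conflict) is
#' reported alongside the primary pair count.
#'
#' @param assemblage data frame for one locality: `taxon_id` (optionally
#'   `locality`).
#' @param guilds a `consensus_guilds` table.
#' @param taxa taxon table supplying `diet` (and `clade` for fallback).
#' @param resolution `"FFG"` or `"FFsG"`.
#' @param clade_map optional named vector from [assign_clade_guilds()] used
#'   for taxa outside the morphometric sample.
#' @param include_inconsistent count taxa flagged inconsistent using their
#'   nearest-core attachment label (default FALSE: they are excluded).
#' @return object of class `conflict_report`: list with `locality`,
#'   `resolution`, `n_conflicts` (pairs), `n_conflicted_taxa`, `pairs`
#'   (data frame), `n_herbivores`, `excluded`.
#' @export
count_ffg_conflicts <- function(assemblage, guilds, taxa,
                                resolution = c("FFG", "FFsG"),
                                clade_map = NULL,
                                include_inconsistent = FALSE) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(guilds, "consensus_guilds"))
  locality <- if ("locality" %in% names(assemblage))
    as.character(assemblage$locality[1L]) else NA_character_
  idx <- match(assemblage$taxon_id, taxa$taxon_id)
  if (anyNA(idx))
    stop("assemblage members absent from taxon table: ",
         paste(assemblage$taxon_id[is.na(idx)], collapse = ", "))
  herb <- unique(assemblage$taxon_id[taxa$diet[idx] == "herbivore"])

  label_of <- function(id) {
    g <- match(id, guilds$taxon_id)
    if (!is.na(g)) {
      if (!guilds$consistent[g] && !include_inconsistent) return(NA_character_)
      lab <- guilds$ffg[g]
      if (resolution == "FFsG" && !is.na(guilds$ffsg[g])) lab <- guilds$ffsg[g]
      return(as.character(lab))
    }
    if (!is.null(clade_map)) {
      cl <- taxa$clade[match(id, taxa$taxon_id)]
      if (cl %in% names(clade_map) && clade_map[[cl]] != "unresolved")
        return(as.character(clade_map[[cl]]))
    }
    NA_character_
  }
  labels <- vapply(herb, label_of, character(1))
  excluded <- herb[is.na(labels)]
  if (length(excluded))
    message("count_ffg_conflicts: excluding unlabelled herbivore(s): ",
            paste(excluded, collapse = ", "))
  herb <- herb[!is.na(labels)]
  labels <- labels[!is.na(labels)]

  pairs <- data.frame(taxon_a = character(), taxon_b = character(),
                      guild = character(), stringsAsFactors = FALSE)
  if (length(herb) >= 2L) {
    cmb <- utils::combn(seq_along(herb), 2L)
    same <- labels[cmb[1L, ]] == labels[cmb[2L, ]]
    pairs <- data.frame(taxon_a = herb[cmb[1L, same]],
                        taxon_b = herb[cmb[2L, same]],
                        guild = labels[cmb[1L, same]],
                        stringsAsFactors = FALSE)
  }
  structure(list(locality = locality, resolution = resolution,
                 n_conflicts = nrow(pairs),
                 n_conflicted_taxa = length(unique(c(pairs$taxon_a, pairs$taxon_b))),
                 pairs = pairs, n_herbivores = length(herb),
                 excluded = excluded),
            class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  cat("conflict_report", if (!is.na(x$locality)) x$locality else "", "(",
      x$resolution, "):", x$n_conflicts, "conflicting pair(s) among",
      x$n_herbivores, "herbivores\n")
  invisible(x)
}

#' Conflict counts for every locality of an assemblage table
#'
#' @param assemblages long assemblage table (`locality`, `taxon_id`, ...).
#' @inheritParams count_ffg_conflicts
#' @return data frame: `locality`, `resolution`, `n_herbivores`,
#'   `n_conflicts`, `n_conflicted_taxa`.
#' @export
conflict_table <- function(assemblages, guilds, taxa,
                           resolution = c("FFG", "FFsG"), clade_map = NULL,
                           include_inconsistent = FALSE) {
  resolution <- match.arg(resolution)
  rows <- lapply(split(assemblages, assemblages$locality), function(a) {
    rep_ <- count_ffg_conflicts(a, guilds, taxa, resolution = resolution,
                                clade_map = clade_map,
                                include_inconsistent = include_inconsistent)
    data.frame(locality = rep_$locality, resolution = rep_$resolution,
               n_herbivores = rep_$n_herbivores,
               n_conflicts = rep_$n_conflicts,
               n_conflicted_taxa = rep_$n_conflicted_taxa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
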