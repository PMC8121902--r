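#' Configuration for the synthetic study generator
#'
#' Defaults mirror the scale of the empirical study the pipeline is designed
#' for: 136 herbivore taxa in eleven subclades of three major clades, eight
#' functional characters with five planted guilds, a 59-landmark jaw scheme
#' (4 fixed + 55 semilandmarks on 4 curves), stage/substage bins from the
#' Changhsingian to the Toarcian, and locality assemblages with abundance
#' counts.
#'
#' @param n_taxa number of herbivore taxa.
#' @param n_guilds number of planted functional guilds.
#' @param separation distance between guild centres in within-guild SD units.
#' @param within_sd within-guild standard deviation (per character, z scale).
#' @param guild_fidelity probability that a taxon falls in its clade's home
#'   guild (else uniform over guilds).
#' @param n_shape_groups number of planted shape-deformation groups.
#' @param deformation magnitude of the smooth per-group displacement field
#'   (fraction of jaw length).
#' @param landmark_noise i.i.d. landmark noise SD (fraction of jaw length).
#' @param bins a `time_bins` scheme.
#' @param mean_extra_bins mean number of bins a range extends beyond its
#'   first bin (geometric durations; 0 means single-bin ranges).
#' @param n_faunivores extra faunivorous taxa (outside the guild analysis)
#'   added to the taxon table for assemblage realism.
#' @param n_assemblages number of localities.
#' @param mean_assemblage_size mean taxa per locality.
#' @param seed master seed; every generator derives its stream from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa = 136L, n_guilds = 5L, separation = 6,
                             within_sd = 1, guild_fidelity = 0.9,
                             n_shape_groups = 2L, deformation = 0.08,
                             landmark_noise = 0.01,
                             bins = default_time_bins(),
                             mean_extra_bins = 2, n_faunivores = 30L,
                             n_assemblages = 12L, mean_assemblage_size = 8,
                             seed = 1L) {
  stopifnot(separation >= 0, guild_fidelity >= 0, guild_fidelity <= 1,
            n_taxa >= n_guilds, within_sd > 0, n_assemblages >= 1)
  structure(list(n_taxa = as.integer(n_taxa), n_guilds = as.integer(n_guilds),
                 separation = separation, within_sd = within_sd,
                 guild_fidelity = guild_fidelity,
                 n_shape_groups = as.integer(n_shape_groups),
                 deformation = deformation, landmark_noise = landmark_noise,
                 bins = bins, mean_extra_bins = mean_extra_bins,
                 n_faunivores = as.integer(n_faunivores),
                 n_assemblages = as.integer(n_assemblages),
                 mean_assemblage_size = mean_assemblage_size,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Subclade sizes emulating the empirical sample's taxonomic structure,
# rescaled to n taxa.
synthetic_clades <- function(n) {
  base <- c(Procolophonoidea = 23, Dicynodontia = 22, Cynognathia = 17,
            Tritylodontidae = 6, Bauriidae = 3, Ornithischia = 7,
            Sauropodomorpha = 29, Silesauridae = 2, Aetosauria = 8,
            Pseudosuchia = 4, Archosauromorpha_basal = 15)
  major <- c(Procolophonoidea = "Parareptilia", Dicynodontia = "Therapsida",
             Cynognathia = "Therapsida", Tritylodontidae = "Therapsida",
             Bauriidae = "Therapsida", Ornithischia = "Archosauromorpha",
             Sauropodomorpha = "Archosauromorpha",
             Silesauridae = "Archosauromorpha", Aetosauria = "Archosauromorpha",
             Pseudosuchia = "Archosauromorpha",
             Archosauromorpha_basal = "Archosauromorpha")
  sizes <- stats::setNames(pmax(1L, round(base / sum(base) * n)), names(base))
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  list(subclade = rep(names(sizes), sizes),
       clade = unname(major[rep(names(sizes), sizes)]))
}

# Character-scale means and spreads used to express z-scale guild structure
# as plausible jaw ratios/angles.
character_scales <- function() {
  list(mean = c(MA_ant = 0.35, MA_post = 0.65, MA_open = 0.22, MAR = 0.25,
                RSL = 0.20, AO = 0.07, RTL = 0.55, SA = 35),
       spread = c(MA_ant = 0.04, MA_post = 0.06, MA_open = 0.03, MAR = 0.03,
                  RSL = 0.03, AO = 0.012, RTL = 0.05, SA = 4))
}

#' Generate a guild-structured functional table (and measurements)
#'
#' Guild centres are placed along mutually orthogonal random directions in
#' the eight-character z-space, scaled so that every pair of centres is
#' `separation * within_sd` apart; members are Gaussian about their centre.
#' Clades are assigned home guilds so that a taxon lands in its clade's
#' guild with probability `guild_fidelity` (else uniformly). The z-scale
#' table is expressed on the character scale and back-solved into a
#' consistent raw measurement set (positive lengths, posterior out-lever
#' not exceeding the anterior) so that [compute_functional_characters()]
#' can be exercised end to end; taxa whose draw is infeasible as a jaw are
#' resampled with a message.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `characters` (a `functional_table`), `measurements`
#'   (data frame), `z` (the z-scale matrix), and `truth` (data frame
#'   `taxon_id`, `guild`, `clade`, `subclade`).
#' @export
generate_functional_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_taxa; g <- cfg$n_guilds; p <- 8L
  ids <- sprintf("taxon_%03d", seq_len(n))
  cl <- synthetic_clades(n)

  dirs <- qr.Q(qr(matrix(stats::rnorm(p * g), p, g)))[, seq_len(g), drop = FALSE]
  centres <- t(dirs) * (cfg$separation * cfg$within_sd / sqrt(2))

  home <- stats::setNames(
    (seq_along(unique(cl$subclade)) - 1L) %% g + 1L, unique(cl$subclade))
  guild <- vapply(cl$subclade, function(s) {
    if (stats::runif(1) <= cfg$guild_fidelity) home[[s]]
    else sample.int(g, 1L)
  }, integer(1))

  sc <- character_scales()
  draw_z <- function(gi) centres[gi, ] + stats::rnorm(p, 0, cfg$within_sd)
  to_chars <- function(z) sc$mean + sc$spread * z
  feasible <- function(ch)
    all(ch[c("MA_ant", "MA_post", "MA_open", "MAR", "RSL", "RTL")] > 0) &&
      ch["AO"] >= 0 && ch["SA"] > 0 && ch["SA"] < 180 &&
      ch["MA_post"] > ch["MA_ant"]

  z <- matrix(NA_real_, n, p, dimnames = list(ids, functional_character_names()))
  resampled <- 0L
  for (i in seq_len(n)) {
    zi <- draw_z(guild[i])
    tries <- 0L
    while (!feasible(to_chars(zi)) && tries < 100L) {
      zi <- draw_z(guild[i]); tries <- tries + 1L; resampled <- resampled + 1L
    }
    if (!feasible(to_chars(zi)))
      stop("could not draw a feasible jaw for ", ids[i],
           "; character scales too wide for this separation")
    z[i, ] <- zi
  }
  if (resampled > 0L)
    message("generate_functional_table: resampled ", resampled,
            " infeasible draw(s)")
  chars <- t(apply(z, 1L, to_chars))

  jaw_length <- exp(stats::rnorm(n, log(10), 0.3))
  oa <- 0.92 * jaw_length
  measurements <- data.frame(
    taxon_id = ids,
    jaw_length = jaw_length,
    tooth_row_length = chars[, "RTL"] * jaw_length,
    max_depth = chars[, "MAR"] * jaw_length,
    symphysis_length = chars[, "RSL"] * jaw_length,
    symphysis_angle = chars[, "SA"],
    inlever_closing = chars[, "MA_ant"] * oa,
    inlever_opening = chars[, "MA_open"] * oa,
    outlever_anterior = oa,
    outlever_posterior = chars[, "MA_ant"] * oa / chars[, "MA_post"],
    articulation_offset_raw = chars[, "AO"] * jaw_length,
    stringsAsFactors = FALSE)

  tab <- data.frame(taxon_id = ids, as.data.frame(chars),
                    stringsAsFactors = FALSE)
  class(tab) <- c("functional_table", "data.frame")
  truth <- data.frame(taxon_id = ids, guild = guild, clade = cl$clade,
                      subclade = cl$subclade, stringsAsFactors = FALSE)
  list(characters = tab, measurements = measurements, z = z, truth = truth)
}

# Template jaw outline: 59 landmarks, 4 fixed (anterior tip, coronoid apex,
# articular, angular), 4 semilandmark curves of 13 + 14 + 14 + 14 points.
template_jaw <- function() {
  seg <- function(a, b, n_interior, bulge = 0) {
    t <- seq(0, 1, length.out = n_interior + 2L)
    nrm <- c(-(b[2] - a[2]), b[1] - a[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    cbind(a[1] + t * (b[1] - a[1]) + bulge * sin(pi * t) * nrm[1],
          a[2] + t * (b[2] - a[2]) + bulge * sin(pi * t) * nrm[2])
  }
  tip <- c(0, 0); coronoid <- c(0.70, 0.25); articular <- c(1.0, 0.05)
  angular <- c(0.55, -0.12)
  s1 <- seg(tip, coronoid, 13L, bulge = 0.03)
  s2 <- seg(coronoid, articular, 14L, bulge = -0.04)
  s3 <- seg(articular, angular, 14L, bulge = -0.05)
  s4 <- seg(angular, tip, 14L, bulge = -0.02)
  coords <- rbind(s1, s2[-1L, ], s3[-1L, ], s4[-1L, , drop = FALSE])
  coords <- coords[-nrow(coords), , drop = FALSE]  # closing point == tip
  fixed <- c(1L, 15L, 30L, 45L)
  curves <- list(1:15, 15:30, 30:45, c(45:59, 1L))
  list(coords = coords, fixed = fixed, curves = curves)
}

#' Generate a synthetic landmark set
#'
#' Deforms a template jaw outline (59 landmarks; 4 fixed + 55 semilandmarks
#' on 4 curves) per planted group with a smooth low-frequency trigonometric
#' displacement field, adds i.i.d. landmark noise, and applies a random
#' similarity transform (rotation, scale, translation) to each specimen so
#' that superimposition has work to do. Reflections are never applied.
#'
#' @param cfg a [synthetic_config()].
#' @param ids optional specimen ids (default `taxon_001` ...).
#' @param groups optional group label per specimen (default: `n_shape_groups`
#'   contiguous blocks).
#' @return list with `shapes` (list of [landmark_config()]) and `truth`
#'   (data frame `taxon_id`, `shape_group`).
#' @export
generate_shape_set <- function(cfg, ids = NULL, groups = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_taxa
  if (is.null(ids)) ids <- sprintf("taxon_%03d", seq_len(n))
  if (is.null(groups))
    groups <- sort(rep(seq_len(cfg$n_shape_groups), length.out = n))
  tpl <- template_jaw()
  k <- nrow(tpl$coords)

  field <- function() {
    cf <- stats::rnorm(8L)
    function(xy) {
      x <- xy[, 1]; y <- xy[, 2]
      cbind(cf[1] * sin(pi * x) + cf[2] * cos(pi * y) + cf[3] * x * y +
              cf[4] * sin(2 * pi * x) / 2,
            cf[5] * sin(pi * y) + cf[6] * cos(pi * x) + cf[7] * x^2 +
              cf[8] * sin(2 * pi * y) / 2)
    }
  }
  fields <- lapply(seq_along(unique(groups)), function(i) field())
  names(fields) <- as.character(unique(groups))

  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    xy <- tpl$coords
    xy <- xy + cfg$deformation * fields[[as.character(groups[i])]](xy) / 4
    xy <- xy + matrix(stats::rnorm(2L * k, 0, cfg$landmark_noise), k, 2L)
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    sc <- exp(stats::rnorm(1, 0, 0.4))
    tr <- stats::rnorm(2L, 0, 2)
    xy <- sweep(sc * xy %*% R, 2L, tr, `+`)
    shapes[[i]] <- landmark_config(ids[i], xy, tpl$fixed, tpl$curves)
  }
  list(shapes = shapes,
       truth = data.frame(taxon_id = ids, shape_group = groups,
                          stringsAsFactors = FALSE))
}

#' Generate stratigraphic ranges and locality assemblages
#'
#' First-appearance bins are uniform over the scheme; durations (extra bins)
#' are geometric with the configured mean, clamped at the youngest bin.
#' Assemblages sample co-occurring taxa from one bin's standing fauna with
#' log-normal abundance counts. Optionally, planted same-guild herbivore
#' pairs are forced into one extra locality so conflict counting has known
#' truth.
#'
#' @param cfg a [synthetic_config()].
#' @param truth truth table from [generate_functional_table()] (supplies
#'   taxon ids, clades and guilds); generated afresh when `NULL`.
#' @param planted_conflicts number of same-guild pairs to force into one
#'   extra locality (0 = none).
#' @return list with `taxa` (taxon table), `assemblages` (long table
#'   `locality`, `bin`, `taxon_id`, `count`) and `planted_locality`.
#' @export
generate_ranges_and_assemblages <- function(cfg, truth = NULL,
                                            planted_conflicts = 0L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(truth)) truth <- generate_functional_table(cfg)$truth
  set.seed(cfg$seed + 2L)
  bins <- cfg$bins
  nb <- nrow(bins)
  n <- nrow(truth)

  first <- sample.int(nb, n, replace = TRUE)
  extra <- if (cfg$mean_extra_bins <= 0) rep(0L, n)
           else stats::rgeom(n, 1 / (1 + cfg$mean_extra_bins))
  last <- pmin(first + extra, nb)
  herb <- data.frame(taxon_id = truth$taxon_id, clade = truth$clade,
                     subclade = truth$subclade,
                     first_bin = bins$bin[first], last_bin = bins$bin[last],
                     diet = "herbivore", stringsAsFactors = FALSE)
  nf <- cfg$n_faunivores
  taxa <- herb
  if (nf > 0L) {
    f_first <- sample.int(nb, nf, replace = TRUE)
    f_extra <- if (cfg$mean_extra_bins <= 0) rep(0L, nf)
               else stats::rgeom(nf, 1 / (1 + cfg$mean_extra_bins))
    fauns <- data.frame(taxon_id = sprintf("faunivore_%02d", seq_len(nf)),
                        clade = sample(unique(truth$clade), nf, replace = TRUE),
                        subclade = "Faunivora",
                        first_bin = bins$bin[f_first],
                        last_bin = bins$bin[pmin(f_first + f_extra, nb)],
                        diet = "faunivore", stringsAsFactors = FALSE)
    taxa <- rbind(herb, fauns)
  }

  membership <- bin_taxa(taxa, bins)
  rows <- list()
  for (a in seq_len(cfg$n_assemblages)) {
    repeat {
      bn <- sample(bins$bin, 1L)
      pool <- unique(membership$taxon_id[membership$bin == bn])
      if (length(pool) >= 2L) break
    }
    size <- min(length(pool), max(2L, stats::rpois(1, cfg$mean_assemblage_size)))
    members <- sample(pool, size)
    rows[[a]] <- data.frame(locality = sprintf("locality_%02d", a), bin = bn,
                            taxon_id = members,
                            count = pmax(1, round(stats::rlnorm(size, 2, 0.8))),
                            stringsAsFactors = FALSE)
  }
  planted_locality <- NA_character_
  if (planted_conflicts > 0L) {
    guilds_avail <- names(which(table(truth$guild) >= 2L))
    if (length(guilds_avail) < planted_conflicts)
      stop("not enough multi-member guilds to plant ", planted_conflicts,
           " conflicts")
    chosen <- sample(guilds_avail, planted_conflicts)
    members <- unlist(lapply(chosen, function(gg)
      sample(truth$taxon_id[truth$guild == gg], 2L)))
    planted_locality <- "locality_planted"
    rows[[length(rows) + 1L]] <-
      data.frame(locality = planted_locality,
                 bin = taxa$first_bin[match(members, taxa$taxon_id)][1L],
                 taxon_id = members,
                 count = pmax(1, round(stats::rlnorm(length(members), 2, 0.8))),
                 stringsAsFactors = FALSE)
  }
  list(taxa = taxa, assemblages = do.call(rbind, rows),
       planted_locality = planted_locality)
}
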