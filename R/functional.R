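#' Compute the eight biomechanical jaw characters
#'
#' Lever-arm and proportion characters computed from linear measurements of
#' the mandible:
#' \describe{
#'   \item{MA_ant}{anterior mechanical advantage, closing in-lever /
#'     anterior out-lever (joint to anteriormost biting point).}
#'   \item{MA_post}{posterior mechanical advantage, closing in-lever /
#'     posterior out-lever.}
#'   \item{MA_open}{opening mechanical advantage, opening in-lever (joint to
#'     retroarticular tip) / anterior out-lever.}
#'   \item{MAR}{maximum aspect ratio, maximum mandible depth / jaw length.}
#'   \item{RSL}{relative symphyseal length, symphysis length / jaw length.}
#'   \item{AO}{articulation offset, perpendicular joint offset from the
#'     tooth-row line / jaw length.}
#'   \item{RTL}{relative tooth-row length, tooth-row (or functional-surface)
#'     length / jaw length.}
#'   \item{SA}{symphyseal angle, passed through in degrees.}
#' }
#' All ratios are dimensionless, so the table is invariant to the unit in
#' which the raw lengths were taken. Taxa with any missing required
#' measurement are dropped listwise with a message (the dropped ids are kept
#' in the `"dropped"` attribute).
#'
#' @param m measurement data frame with column `taxon_id` plus the ten
#'   columns named by `guildspace:::measurement_names()`.
#' @return data frame of class `functional_table`: `taxon_id` plus the eight
#'   characters.
#' @export
compute_functional_characters <- function(m) {
  stopifnot(is.data.frame(m), "taxon_id" %in% names(m))
  need <- measurement_names()
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("missing measurement column(s): ", paste(missing_cols, collapse = ", "))

  complete <- stats::complete.cases(m[, need])
  dropped <- m$taxon_id[!complete]
  if (length(dropped))
    message("compute_functional_characters: dropping ", length(dropped),
            " taxon/taxa with missing measurements: ",
            paste(dropped, collapse = ", "))
  m <- m[complete, , drop = FALSE]
  if (!nrow(m)) stop("no taxa with complete measurements")

  lengths <- c("jaw_length", "tooth_row_length", "max_depth", "symphysis_length",
               "inlever_closing", "inlever_opening", "outlever_anterior",
               "outlever_posterior")
  for (col in lengths) {
    bad <- m[[col]] <= 0
    if (any(bad))
      stop("non-positive ", col, " for taxon: ",
           paste(m$taxon_id[bad], collapse = ", "))
  }
  if (any(m$articulation_offset_raw < 0))
    stop("negative articulation offset for taxon: ",
         paste(m$taxon_id[m$articulation_offset_raw < 0], collapse = ", "))
  if (any(m$symphysis_angle < 0 | m$symphysis_angle >= 180))
    stop("symphysis angle outside [0, 180) for taxon: ",
         paste(m$taxon_id[m$symphysis_angle < 0 | m$symphysis_angle >= 180],
               collapse = ", "))
  if (any(m$outlever_posterior > m$outlever_anterior))
    stop("posterior out-lever exceeds anterior out-lever for taxon: ",
         paste(m$taxon_id[m$outlever_posterior > m$outlever_anterior],
               collapse = ", "))

  out <- data.frame(
    taxon_id = m$taxon_id,
    MA_ant  = m$inlever_closing / m$outlever_anterior,
    MA_post = m$inlever_closing / m$outlever_posterior,
    MA_open = m$inlever_opening / m$outlever_anterior,
    MAR     = m$max_depth / m$jaw_length,
    RSL     = m$symphysis_length / m$jaw_length,
    AO      = m$articulation_offset_raw / m$jaw_length,
    RTL     = m$tooth_row_length / m$jaw_length,
    SA      = m$symphysis_angle,
    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  class(out) <- c("functional_table", "data.frame")
  out
}

#' Character names of the functional table
#' @return character vector of the eight character names.
#' @export
functional_character_names <- function() {
  c("MA_ant", "MA_post", "MA_open", "MAR", "RSL", "AO", "RTL", "SA")
}

#' Column-wise z-standardisation (SFMD)
#'
#' Centres each character and divides by its sample standard deviation
#' (n - 1 denominator), producing the standardised functional measurement
#' data used for ordination, distances and clustering. The transform
#' parameters are stored so the mapping can be inverted.
#'
#' @param x a `functional_table`, or any numeric matrix/data frame with taxa
#'   as rows (a `taxon_id` column, if present, becomes row names).
#' @return numeric matrix of class `sfmd` with attributes `center` and
#'   `scale`.
#' @export
z_standardize <- function(x) {
  if (is.data.frame(x)) {
    ids <- if ("taxon_id" %in% names(x)) x$taxon_id else rownames(x)
    x <- as.matrix(x[, setdiff(names(x), "taxon_id"), drop = FALSE])
    rownames(x) <- ids
  }
  if (!is.numeric(x)) stop("non-numeric input")
  if (nrow(x) < 2L) stop("need at least two taxa to standardise")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  zero <- sdv < .Machine$double.eps^0.5
  if (any(zero))
    stop("zero-variance character(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  structure(z, center = mu, scale = sdv, class = c("sfmd", class(z)))
}
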