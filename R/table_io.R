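#' Read and validate a pipeline input table
#'
#' CSV readers for the four tabular inputs. Column requirements:
#' \describe{
#'   \item{taxa}{`taxon_id`, `clade`, `subclade`, `first_bin`, `last_bin`,
#'     `diet` (herbivore/faunivore).}
#'   \item{measurements}{`taxon_id` plus the ten linear measurements consumed
#'     by [compute_functional_characters()]. Blank numeric cells are kept as
#'     `NA` and reported.}
#'   \item{assemblages}{`locality`, `bin`, `taxon_id`, optional `count`.}
#'   \item{bins}{`bin`, `start_ma`, `end_ma`.}
#' }
#'
#' @param path CSV path with a header row.
#' @param schema one of `"measurements"`, `"taxa"`, `"assemblages"`, `"bins"`.
#' @param taxa optional taxon table against which assemblage members are
#'   checked; unknown taxa are reported in the `"unknown_taxa"` attribute.
#' @return a validated data frame (a `time_bins` table for schema `"bins"`).
#' @export
read_table <- function(path, schema = c("measurements", "taxa", "assemblages", "bins"),
                       taxa = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- switch(schema,
    taxa = c("taxon_id", "clade", "subclade", "first_bin", "last_bin", "diet"),
    measurements = c("taxon_id", measurement_names()),
    assemblages = c("locality", "bin", "taxon_id"),
    bins = c("bin", "start_ma", "end_ma"))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("schema '", schema, "': required column(s) absent: ",
         paste(missing_cols, collapse = ", "))

  if (schema %in% c("taxa", "measurements") && anyDuplicated(tab$taxon_id))
    stop("duplicate taxon_id: ",
         paste(unique(tab$taxon_id[duplicated(tab$taxon_id)]), collapse = ", "))

  if (schema == "measurements") {
    for (col in measurement_names()) {
      v <- tab[[col]]
      if (is.character(v)) {
        v[!nzchar(trimws(v))] <- NA
        num <- suppressWarnings(as.numeric(v))
        if (any(!is.na(v) & is.na(num)))
          stop("non-numeric value in measurement column '", col, "'")
        tab[[col]] <- num
      }
    }
    n_missing <- sum(is.na(tab[, measurement_names()]))
    attr(tab, "n_missing") <- n_missing
    if (n_missing > 0)
      message("read_table: ", n_missing, " missing measurement cell(s)")
  }
  if (schema == "taxa") {
    bad <- setdiff(unique(tab$diet), c("herbivore", "faunivore"))
    if (length(bad)) stop("unknown diet class(es): ", paste(bad, collapse = ", "))
  }
  if (schema == "assemblages") {
    if (!"count" %in% names(tab)) tab$count <- NA_real_
    if (any(!is.na(tab$count) & tab$count < 0)) stop("negative abundance count")
    if (!is.null(taxa)) {
      unknown <- setdiff(unique(tab$taxon_id), taxa$taxon_id)
      attr(tab, "unknown_taxa") <- unknown
      if (length(unknown))
        warning("assemblage members absent from taxon table: ",
                paste(unknown, collapse = ", "))
    }
  }
  if (schema == "bins") tab <- as_time_bins(tab)
  tab
}

measurement_names <- function() {
  c("jaw_length", "tooth_row_length", "max_depth", "symphysis_length",
    "symphysis_angle", "inlever_closing", "inlever_opening",
    "outlever_anterior", "outlever_posterior", "articulation_offset_raw")
}

#' Write a pipeline product to CSV
#'
#' Tabular products are written as plain CSV at full precision so that the
#' matching reader round-trips values to within 1e-9.
#'
#' @param obj a data frame or one of the pipeline's classed products
#'   (`disparity_curve`, `consensus_guilds`, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  UseMethod("write_results")
}

#' @export
write_results.data.frame <- function(obj, path) {
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("unwritable path (no such directory): ", path)
  df <- as.data.frame(obj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- NA
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @export
write_results.matrix <- function(obj, path) {
  df <- as.data.frame(obj)
  if (!is.null(rownames(obj))) df <- cbind(id = rownames(obj), df)
  write_results.data.frame(df, path)
}

#' @export
write_results.default <- function(obj, path) {
  write_results(as.data.frame(unclass(obj)), path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  for (col in names(tab)) {
    v <- tab[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (!any(!is.na(v) & nzchar(v) & is.na(num)) && any(!is.na(num)))
        tab[[col]] <- num
    }
  }
  tab
}
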