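#' Default time-bin scheme (Changhsingian to Toarcian)
#'
#' Stage/substage bins spanning the latest Permian through the end of the
#' Early Jurassic, with the Carnian and Norian split into lower/middle/upper
#' substages. Stage boundary ages (Ma) follow the 2019 International
#' Chronostratigraphic Chart; substage boundaries within the Carnian and
#' Norian, which the chart does not formalise numerically, are interpolated
#' evenly within the stage.
#'
#' @return A data frame of class `time_bins` with columns `bin`, `start_ma`,
#'   `end_ma` and `mid_ma`, ordered from oldest to youngest. `start_ma` is the
#'   older (larger) age of each bin.
#' @export
default_time_bins <- function() {
  split3 <- function(stage, a, b) {
    cuts <- seq(a, b, length.out = 4)
    data.frame(bin = paste(c("lower", "middle", "upper"), stage),
               start_ma = cuts[1:3], end_ma = cuts[2:4])
  }
  bins <- rbind(
    data.frame(bin = "Changhsingian", start_ma = 254.14, end_ma = 251.902),
    data.frame(bin = "Induan",        start_ma = 251.902, end_ma = 251.2),
    data.frame(bin = "Olenekian",     start_ma = 251.2,  end_ma = 247.2),
    data.frame(bin = "Anisian",       start_ma = 247.2,  end_ma = 242),
    data.frame(bin = "Ladinian",      start_ma = 242,    end_ma = 237),
    split3("Carnian", 237, 227),
    split3("Norian", 227, 208.5),
    data.frame(bin = "Rhaetian",      start_ma = 208.5,  end_ma = 201.3),
    data.frame(bin = "Hettangian",    start_ma = 201.3,  end_ma = 199.3),
    data.frame(bin = "Sinemurian",    start_ma = 199.3,  end_ma = 190.8),
    data.frame(bin = "Pliensbachian", start_ma = 190.8,  end_ma = 182.7),
    data.frame(bin = "Toarcian",      start_ma = 182.7,  end_ma = 174.1)
  )
  as_time_bins(bins)
}

#' Validate and classify a time-bin table
#'
#' @param bins data frame with columns `bin`, `start_ma`, `end_ma` (old to
#'   young or young to old; stored old to young).
#' @return the table, ordered oldest first, with `mid_ma` added and class
#'   `time_bins`.
#' @export
as_time_bins <- function(bins) {
  stopifnot(is.data.frame(bins), all(c("bin", "start_ma", "end_ma") %in% names(bins)))
  bins <- bins[order(-bins$start_ma), , drop = FALSE]
  if (anyDuplicated(bins$bin)) stop("duplicate bin names in time-bin scheme")
  if (!all(bins$start_ma > bins$end_ma))
    stop("each bin must have start_ma > end_ma (ages in Ma)")
  if (nrow(bins) > 1 &&
      !isTRUE(all.equal(bins$start_ma[-1], bins$end_ma[-nrow(bins)], tolerance = 1e-8)))
    stop("time bins must be contiguous")
  bins$mid_ma <- (bins$start_ma + bins$end_ma) / 2
  rownames(bins) <- NULL
  class(bins) <- c("time_bins", "data.frame")
  bins
}

#' Position of bin names within a scheme
#'
#' @param bin character vector of bin names.
#' @param bins a `time_bins` table.
#' @return integer indices (1 = oldest); unknown names raise an error.
#' @export
bin_index <- function(bin, bins) {
  idx <- match(bin, bins$bin)
  if (anyNA(idx))
    stop("unknown time bin(s): ", paste(unique(bin[is.na(idx)]), collapse = ", "))
  idx
}
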