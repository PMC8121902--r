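#' Landmark configuration constructor
#'
#' A single specimen's 2D landmark configuration: fixed landmarks plus
#' semilandmark curves along the mandible outline.
#'
#' @param specimen_id specimen/taxon identifier.
#' @param coords numeric matrix, one row per landmark, two columns (x, y).
#'   Coordinates are raw units times the TPS SCALE factor when one is present.
#' @param fixed_indices integer indices of the fixed (non-sliding) landmarks.
#' @param curves list of integer vectors; each vector lists the landmark
#'   indices of one outline curve in order, including its two (fixed or
#'   terminal) anchor points, so the interior points are the semilandmarks.
#' @param scale optional positive scale factor recorded from the source file.
#' @return object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, coords, fixed_indices = integer(),
                            curves = list(), scale = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || !is.numeric(coords))
    stop("coords must be a numeric n x 2 matrix")
  n <- nrow(coords)
  idx <- c(fixed_indices, unlist(curves))
  if (length(idx) && (any(idx < 1L) || any(idx > n)))
    stop("landmark indices out of range for specimen ", specimen_id)
  semis <- setdiff(unlist(lapply(curves, function(cv) cv[-c(1L, length(cv))])),
                   fixed_indices)
  if (anyDuplicated(semis))
    stop("semilandmark appears in more than one curve for specimen ", specimen_id)
  if (!is.null(scale) && (!is.numeric(scale) || scale <= 0))
    stop("scale must be a positive number")
  structure(list(specimen_id = as.character(specimen_id), coords = coords,
                 fixed_indices = as.integer(fixed_indices),
                 curves = lapply(curves, as.integer), scale = scale),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("landmark_config", x$specimen_id, "-", nrow(x$coords), "landmarks (",
      length(x$fixed_indices), "fixed,", length(x$curves), "curves )\n")
  invisible(x)
}

# Semilandmark slider triplets (index, left neighbour, right neighbour)
# implied by the curve structure: interior points of each curve slide along
# the chord between their immediate neighbours; anchors do not slide.
sliders_from_curves <- function(curves) {
  rows <- lapply(curves, function(cv) {
    if (length(cv) < 3L) return(NULL)
    i <- 2L:(length(cv) - 1L)
    cbind(point = cv[i], before = cv[i - 1L], after = cv[i + 1L])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(integer(), 0, 3,
                                  dimnames = list(NULL, c("point", "before", "after")))
  out
}

#' Read a TPS landmark file
#'
#' Accepts the common TPS dialect: `LM=` starts a record, followed by one
#' coordinate line per landmark; optional `CURVES=`/`POINTS=` blocks describe
#' semilandmark curves; `ID=` names the specimen and `SCALE=` gives a scale
#' factor applied to the coordinates. Keys are case-insensitive. When a file
#' carries no CURVES blocks, curve structure may be supplied through a sidecar
#' slider table (see [read_slider_table()]).
#'
#' @param path file path.
#' @param sliders optional slider matrix/data frame with columns
#'   (point, before, after) used to reconstruct curves when the file has none.
#' @return list of [landmark_config()] objects, in file order.
#' @export
read_tps <- function(path, sliders = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("﻿", "", lines)
  key <- toupper(sub("=.*", "", lines))
  starts <- which(key == "LM" & grepl("=", lines, fixed = TRUE))
  if (!length(starts)) stop("no LM= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    out[[r]] <- parse_tps_record(rec, r, sliders)
  }
  out
}

parse_tps_record <- function(rec, record_no, sliders) {
  val <- function(k) {
    hit <- grep(paste0("^\\s*", k, "\\s*="), rec, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^[^=]*=", "", hit[1L]))
  }
  n_lm <- suppressWarnings(as.integer(val("LM")))
  if (is.na(n_lm)) stop("record ", record_no, ": unreadable LM= count")
  is_key <- grepl("^\\s*[A-Za-z]+\\s*=", rec)
  coord_lines <- which(!is_key & nzchar(trimws(rec)))

  # coordinate lines are consumed in order: first n_lm belong to the
  # configuration; any further ones belong to CURVES/POINTS blocks
  parse_xy <- function(ln, what) {
    parts <- strsplit(trimws(rec[ln]), "[ \t,]+")[[1L]]
    xy <- suppressWarnings(as.numeric(parts))
    if (length(xy) != 2L || anyNA(xy))
      stop("record ", record_no, ": non-numeric or malformed ", what,
           " coordinate at line ", ln)
    xy
  }

  n_curves <- suppressWarnings(as.integer(val("CURVES")))
  curve_pts <- integer()
  if (!is.na(n_curves) && !is.null(val("CURVES"))) {
    pts_lines <- grep("^\\s*POINTS\\s*=", rec, ignore.case = TRUE)
    if (length(pts_lines) != n_curves)
      stop("record ", record_no, ": CURVES=", n_curves, " but ",
           length(pts_lines), " POINTS= entries")
    curve_pts <- vapply(pts_lines, function(ln) {
      p <- suppressWarnings(as.integer(sub("^[^=]*=", "", rec[ln])))
      if (is.na(p)) stop("record ", record_no, ": unreadable POINTS= entry")
      p
    }, integer(1))
  } else {
    n_curves <- 0L
  }

  need <- n_lm + sum(curve_pts)
  if (length(coord_lines) < need)
    stop("record ", record_no, ": LM=", n_lm, " (+", sum(curve_pts),
         " curve points) but only ", length(coord_lines), " coordinate lines")
  coords <- t(vapply(coord_lines[seq_len(n_lm)], parse_xy,
                     numeric(2), what = "landmark"))

  id <- val("ID")
  if (is.null(id)) id <- paste0("specimen_", record_no)
  scale <- suppressWarnings(as.numeric(val("SCALE")))
  if (length(scale) && !is.na(scale)) coords <- coords * scale else scale <- NULL

  if (n_curves > 0L) {
    # curve coordinate blocks restate outline points; map them onto the
    # configuration by nearest coordinate match
    off <- n_lm
    curves <- vector("list", n_curves)
    for (ci in seq_len(n_curves)) {
      pts <- t(vapply(coord_lines[off + seq_len(curve_pts[ci])], parse_xy,
                      numeric(2), what = "curve"))
      if (!is.null(scale)) pts <- pts * scale
      curves[[ci]] <- vapply(seq_len(nrow(pts)), function(i) {
        d2 <- (coords[, 1] - pts[i, 1])^2 + (coords[, 2] - pts[i, 2])^2
        which.min(d2)
      }, integer(1))
      off <- off + curve_pts[ci]
    }
    fixed <- setdiff(seq_len(n_lm),
                     unlist(lapply(curves, function(cv) cv[-c(1L, length(cv))])))
  } else if (!is.null(sliders)) {
    curves <- curves_from_sliders(as.matrix(sliders))
    fixed <- setdiff(seq_len(n_lm), sliders[, 1L])
  } else {
    curves <- list()
    fixed <- seq_len(n_lm)
  }
  landmark_config(id, coords, fixed, curves, scale)
}

# Chain slider triplets (point, before, after) back into maximal curves.
curves_from_sliders <- function(sl) {
  sl <- matrix(as.integer(sl), ncol = 3)
  nxt <- stats::setNames(sl[, 3L], sl[, 1L])
  starts <- sl[!(sl[, 2L] %in% sl[, 1L]), , drop = FALSE]
  lapply(seq_len(nrow(starts)), function(i) {
    cv <- c(starts[i, 2L], starts[i, 1L])
    repeat {
      last <- cv[length(cv)]
      if (!as.character(last) %in% names(nxt)) break
      cv <- c(cv, nxt[[as.character(last)]])
    }
    cv
  })
}

#' Read a sidecar semilandmark slider table
#'
#' Three integer columns: the sliding point's index and its left and right
#' neighbours along the outline.
#'
#' @param path CSV path (header required).
#' @return integer matrix with columns point, before, after.
#' @export
read_slider_table <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 3L) stop("slider table needs 3 columns (point, before, after)")
  m <- as.matrix(tab[, 1:3])
  if (!is.numeric(m) || anyNA(m)) stop("slider table must be all-integer")
  storage.mode(m) <- "integer"
  colnames(m) <- c("point", "before", "after")
  m
}

#' Write landmark configurations to a TPS file
#'
#' @param shapes list of `landmark_config` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(shapes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in shapes) {
    writeLines(paste0("LM=", nrow(s$coords)), con)
    writeLines(apply(s$coords, 1L, function(p)
      paste(format(p, digits = 15, scientific = FALSE, trim = TRUE), collapse = " ")), con)
    if (length(s$curves)) {
      writeLines(paste0("CURVES=", length(s$curves)), con)
      for (cv in s$curves) {
        writeLines(paste0("POINTS=", length(cv)), con)
        writeLines(apply(s$coords[cv, , drop = FALSE], 1L, function(p)
          paste(format(p, digits = 15, scientific = FALSE, trim = TRUE), collapse = " ")), con)
      }
    }
    writeLines(paste0("ID=", s$specimen_id), con)
  }
  invisible(path)
}
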