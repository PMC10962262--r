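.detectionCols <- c("frame", "time_s", "tank", "status", "cx", "cy",
                    "bbox_x", "bbox_y", "bbox_w", "bbox_h",
                    "major", "minor", "angle_deg", "area")

.metricsCols <- c("frame", "time_s", "tank", "valid", "speed_cm_s", "moving",
                  "in_end", "in_right_half", "oriented_right", "rfc_cw",
                  "aspect_ratio", "heading_deg", "heading_source")

.checkCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s table lacks columns: %s", what,
                 paste(missing, collapse = ", ")))
  df
}

#' Read and write the pipeline's CSV tables
#'
#' All tabular interchange is UTF-8 CSV with headers. The readers validate
#' the schema and fail listing any missing columns.
#'
#' @param x the table to write.
#' @param path file path.
#' @return readers return the validated data.frame; writers return
#'   \code{path} invisibly.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeDetections <- function(x, path) {
  utils::write.csv(.checkCols(x, .detectionCols, "detections")[.detectionCols],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readDetections <- function(path) {
  .checkCols(utils::read.csv(path, stringsAsFactors = FALSE),
             .detectionCols, "detections")
}

#' @rdname tableIO
#' @export
writeMetrics <- function(x, path) {
  utils::write.csv(.checkCols(x, .metricsCols, "metrics")[.metricsCols],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readMetrics <- function(path) {
  .checkCols(utils::read.csv(path, stringsAsFactors = FALSE),
             .metricsCols, "metrics")
}

# numeric parser tolerant of "%" suffixes and the Unicode minus U+2212
.parseProfileNumber <- function(x) {
  s <- trimws(as.character(x))
  s <- gsub("−", "-", s)
  s <- sub("%$", "", s)
  suppressWarnings(as.numeric(s))
}

#' Read a behavioral-profile table
#'
#' Expects a CSV with the 24 canonical measure columns (see
#' \code{\link{profileMeasureNames}}), in any order, plus optional
#' identifier columns (\code{fish}, \code{group}). Percent cells are
#' accepted with or without a trailing \code{"\%"} and with either the
#' ASCII hyphen or the Unicode minus sign; they are mapped to plain
#' numeric percentage points.
#'
#' @param path CSV path.
#' @return data.frame of profiles with numeric measure columns.
#' @export
readProfileTable <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE, encoding = "UTF-8"),
                 error = function(e) stop("cannot parse profile table: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) == 0) stop("profile table is empty")
  meas <- profileMeasureNames()
  missing <- setdiff(meas, names(df))
  if (length(missing))
    stop("profile table lacks measure columns: ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(names(df), c(meas, "fish", "group"))
  if (length(unknown))
    stop("profile table has unknown columns: ",
         paste(unknown, collapse = ", "))
  for (m in meas) {
    v <- .parseProfileNumber(df[[m]])
    if (any(is.na(v) & !is.na(df[[m]])))
      stop("non-numeric values in column ", m)
    df[[m]] <- v
  }
  df
}

#' Write a behavioral-profile table
#'
#' Emits plain numeric percentage points (no \code{"\%"} suffix) with ASCII
#' hyphens, the canonical measure order, and any identifier columns first.
#'
#' @param profiles data.frame of profiles.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTable <- function(profiles, path) {
  meas <- profileMeasureNames()
  .checkCols(profiles, meas, "profile")
  idCols <- intersect(c("fish", "group"), names(profiles))
  utils::write.csv(profiles[, c(idCols, meas)], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write tank ROI sets as YAML
#'
#' The file holds a \code{tanks} sequence of mappings with \code{tank_id},
#' \code{x0}, \code{y0}, \code{width}, \code{height} and optional
#' \code{mm_per_px} / \code{end_fraction} (defaults 76/70 and 0.20).
#'
#' @param path file path.
#' @param rois list of \code{\link{tankROI}} (for writing).
#' @return \code{readTankROIs} returns a list of \code{TankROI};
#'   \code{writeTankROIs} returns \code{path} invisibly.
#' @export
readTankROIs <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$tanks)) cfg$tanks else cfg
  lapply(entries, function(e) {
    tankROI(e$tank_id, e$x0, e$y0, e$width, e$height,
            mmPerPx = if (is.null(e$mm_per_px)) 76 / 70 else e$mm_per_px,
            endFraction = if (is.null(e$end_fraction)) 0.20 else e$end_fraction)
  })
}

#' @rdname readTankROIs
#' @export
writeTankROIs <- function(rois, path) {
  entries <- lapply(rois, function(r) {
    rc <- r@rect
    list(tank_id = r@tankId, x0 = rc[1], y0 = rc[2],
         width = rc[3], height = rc[4],
         mm_per_px = r@mmPerPx, end_fraction = r@endFraction)
  })
  yaml::write_yaml(list(tanks = entries), path)
  invisible(path)
}
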