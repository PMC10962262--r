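# Angle convention used throughout: degrees in [0, 360) measured from the +x
# axis with y pointing down (image convention). An axis (ellipse) angle lives
# in [0, 180) and is direction-ambiguous; a heading resolves the ambiguity.

.degEps <- 1e-9

.headingVec <- function(deg) {
  rad <- deg * pi / 180
  cbind(cos(rad), sin(rad))
}

#' Speed between two consecutive detections
#'
#' Euclidean centroid displacement converted through the mm-per-pixel scale:
#' \code{speed = |d| px * mmPerPx / 10 / dt} cm/s. Undefined (NA) when either
#' detection is missing.
#'
#' @param prev,curr one-row detection data.frames (or \code{NULL} /
#'   \code{status == "missing"} for an absent detection).
#' @param mmPerPx scale in mm per pixel (default 76/70).
#' @param dt time between the frames, seconds (> 0).
#' @return speed in cm/s, or \code{NA}.
#' @examples
#' a <- data.frame(status = "found", cx = 0, cy = 0)
#' b <- data.frame(status = "found", cx = 70, cy = 0)
#' computeSpeed(a, b)   # 7.6 cm/s at the 76 mm / 70 px scale
#' @export
computeSpeed <- function(prev, curr, mmPerPx = 76 / 70, dt = 1) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive scalar")
  miss <- function(d) is.null(d) || nrow(d) == 0 ||
    (!is.null(d$status) && d$status != "found") || is.na(d$cx)
  if (miss(prev) || miss(curr)) return(NA_real_)
  disp <- sqrt((curr$cx - prev$cx)^2 + (curr$cy - prev$cy)^2)
  disp * mmPerPx / 10 / dt
}

#' Movement flag from speed
#'
#' A frame counts as moving when the fish swam strictly faster than 1 cm/s.
#' NA speeds propagate.
#'
#' @param speed speed in cm/s; vectorized.
#' @return logical vector (NA where speed is NA).
#' @examples
#' classifyMoving(c(7.6, 1.0, NA))
#' @export
classifyMoving <- function(speed) {
  speed > 1.0
}

#' End-zone and right-half occupancy flags
#'
#' With W the tank width and f the end fraction: the fish is in an end zone
#' when \code{cx < f*W} or \code{cx >= (1-f)*W}, and in the right half when
#' \code{cx > W/2} (the exact center counts as left).
#'
#' @param cx tank-local centroid x in px; vectorized; NA for missing
#'   detections.
#' @param roi the \code{\link{tankROI}}.
#' @return data.frame with logical columns \code{in_end} and
#'   \code{in_right_half} (NA where \code{cx} is NA).
#' @examples
#' roi <- tankROI(1, 0, 0, 320, 240)
#' zoneFlags(c(16, 160, 272), roi)
#' @export
zoneFlags <- function(cx, roi) {
  W <- roiWidth(roi)
  f <- endFraction(roi)
  data.frame(
    in_end = cx < f * W | cx >= (1 - f) * W,
    in_right_half = cx > W / 2
  )
}

# Vectorized heading candidates: the ellipse axis disambiguated by where the
# centroid sits relative to the bounding-box center (the centroid lies toward
# the heavier head/trunk). Returns NA where the projection of that offset on
# the axis is below minOffsetPx.
.headingCandidate <- function(angleDeg, cx, cy, bboxX, bboxY, bboxW, bboxH,
                              minOffsetPx = 0.2) {
  u <- .headingVec(angleDeg)
  vx <- cx - (bboxX + (bboxW - 1) / 2)
  vy <- cy - (bboxY + (bboxH - 1) / 2)
  proj <- vx * u[, 1] + vy * u[, 2]
  out <- ifelse(proj > 0, angleDeg %% 180, (angleDeg + 180) %% 360)
  out[abs(proj) < minOffsetPx] <- NA_real_
  out
}

#' Resolve a fish heading from one detection
#'
#' The moment ellipse fixes the body axis only modulo 180 degrees. The head
#' side is chosen so the heading points from the bounding-box center toward
#' the centroid (projected on the axis): the centroid sits toward the
#' heavier head/trunk. If the projection magnitude is below
#' \code{minOffsetPx} the previous heading is carried forward
#' (\code{source = "carried_forward"}); with no previous heading the result
#' is undefined.
#'
#' @param det one-row found detection (needs \code{angle_deg}, \code{cx},
#'   \code{cy} and the bbox columns).
#' @param prev previous heading in degrees, or \code{NA}.
#' @param minOffsetPx minimum axis projection of the centroid-vs-bbox-center
#'   offset, px (default 0.2).
#' @return list with \code{angle} (degrees in [0, 360) or NA) and
#'   \code{source} (\code{"head_cue"}, \code{"carried_forward"} or
#'   \code{"undefined"}).
#' @export
resolveHeading <- function(det, prev = NA_real_, minOffsetPx = 0.2) {
  stopifnot(nrow(det) == 1, det$status == "found")
  cand <- .headingCandidate(det$angle_deg, det$cx, det$cy, det$bbox_x,
                            det$bbox_y, det$bbox_w, det$bbox_h, minOffsetPx)
  if (!is.na(cand)) return(list(angle = cand, source = "head_cue"))
  if (!is.na(prev)) return(list(angle = prev, source = "carried_forward"))
  list(angle = NA_real_, source = "undefined")
}

# Right flank toward tank center, vectorized over headings/positions. Under
# the y-down convention the fish's right side points along the heading
# rotated +90 degrees: r = (-u_y, u_x). True iff r . (center - position) > 0;
# a persistent TRUE corresponds to clockwise circling seen from above.
.rfcFlagVec <- function(headingDeg, cx, cy, roi) {
  u <- .headingVec(headingDeg)
  rx <- -u[, 2]
  ry <- u[, 1]
  ccx <- roiWidth(roi) / 2 - cx
  ccy <- roiHeight(roi) / 2 - cy
  rx * ccx + ry * ccy > 0
}

#' Right-flank-to-center flag
#'
#' @param headingDeg heading in degrees (NA gives NA); vectorized.
#' @param cx,cy tank-local position, px.
#' @param roi the \code{\link{tankROI}}.
#' @return logical vector; a tie (right flank exactly tangential) is FALSE.
#' @examples
#' roi <- tankROI(1, 0, 0, 320, 240)
#' rfcFlag(270, 10, 120, roi)   # heading up-screen at the left wall: TRUE
#' @export
rfcFlag <- function(headingDeg, cx, cy, roi) {
  .rfcFlagVec(headingDeg, cx, cy, roi)
}

# oriented-right: heading has a strictly positive x-component; exact +/-90
# maps to FALSE.
.orientedRightVec <- function(headingDeg) {
  a <- headingDeg %% 360
  ifelse(is.na(a), NA, abs(a - 90) > .degEps & abs(a - 270) > .degEps &
           (a < 90 | a > 270))
}

#' Per-frame behavioral metrics from the detection stream
#'
#' For every detection row computes: speed (defined only when the current
#' and the immediately preceding frame of the same tank are both found; no
#' interpolation across gaps), the moving flag (speed > 1 cm/s), end-zone
#' and right-half occupancy, the resolved heading with carry-forward across
#' ambiguous frames, the oriented-right flag (heading with positive
#' x-component), the right-flank-to-center flag, and the ellipse aspect
#' ratio.
#'
#' @param detections detections table from \code{\link{analyzeMovie}},
#'   ordered by (frame, tank).
#' @param rois list of \code{\link{tankROI}}; must cover every tank id in
#'   the table.
#' @param intervalS seconds between consecutive frames.
#' @param minOffsetPx heading disambiguation threshold, px.
#' @return the metrics table: data.frame with columns \code{frame},
#'   \code{time_s}, \code{tank}, \code{valid}, \code{speed_cm_s},
#'   \code{moving}, \code{in_end}, \code{in_right_half},
#'   \code{oriented_right}, \code{rfc_cw}, \code{aspect_ratio},
#'   \code{heading_deg}, \code{heading_source}.
#' @export
metricsSeries <- function(detections, rois, intervalS = 1, minOffsetPx = 0.2) {
  req <- c("frame", "time_s", "tank", "status", "cx", "cy")
  if (!all(req %in% names(detections)))
    stop("detections table lacks columns: ",
         paste(setdiff(req, names(detections)), collapse = ", "))
  o <- order(detections$frame, detections$tank)
  if (!identical(o, seq_len(nrow(detections))))
    stop("detections must be ordered by (frame, tank)")
  roiIds <- vapply(rois, tankId, integer(1))
  if (!all(detections$tank %in% roiIds))
    stop("no ROI supplied for tank(s): ",
         paste(setdiff(unique(detections$tank), roiIds), collapse = ", "))

  n <- nrow(detections)
  out <- data.frame(
    frame = detections$frame, time_s = detections$time_s,
    tank = detections$tank, valid = detections$status == "found",
    speed_cm_s = NA_real_, moving = NA, in_end = NA, in_right_half = NA,
    oriented_right = NA, rfc_cw = NA, aspect_ratio = NA_real_,
    heading_deg = NA_real_, heading_source = "undefined",
    stringsAsFactors = FALSE
  )
  for (tid in unique(detections$tank)) {
    roi <- rois[[match(tid, roiIds)]]
    rows <- which(detections$tank == tid)
    d <- detections[rows, ]
    found <- d$status == "found"
    # speed: needs found in this and the immediately preceding frame
    adj <- c(FALSE, diff(d$frame) == 1)
    ok <- found & adj & c(FALSE, found[-length(found)])
    disp <- c(NA, sqrt(diff(d$cx)^2 + diff(d$cy)^2))
    spd <- ifelse(ok, disp * mmPerPx(roi) / 10 / intervalS, NA_real_)
    out$speed_cm_s[rows] <- spd
    out$moving[rows] <- classifyMoving(spd)
    zf <- zoneFlags(ifelse(found, d$cx, NA_real_), roi)
    out$in_end[rows] <- zf$in_end
    out$in_right_half[rows] <- zf$in_right_half
    # heading with carry-forward over found frames
    cand <- rep(NA_real_, nrow(d))
    cand[found] <- .headingCandidate(
      d$angle_deg[found], d$cx[found], d$cy[found], d$bbox_x[found],
      d$bbox_y[found], d$bbox_w[found], d$bbox_h[found], minOffsetPx)
    src <- ifelse(found & !is.na(cand), "head_cue", "undefined")
    heading <- cand
    last <- NA_real_
    for (j in seq_len(nrow(d))) {
      if (!found[j]) next
      if (is.na(heading[j])) {
        if (!is.na(last)) {
          heading[j] <- last
          src[j] <- "carried_forward"
        }
      }
      last <- heading[j]
    }
    out$heading_deg[rows] <- heading
    out$heading_source[rows] <- src
    out$oriented_right[rows] <- .orientedRightVec(heading)
    out$rfc_cw[rows] <- ifelse(is.na(heading), NA,
                               .rfcFlagVec(heading, d$cx, d$cy, roi))
    out$aspect_ratio[rows] <- ifelse(found, d$major / d$minor, NA_real_)
  }
  out
}

#' Mirror a detections table across the tank midline
#'
#' Reflects x-coordinates (positions, bounding boxes and ellipse angles) of
#' every detection through \code{x -> W - x}. Useful for anti-symmetry
#' checks: mirroring negates right-half occupancy, right orientation and the
#' clockwise flag while preserving speed, movement and end-zone occupancy.
#'
#' @param detections detections table (tank-local coordinates).
#' @param roi the \code{\link{tankROI}} the coordinates refer to.
#' @return the mirrored detections table.
#' @export
mirrorDetections <- function(detections, roi) {
  W <- roiWidth(roi)
  m <- detections
  f <- m$status == "found"
  m$cx[f] <- W - m$cx[f]
  if ("bbox_x" %in% names(m))
    m$bbox_x[f] <- W - (m$bbox_x[f] + m$bbox_w[f] - 1)
  if ("angle_deg" %in% names(m))
    m$angle_deg[f] <- (180 - m$angle_deg[f]) %% 180
  m
}
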