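#' Simulate one ground-truthed tank trajectory
#'
#' Discrete-time biased random walk in continuous tank-local pixel
#' coordinates at one step per frame. Each frame the fish attempts a
#' movement step with probability \code{pMove} (multiplied by the startle
#' factor in the first period after a blank-to-lines transition, the
#' surplus decaying by \code{habituationRate} per transition). A moving
#' step draws a speed from the zero-truncated normal
#' \code{(baseSpeed, sigmaSpeed)} and a direction from the drift vector
#' combining heading persistence, attraction to the nearest long wall
#' (\code{wallBias}), attraction to the nearest end (\code{endBias}) and
#' the optomotor term \code{omrGain} (decayed by \code{habituationRate} per
#' stimulus period) aligned with the line motion, plus angular noise.
#' Walls reflect, with a safety margin so a rendered body stays inside the
#' ROI. The body heading follows the intended swim direction while moving
#' (a wall stopping the step does not spin the fish) and persists while
#' stationary. The walk is fully deterministic given
#' \code{params@seed}.
#'
#' Per-frame flags (\code{moving}, \code{in_end}, \code{in_right_half},
#' \code{oriented_right}, \code{rfc_cw}) and the realized speed are
#' bookkept from the realized positions and headings with exactly the
#' kinematics definitions, via \code{\link{expectedFlags}}.
#'
#' @param params a \code{\link{behaviorParams}} object.
#' @param sched an \code{\link[=ExperimentSchedule-class]{ExperimentSchedule}}.
#' @param roi the \code{\link{tankROI}} the fish lives in.
#' @param intervalS frame interval in seconds (default 1).
#' @param marginPx reflecting-wall margin in px (default 16, half a rendered
#'   body length plus clearance).
#' @return a ground-truth track: data.frame with columns \code{frame}
#'   (0-based), \code{time_s}, \code{tank}, \code{x}, \code{y},
#'   \code{heading_deg}, \code{speed_cm_s}, \code{moving}, \code{in_end},
#'   \code{in_right_half}, \code{oriented_right}, \code{rfc_cw},
#'   \code{period}.
#' @examples
#' sched <- defaultSchedule(periodS = 10)   # compressed trial for a demo
#' roi <- defaultTankROIs()[[1]]
#' tr <- simulateTrajectory(behaviorParams(seed = 7), sched, roi)
#' mean(tr$in_right_half)
#' @export
simulateTrajectory <- function(params, sched, roi, intervalS = 1,
                               marginPx = 16) {
  stopifnot(is(params, "BehaviorParams"), is(sched, "ExperimentSchedule"),
            is(roi, "TankROI"))
  validObject(params)
  p <- periods(sched)
  total <- p$end_s[nrow(p)]
  nFrames <- as.integer(round(total / intervalS))
  W <- roiWidth(roi); H <- roiHeight(roi)
  if (W <= 2 * marginPx || H <= 2 * marginPx)
    stop("ROI too small for the wall margin")

  # per-period stimulus bookkeeping
  isStim <- p$kind == "moving_lines"
  stimRank <- cumsum(isStim)                       # 1 for first lines period
  omrMult <- ifelse(isStim, params@habituationRate^(pmax(stimRank - 1, 0)), 0)
  transition <- isStim & c(FALSE, !isStim[-length(isStim)])
  transRank <- cumsum(transition)
  startleMult <- rep(1, nrow(p))
  startleMult[transition] <-
    1 + (params@startleGain - 1) *
    params@habituationRate^(transRank[transition] - 1)
  lineDir <- ifelse(p$direction == "leftward", -1,
             ifelse(p$direction == "rightward", 1, 0))

  times <- (0:(nFrames - 1)) * intervalS
  perIdx <- findInterval(times, p$start_s)

  set.seed(params@seed)
  x <- numeric(nFrames); y <- numeric(nFrames)
  heading <- numeric(nFrames); realSpeed <- rep(NA_real_, nFrames)
  x[1] <- stats::runif(1, marginPx, W - marginPx)
  y[1] <- stats::runif(1, marginPx, H - marginPx)
  heading[1] <- stats::runif(1, 0, 360)
  turnSd <- params@turnSigmaDeg * pi / 180
  pxPerCm <- 10 / mmPerPx(roi)
  reflect <- function(v, lo, hi) {
    span <- 2 * (hi - lo)
    v <- (v - lo) %% span
    lo + ifelse(v > hi - lo, span - v, v)
  }
  p0 <- stats::pnorm(0, params@baseSpeed, params@sigmaSpeed)
  for (i in 2:nFrames) {
    pi_ <- perIdx[i]
    pm <- min(1, params@pMove * startleMult[pi_])
    if (stats::runif(1) < pm) {
      spd <- if (params@sigmaSpeed == 0) params@baseSpeed else
        stats::qnorm(p0 + stats::runif(1) * (1 - p0),
                     params@baseSpeed, params@sigmaSpeed)
      hRad <- heading[i - 1] * pi / 180
      wallVec <- c(0, if (y[i - 1] < H / 2) -1 else 1)
      endVec <- c(if (x[i - 1] < W / 2) -1 else 1, 0)
      omrVec <- c(params@omrGain * omrMult[pi_] * lineDir[pi_], 0)
      drift <- c(cos(hRad), sin(hRad)) +
        params@wallBias * wallVec + params@endBias * endVec + omrVec
      theta <- if (sum(drift^2) < 1e-12) hRad else atan2(drift[2], drift[1])
      theta <- theta + stats::rnorm(1, 0, turnSd)
      step <- spd * pxPerCm * intervalS
      x[i] <- reflect(x[i - 1] + step * cos(theta), marginPx, W - marginPx)
      y[i] <- reflect(y[i - 1] + step * sin(theta), marginPx, H - marginPx)
      # body orientation follows the intended swim direction; a wall that
      # stops or deflects the step does not spin the fish around
      heading[i] <- (theta * 180 / pi) %% 360
    } else {
      x[i] <- x[i - 1]; y[i] <- y[i - 1]
      heading[i] <- heading[i - 1]
    }
    disp <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
    realSpeed[i] <- disp * mmPerPx(roi) / 10 / intervalS
  }
  track <- data.frame(
    frame = 0:(nFrames - 1), time_s = times, tank = tankId(roi),
    x = x, y = y, heading_deg = heading, period = perIdx
  )
  flags <- expectedFlags(track, roi, intervalS = intervalS)
  track$speed_cm_s <- flags$speed_cm_s
  track$moving <- flags$moving
  track$in_end <- flags$in_end
  track$in_right_half <- flags$in_right_half
  track$oriented_right <- flags$oriented_right
  track$rfc_cw <- flags$rfc_cw
  track
}

#' Exact expected per-frame metrics of a ground-truth track
#'
#' Applies the kinematics definitions directly to the true positions and
#' headings (no imaging): speed from consecutive positions through the
#' mm-per-pixel scale, moving as speed > 1 cm/s, end-zone / right-half
#' occupancy from x, oriented-right from the heading's x-component and the
#' right-flank-to-center flag from the rotated heading. This is the exact
#' output the kinematics module produces on perfect detections of the same
#' track.
#'
#' @param track data.frame with columns \code{frame}, \code{time_s},
#'   \code{x}, \code{y}, \code{heading_deg} (and optionally \code{tank}).
#' @param roi the \code{\link{tankROI}}.
#' @param intervalS frame interval, seconds.
#' @return a metrics table with the same columns as
#'   \code{\link{metricsSeries}} output.
#' @export
expectedFlags <- function(track, roi, intervalS = 1) {
  n <- nrow(track)
  disp <- c(NA, sqrt(diff(track$x)^2 + diff(track$y)^2))
  adj <- c(FALSE, diff(track$frame) == 1)
  spd <- ifelse(adj, disp * mmPerPx(roi) / 10 / intervalS, NA_real_)
  zf <- zoneFlags(track$x, roi)
  data.frame(
    frame = track$frame, time_s = track$time_s,
    tank = if (is.null(track$tank)) tankId(roi) else track$tank,
    valid = TRUE,
    speed_cm_s = spd, moving = classifyMoving(spd),
    in_end = zf$in_end, in_right_half = zf$in_right_half,
    oriented_right = .orientedRightVec(track$heading_deg),
    rfc_cw = .rfcFlagVec(track$heading_deg, track$x, track$y, roi),
    aspect_ratio = NA_real_,
    heading_deg = track$heading_deg,
    heading_source = "head_cue",
    stringsAsFactors = FALSE
  )
}

#' Perfect detections from a ground-truth track
#'
#' Converts true positions and headings into the detection geometry an
#' ideal imaging stage would report: centroid at the true position, ellipse
#' axis along the heading, and the bounding-box center displaced by
#' \code{headOffsetPx} opposite the heading (the centroid sits toward the
#' head), so the heading resolution rule recovers the true heading exactly.
#'
#' @param track a ground-truth track.
#' @param roi the \code{\link{tankROI}}.
#' @param bodyMajorPx,bodyMinorPx full ellipse axes, px.
#' @param headOffsetPx centroid-to-bbox-center offset along the heading, px.
#' @return a detections table with the \code{\link{analyzeMovie}} schema.
#' @export
trackDetections <- function(track, roi, bodyMajorPx = 28, bodyMinorPx = 8,
                            headOffsetPx = 0.8) {
  h <- track$heading_deg * pi / 180
  ux <- cos(h); uy <- sin(h)
  bcx <- track$x - headOffsetPx * ux
  bcy <- track$y - headOffsetPx * uy
  bw <- abs(bodyMajorPx * ux) + abs(bodyMinorPx * uy)
  bh <- abs(bodyMajorPx * uy) + abs(bodyMinorPx * ux)
  data.frame(
    frame = track$frame, time_s = track$time_s, tank = track$tank,
    status = "found",
    cx = track$x, cy = track$y,
    bbox_x = bcx - (bw - 1) / 2, bbox_y = bcy - (bh - 1) / 2,
    bbox_w = bw, bbox_h = bh,
    major = bodyMajorPx, minor = bodyMinorPx,
    angle_deg = track$heading_deg %% 180,
    area = pi * bodyMajorPx * bodyMinorPx / 4,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of fish, one per tank
#'
#' @param params a \code{\link{behaviorParams}} object; fish i uses seed
#'   \code{seed + i - 1} unless \code{seeds} is given.
#' @param rois list of \code{\link{tankROI}} objects.
#' @param sched the schedule.
#' @param intervalS frame interval, seconds.
#' @param seeds optional integer vector of per-fish seeds.
#' @return list of ground-truth tracks, one per ROI.
#' @export
simulateCohort <- function(params, rois, sched, intervalS = 1, seeds = NULL) {
  if (is.null(seeds)) seeds <- params@seed + seq_along(rois) - 1L
  stopifnot(length(seeds) == length(rois))
  lapply(seq_along(rois), function(i) {
    pi_ <- params
    pi_@seed <- as.integer(seeds[i])
    simulateTrajectory(pi_, sched, rois[[i]], intervalS = intervalS)
  })
}

#' Combined perfect detections of a cohort
#'
#' @param tracks list of tracks (one per ROI, equal frame counts).
#' @param rois matching list of ROIs.
#' @param ... passed to \code{\link{trackDetections}}.
#' @return one detections table ordered by (frame, tank).
#' @export
cohortDetections <- function(tracks, rois, ...) {
  stopifnot(length(tracks) == length(rois))
  det <- do.call(rbind, lapply(seq_along(tracks), function(i)
    trackDetections(tracks[[i]], rois[[i]], ...)))
  det <- det[order(det$frame, det$tank), ]
  rownames(det) <- NULL
  det
}

#' Rendering settings for synthetic frames
#'
#' @param background background gray value (all channels), default 245.
#'   The tank bottom is near-white, so its red channel sits close to the
#'   saturated red of the stripe stimulus and thresholding ignores the
#'   stripes.
#' @param fishValue fish body value (all channels), default 30.
#' @param bodyMajorPx,bodyMinorPx full body axes, px (default 28 x 8, an
#'   adult zebrafish at the 76 mm / 70 px scale).
#' @param headSkew head-weighted width asymmetry in [0, 1): the body half
#'   width scales with \code{1 + headSkew * s / a} along the axis, so the
#'   raster centroid sits \code{headSkew * a / 4} toward the head of the
#'   geometric center.
#' @param stripes draw the red moving-line stimulus (default TRUE).
#' @return a list of rendering constants.
#' @export
renderConfig <- function(background = 245, fishValue = 30,
                         bodyMajorPx = 28, bodyMinorPx = 8,
                         headSkew = 0.3, stripes = TRUE) {
  stopifnot(headSkew >= 0, headSkew < 1, bodyMajorPx >= bodyMinorPx)
  list(background = background, fishValue = fishValue,
       bodyMajorPx = bodyMajorPx, bodyMinorPx = bodyMinorPx,
       headSkew = headSkew, stripes = stripes)
}

# draw one egg-shaped fish body into an RGB array (in place via returned arr)
.drawFish <- function(arr, cxg, cyg, headingDeg, cfg) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  a <- cfg$bodyMajorPx / 2; b <- cfg$bodyMinorPx / 2; k <- cfg$headSkew
  hRad <- headingDeg * pi / 180
  ux <- cos(hRad); uy <- sin(hRad)
  # shift the geometric center so the raster centroid lands on (cxg, cyg)
  gx <- cxg - (k * a / 4) * ux
  gy <- cyg - (k * a / 4) * uy
  xs <- max(0, floor(gx - a - 2)):min(W - 1, ceiling(gx + a + 2))
  ys <- max(0, floor(gy - a - 2)):min(H - 1, ceiling(gy + a + 2))
  dx <- outer(rep(1, length(ys)), xs - gx)
  dy <- outer(ys - gy, rep(1, length(xs)))
  s <- dx * ux + dy * uy
  tt <- -dx * uy + dy * ux
  wfac <- 1 + k * s / a
  inside <- abs(s) <= a & wfac > 0 & (s / a)^2 + (tt / (b * wfac))^2 <= 1
  if (any(inside)) {
    rows <- ys[row(inside)[inside]] + 1L
    cols <- xs[col(inside)[inside]] + 1L
    for (ch in 1:3) arr[cbind(rows, cols, ch)] <- cfg$fishValue
  }
  arr
}

#' Render synthetic frames of a multi-tank movie
#'
#' Produces a frame source (see \code{\link{frameSource}}) drawing, for each
#' requested frame: a light-gray background, pure-red (255, 0, 0) stripe
#' patterns of the schedule's thickness/spacing translated at the
#' schedule's speed during moving-line periods, and one dark egg-shaped
#' fish per ROI at its track position and heading. The head-weighted body
#' asymmetry displaces the bounding-box center away from the centroid along
#' the heading, giving the detection stage its head cue. Stripe phase and
#' period lookup use each track row's absolute \code{time_s}, so a
#' row-subset of a track renders the matching portion of the trial.
#'
#' @param tracks list of ground-truth tracks, one per ROI, equal row counts.
#' @param rois matching list of \code{\link{tankROI}} objects.
#' @param sched the schedule (for stripe geometry and timing).
#' @param cfg a \code{\link{renderConfig}}.
#' @param frameWidth,frameHeight canvas size, px.
#' @return a frame source: \code{list(get = function(i), n)} with \code{i}
#'   0-based; \code{get} returns a \code{frameHeight x frameWidth x 3}
#'   array in 0..255.
#' @export
renderFrames <- function(tracks, rois, sched, cfg = renderConfig(),
                         frameWidth = 640, frameHeight = 960) {
  stopifnot(length(tracks) == length(rois))
  ns <- vapply(tracks, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("all tracks must have the same frame count")
  p <- periods(sched)
  total <- p$end_s[nrow(p)]
  getFrame <- function(i) {
    arr <- array(cfg$background, c(frameHeight, frameWidth, 3))
    t_ <- tracks[[1]]$time_s[i + 1]
    per <- p[findInterval(min(t_, total - 1e-9), p$start_s), ]
    for (j in seq_along(rois)) {
      roi <- rois[[j]]
      r <- roi@rect
      if (cfg$stripes && per$kind == "moving_lines") {
        thPx <- per$thickness_mm / mmPerPx(roi)
        spPx <- per$spacing_mm / mmPerPx(roi)
        periodPx <- thPx + spPx
        speedPx <- per$speed_cm_s * 10 / mmPerPx(roi)
        dir <- if (per$direction == "rightward") 1 else -1
        xloc <- 0:(r[3] - 1)
        phase <- (xloc - dir * speedPx * t_) %% periodPx
        redCols <- which(phase < thPx)
        if (length(redCols)) {
          rowsIdx <- (r[2] + 1):(r[2] + r[4])
          colsIdx <- r[1] + redCols
          arr[rowsIdx, colsIdx, 1] <- 255
          arr[rowsIdx, colsIdx, 2] <- 0
          arr[rowsIdx, colsIdx, 3] <- 0
        }
      }
      tr <- tracks[[j]][i + 1, ]
      arr <- .drawFish(arr, r[1] + tr$x, r[2] + tr$y, tr$heading_deg, cfg)
    }
    arr
  }
  list(get = getFrame, n = ns[1])
}
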