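#' @import methods
NULL

.PHASES <- c("baseline", "stimulus", "post")
.KINDS <- c("blank", "moving_lines")
.DIRECTIONS <- c("none", "leftward", "rightward")

.scheduleColumns <- c(
  "index", "start_s", "end_s", "phase", "kind", "direction",
  "thickness_mm", "spacing_mm", "speed_cm_s"
)

#' Stimulus timeline of a behavioral trial
#'
#' An \code{ExperimentSchedule} holds the ordered sequence of equal-length
#' analysis periods making up one trial, together with the visual stimulus
#' shown in each period. The canonical trial (see
#' \code{\link{defaultSchedule}}) consists of 18 ten-minute periods: a
#' baseline hour with a blank background, an hour of moving red lines of
#' increasing thickness alternating leftward/rightward, and a post-stimulus
#' blank hour.
#'
#' @slot periods a \code{data.frame} with one row per period and columns
#'   \code{index}, \code{start_s}, \code{end_s} (half-open \code{[start, end)}
#'   seconds from trial start), \code{phase} (\code{baseline} /
#'   \code{stimulus} / \code{post}), \code{kind} (\code{blank} /
#'   \code{moving_lines}), \code{direction} (\code{none} / \code{leftward} /
#'   \code{rightward}), \code{thickness_mm}, \code{spacing_mm} and
#'   \code{speed_cm_s}.
#'
#' @seealso \code{\link{defaultSchedule}}, \code{\link{periodOf}},
#'   \code{\link{phaseOf}}, \code{\link{readSchedule}}
#' @exportClass ExperimentSchedule
setClass("ExperimentSchedule", representation(periods = "data.frame"))

setValidity("ExperimentSchedule", function(object) {
  p <- object@periods
  msgs <- character()
  if (!all(.scheduleColumns %in% names(p)))
    return(paste("periods must have columns:", paste(.scheduleColumns, collapse = ", ")))
  n <- nrow(p)
  if (n < 3) msgs <- c(msgs, "a schedule needs at least 3 periods")
  if (n %% 3 != 0) msgs <- c(msgs, "number of periods must split into three equal phases")
  if (!identical(p$index, seq_len(n))) msgs <- c(msgs, "period indices must be 1..n in order")
  if (n >= 1 && p$start_s[1] != 0) msgs <- c(msgs, "first period must start at t = 0")
  if (any(p$end_s <= p$start_s)) msgs <- c(msgs, "periods must have positive duration")
  durs <- p$end_s - p$start_s
  if (max(durs) - min(durs) > 1e-9) msgs <- c(msgs, "all periods must have equal duration")
  if (n > 1 && any(abs(p$start_s[-1] - p$end_s[-n]) > 1e-9))
    msgs <- c(msgs, "periods must be contiguous")
  third <- n / 3
  expected_phase <- rep(.PHASES, each = third)
  if (n %% 3 == 0 && !identical(as.character(p$phase), expected_phase))
    msgs <- c(msgs, "phases must be baseline/stimulus/post in three equal blocks")
  if (!all(p$kind %in% .KINDS)) msgs <- c(msgs, "unknown stimulus kind")
  if (!all(p$direction %in% .DIRECTIONS)) msgs <- c(msgs, "unknown stimulus direction")
  blank <- p$kind == "blank"
  if (any(blank & (p$direction != "none" | p$thickness_mm != 0 |
                   p$spacing_mm != 0 | p$speed_cm_s != 0)))
    msgs <- c(msgs, "blank periods must have direction 'none' and zero line geometry")
  lines <- p$kind == "moving_lines"
  if (any(lines & (p$direction == "none" | p$thickness_mm <= 0 |
                   p$spacing_mm <= 0 | p$speed_cm_s <= 0)))
    msgs <- c(msgs, "moving_lines periods need a direction and positive thickness/spacing/speed")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Rectangular region of interest for one tank
#'
#' A \code{TankROI} locates one tank inside the combined camera frame and
#' carries the geometric constants needed to interpret positions inside it:
#' the mm-per-pixel scale (default 76 mm / 70 px from the arena calibration)
#' and the fraction of tank length counted as "end zone" at each of the left
#' and right ends (default 0.20). All detection coordinates are reported
#' tank-locally with the ROI origin at its top-left corner, x rightward and
#' y downward.
#'
#' @slot tankId integer tank identifier (1..8 in the canonical layout).
#' @slot rect numeric length-4 \code{(x0, y0, width, height)} in frame pixels,
#'   zero-based origin.
#' @slot mmPerPx physical scale in mm per pixel.
#' @slot endFraction fraction of tank width forming each end zone, in (0, 0.5).
#'
#' @seealso \code{\link{tankROI}}, \code{\link{defaultTankROIs}}
#' @exportClass TankROI
setClass("TankROI", representation(
  tankId = "integer", rect = "numeric",
  mmPerPx = "numeric", endFraction = "numeric"
))

setValidity("TankROI", function(object) {
  msgs <- character()
  if (length(object@rect) != 4) msgs <- c(msgs, "rect must be (x0, y0, width, height)")
  else {
    if (any(object@rect[3:4] <= 0)) msgs <- c(msgs, "ROI width/height must be positive")
    if (any(object@rect[1:2] < 0)) msgs <- c(msgs, "ROI origin must be non-negative")
  }
  if (length(object@mmPerPx) != 1 || object@mmPerPx <= 0)
    msgs <- c(msgs, "mmPerPx must be a positive scalar")
  if (length(object@endFraction) != 1 ||
      object@endFraction <= 0 || object@endFraction >= 0.5)
    msgs <- c(msgs, "endFraction must lie in (0, 0.5)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Particle-analysis settings for fish detection
#'
#' Controls how each tank ROI of the red channel is thresholded and which
#' connected components are accepted as candidate fish. Foreground is always
#' the set of pixels strictly darker than the threshold (dark fish on a light
#' tank bottom); components are 8-connected and filtered to
#' \code{[minArea, maxArea]} square pixels. The default Otsu mode recomputes
#' the threshold per ROI per frame, which tolerates illumination differences
#' between tanks; a fixed global threshold is available for strict
#' reproducibility.
#'
#' @slot thresholdMode \code{"otsu"} or \code{"fixed"}.
#' @slot fixedThreshold threshold in 0..255 used when \code{thresholdMode}
#'   is \code{"fixed"}; foreground is \code{gray < fixedThreshold}.
#' @slot minArea,maxArea accepted particle area range in px^2. Defaults 50
#'   and 2000 bracket an adult zebrafish (~28 x 7 px at 76 mm / 70 px).
#'
#' @seealso \code{\link{detectionConfig}}, \code{\link{segmentParticles}}
#' @exportClass DetectionConfig
setClass("DetectionConfig", representation(
  thresholdMode = "character", fixedThreshold = "numeric",
  minArea = "numeric", maxArea = "numeric"
))

setValidity("DetectionConfig", function(object) {
  msgs <- character()
  if (!object@thresholdMode %in% c("otsu", "fixed"))
    msgs <- c(msgs, "thresholdMode must be 'otsu' or 'fixed'")
  if (object@fixedThreshold < 0 || object@fixedThreshold > 255)
    msgs <- c(msgs, "fixedThreshold must be in 0..255")
  if (!(object@minArea > 0 && object@minArea < object@maxArea))
    msgs <- c(msgs, "need 0 < minArea < maxArea")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Ground-truth behavioral parameters of a simulated fish
#'
#' Parameterizes the biased random walk used by
#' \code{\link{simulateTrajectory}}. A simulated fish attempts a movement
#' step with probability \code{pMove} each frame; when moving it draws a
#' speed from a zero-truncated normal and heads along a drift vector that
#' combines persistence, attraction to the nearest long wall (thigmotaxis),
#' attraction to the nearest tank end, and an optomotor term aligned with
#' (positive \code{omrGain}) or against (negative \code{omrGain}) the moving
#' lines. \code{startleGain} multiplies \code{pMove} in the first period
#' after each blank-to-lines transition and \code{habituationRate} decays
#' both the optomotor gain and the startle effect across successive
#' stimulus periods.
#'
#' @slot baseSpeed mean of the truncated-normal speed draw, cm/s.
#' @slot sigmaSpeed spread of the speed draw, cm/s.
#' @slot pMove per-frame probability of attempting a movement step.
#' @slot wallBias drift strength toward the nearest long wall (unitless, >= 0).
#' @slot endBias drift strength toward the nearest left/right end (>= 0).
#' @slot omrGain signed optomotor drift strength; positive swims with the
#'   lines, negative against them.
#' @slot startleGain multiplier applied to \code{pMove} in the first period
#'   after a blank-to-lines transition.
#' @slot habituationRate per-stimulus-period decay in (0, 1] applied to the
#'   optomotor gain and to the startle surplus.
#' @slot turnSigmaDeg angular noise (sd, degrees) added to each step heading.
#' @slot seed RNG seed making the trajectory fully reproducible.
#'
#' @seealso \code{\link{behaviorParams}}, \code{\link{simulateTrajectory}}
#' @exportClass BehaviorParams
setClass("BehaviorParams", representation(
  baseSpeed = "numeric", sigmaSpeed = "numeric", pMove = "numeric",
  wallBias = "numeric", endBias = "numeric", omrGain = "numeric",
  startleGain = "numeric", habituationRate = "numeric",
  turnSigmaDeg = "numeric", seed = "integer"
))

setValidity("BehaviorParams", function(object) {
  msgs <- character()
  if (object@baseSpeed <= 0) msgs <- c(msgs, "baseSpeed must be positive")
  if (object@sigmaSpeed < 0) msgs <- c(msgs, "sigmaSpeed must be non-negative")
  if (object@pMove < 0 || object@pMove > 1) msgs <- c(msgs, "pMove must be in [0, 1]")
  if (object@wallBias < 0) msgs <- c(msgs, "wallBias must be >= 0")
  if (object@endBias < 0) msgs <- c(msgs, "endBias must be >= 0")
  if (object@startleGain < 0) msgs <- c(msgs, "startleGain must be >= 0")
  if (object@habituationRate <= 0 || object@habituationRate > 1)
    msgs <- c(msgs, "habituationRate must be in (0, 1]")
  if (object@turnSigmaDeg < 0) msgs <- c(msgs, "turnSigmaDeg must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

# ---- constructors ----------------------------------------------------------

#' Construct a tank ROI
#'
#' @param tankId integer tank identifier.
#' @param x0,y0 zero-based pixel offsets of the ROI's top-left corner.
#' @param width,height ROI size in pixels.
#' @param mmPerPx physical scale, mm per pixel (default 76/70).
#' @param endFraction end-zone fraction of tank width (default 0.20).
#' @return a \code{\link[=TankROI-class]{TankROI}} object.
#' @examples
#' tankROI(1, 0, 0, 320, 240)
#' @export
tankROI <- function(tankId, x0, y0, width, height,
                    mmPerPx = 76 / 70, endFraction = 0.20) {
  new("TankROI", tankId = as.integer(tankId),
      rect = as.numeric(c(x0, y0, width, height)),
      mmPerPx = as.numeric(mmPerPx), endFraction = as.numeric(endFraction))
}

#' Canonical eight-tank ROI layout
#'
#' The combined frame stacks two 640 x 480 camera fields vertically
#' (640 x 960 total); each field holds a 2 x 2 grid of tanks, giving eight
#' 320 x 240 ROIs numbered row-major from the top-left.
#'
#' @param frameWidth,frameHeight combined frame size in px.
#' @param mmPerPx,endFraction passed to \code{\link{tankROI}}.
#' @return a list of eight \code{TankROI} objects.
#' @examples
#' rois <- defaultTankROIs()
#' vapply(rois, tankId, integer(1))
#' @export
defaultTankROIs <- function(frameWidth = 640, frameHeight = 960,
                            mmPerPx = 76 / 70, endFraction = 0.20) {
  w <- frameWidth / 2
  h <- frameHeight / 4
  rois <- vector("list", 8)
  id <- 0L
  for (row in 0:3) {
    for (col in 0:1) {
      id <- id + 1L
      rois[[id]] <- tankROI(id, col * w, row * h, w, h,
                            mmPerPx = mmPerPx, endFraction = endFraction)
    }
  }
  rois
}

#' Construct detection settings
#'
#' @param thresholdMode \code{"otsu"} (per-ROI, per-frame) or \code{"fixed"}.
#' @param fixedThreshold threshold used in fixed mode (foreground strictly
#'   below it).
#' @param minArea,maxArea accepted particle area range, px^2.
#' @return a \code{\link[=DetectionConfig-class]{DetectionConfig}} object.
#' @examples
#' detectionConfig()
#' detectionConfig("fixed", fixedThreshold = 128)
#' @export
detectionConfig <- function(thresholdMode = c("otsu", "fixed"),
                            fixedThreshold = 128,
                            minArea = 50, maxArea = 2000) {
  new("DetectionConfig", thresholdMode = match.arg(thresholdMode),
      fixedThreshold = as.numeric(fixedThreshold),
      minArea = as.numeric(minArea), maxArea = as.numeric(maxArea))
}

#' Construct simulation parameters
#'
#' Defaults describe a moderately active adult zebrafish with thigmotaxis,
#' end-zone preference, a negative optomotor drift (it swims against the
#' lines), a startle surge at stimulus onset and partial habituation --
#' the qualitative regime observed in wild-type adults.
#'
#' @param baseSpeed,sigmaSpeed truncated-normal speed draw, cm/s.
#' @param pMove per-frame movement probability.
#' @param wallBias,endBias drift strengths toward the nearest long wall and
#'   nearest end.
#' @param omrGain signed optomotor drift strength.
#' @param startleGain movement-probability multiplier at stimulus onset.
#' @param habituationRate per-stimulus-period decay in (0, 1].
#' @param turnSigmaDeg angular step noise, degrees.
#' @param seed RNG seed.
#' @return a \code{\link[=BehaviorParams-class]{BehaviorParams}} object.
#' @examples
#' behaviorParams(omrGain = 0)       # unbiased fish
#' behaviorParams(omrGain = -2.5)    # strong negative optomotor drift
#' @export
behaviorParams <- function(baseSpeed = 3.0, sigmaSpeed = 1.0, pMove = 0.45,
                           wallBias = 0.5, endBias = 0.15, omrGain = -0.6,
                           startleGain = 2.0, habituationRate = 0.7,
                           turnSigmaDeg = 40, seed = 1L) {
  new("BehaviorParams", baseSpeed = as.numeric(baseSpeed),
      sigmaSpeed = as.numeric(sigmaSpeed), pMove = as.numeric(pMove),
      wallBias = as.numeric(wallBias), endBias = as.numeric(endBias),
      omrGain = as.numeric(omrGain), startleGain = as.numeric(startleGain),
      habituationRate = as.numeric(habituationRate),
      turnSigmaDeg = as.numeric(turnSigmaDeg), seed = as.integer(seed))
}

# ---- accessors -------------------------------------------------------------

#' Accessors for schedule and ROI objects
#'
#' \code{periods} returns the period table of a schedule; \code{nPeriods} its
#' row count; \code{tankId}, \code{roiRect}, \code{roiWidth},
#' \code{roiHeight}, \code{mmPerPx} and \code{endFraction} read the
#' corresponding \code{TankROI} geometry.
#'
#' @param x an \code{ExperimentSchedule} or \code{TankROI}.
#' @return the slot value (a data.frame, integer or numeric).
#' @name accessors
#' @aliases periods nPeriods tankId roiRect roiWidth roiHeight mmPerPx
#'   endFraction
#' @examples
#' sched <- defaultSchedule()
#' nPeriods(sched)
#' roiWidth(defaultTankROIs()[[1]])
NULL

#' @rdname accessors
#' @export
setGeneric("periods", function(x) standardGeneric("periods"))
#' @rdname accessors
#' @export
setMethod("periods", "ExperimentSchedule", function(x) x@periods)

#' @rdname accessors
#' @export
setGeneric("nPeriods", function(x) standardGeneric("nPeriods"))
#' @rdname accessors
#' @export
setMethod("nPeriods", "ExperimentSchedule", function(x) nrow(x@periods))

#' @rdname accessors
#' @export
setGeneric("tankId", function(x) standardGeneric("tankId"))
#' @rdname accessors
#' @export
setMethod("tankId", "TankROI", function(x) x@tankId)

#' @rdname accessors
#' @export
setGeneric("roiRect", function(x) standardGeneric("roiRect"))
#' @rdname accessors
#' @export
setMethod("roiRect", "TankROI", function(x) {
  r <- x@rect
  names(r) <- c("x0", "y0", "width", "height")
  r
})

#' @rdname accessors
#' @export
setGeneric("roiWidth", function(x) standardGeneric("roiWidth"))
#' @rdname accessors
#' @export
setMethod("roiWidth", "TankROI", function(x) x@rect[3])

#' @rdname accessors
#' @export
setGeneric("roiHeight", function(x) standardGeneric("roiHeight"))
#' @rdname accessors
#' @export
setMethod("roiHeight", "TankROI", function(x) x@rect[4])

#' @rdname accessors
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))
#' @rdname accessors
#' @export
setMethod("mmPerPx", "TankROI", function(x) x@mmPerPx)

#' @rdname accessors
#' @export
setGeneric("endFraction", function(x) standardGeneric("endFraction"))
#' @rdname accessors
#' @export
setMethod("endFraction", "TankROI", function(x) x@endFraction)

# ---- show methods ----------------------------------------------------------

setMethod("show", "ExperimentSchedule", function(object) {
  p <- object@periods
  cat(sprintf("ExperimentSchedule: %d periods of %g s (total %g s)\n",
              nrow(p), p$end_s[1] - p$start_s[1], p$end_s[nrow(p)]))
  nstim <- sum(p$kind == "moving_lines")
  cat(sprintf("  phases: %d baseline / %d stimulus (%d with moving lines) / %d post\n",
              sum(p$phase == "baseline"), sum(p$phase == "stimulus"),
              nstim, sum(p$phase == "post")))
  invisible(NULL)
})

setMethod("show", "TankROI", function(object) {
  r <- object@rect
  cat(sprintf("TankROI %d: %g x %g px at (%g, %g); %.4f mm/px; end zone %g%%\n",
              object@tankId, r[3], r[4], r[1], r[2],
              object@mmPerPx, 100 * object@endFraction))
  invisible(NULL)
})

setMethod("show", "DetectionConfig", function(object) {
  thr <- if (object@thresholdMode == "otsu") "Otsu (per ROI per frame)"
         else sprintf("fixed at %g", object@fixedThreshold)
  cat(sprintf("DetectionConfig: threshold %s; particle area %g-%g px^2\n",
              thr, object@minArea, object@maxArea))
  invisible(NULL)
})

setMethod("show", "BehaviorParams", function(object) {
  cat(sprintf(paste0(
    "BehaviorParams: speed %.2f +/- %.2f cm/s, pMove %.2f\n",
    "  wallBias %.2f, endBias %.2f, omrGain %+.2f\n",
    "  startleGain %.2f, habituationRate %.2f, turn sd %g deg, seed %d\n"),
    object@baseSpeed, object@sigmaSpeed, object@pMove, object@wallBias,
    object@endBias, object@omrGain, object@startleGain,
    object@habituationRate, object@turnSigmaDeg, object@seed))
  invisible(NULL)
})
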