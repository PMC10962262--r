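#' Extract the red channel of an RGB frame
#'
#' The moving-line stimuli are pure red on a light background, so they
#' saturate the red channel and vanish there, while the dark fish body keeps
#' its contrast. All downstream detection therefore operates on the red
#' channel only.
#'
#' @param frame numeric array \code{height x width x 3} with values in
#'   0..255, or an already-gray matrix (passed through with a warning).
#' @return a \code{height x width} numeric matrix.
#' @examples
#' f <- array(255, c(4, 4, 3)); f[2, 2, ] <- c(20, 20, 20)
#' extractRedChannel(f)[2, 2]
#' @export
extractRedChannel <- function(frame) {
  if (is.matrix(frame)) {
    warning("frame has a single channel; passing it through unchanged")
    return(frame)
  }
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    stop("frame must be a height x width x 3 array")
  frame[, , 1]
}

# Otsu threshold on 0..255 gray values: returns the cut value `thr` such that
# foreground = pixels strictly below thr. Maximizes between-class variance on
# a 256-bin histogram.
.otsuCut <- function(gray) {
  v <- pmin(pmax(floor(as.numeric(gray)), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mT <- m0[256]
  w1 <- n - w0
  # split after level k: class0 = [0..k], class1 = [k+1..255]
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (mT - m0) / w1, 0)
  bc <- w0 * w1 * (mu0 - mu1)^2
  bc[256] <- -Inf
  # histograms with an empty gap between classes maximize the criterion on a
  # plateau; take its midpoint (the conventional robust choice)
  k <- round(mean(which(bc >= max(bc) - 1e-9))) - 1L
  k + 1L  # foreground is strictly below this
}

# 8-connected component labeling restricted to foreground pixels.
# fg: logical matrix. Returns integer matrix of labels (0 = background).
.labelComponents8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (!length(idx)) return(lab)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  nextLab <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    nextLab <- nextLab + 1L
    lab[seed] <- nextLab
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      nbr <- rep(frontier, each = 8L) + rep(off, times = length(frontier))
      rOk <- rep(r, each = 8L) + rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L),
                                     times = length(frontier))
      keep <- nbr >= 1L & nbr <= nr * nc & rOk >= 1L & rOk <= nr
      nbr <- unique(nbr[keep])
      nbr <- nbr[fg[nbr] & lab[nbr] == 0L]
      lab[nbr] <- nextLab
      frontier <- nbr
    }
  }
  lab
}

# Moment statistics for labeled foreground pixels. Coordinates are zero-based
# pixel indices (x = column - 1 rightward, y = row - 1 downward); centroids
# are plain means of pixel indices. Ellipse axes are full lengths from the
# eigenvalues of the second central moments (4 * sqrt(lambda), exact for a
# solid continuous ellipse), floored at the single-pixel spread 1/12 so
# degenerate particles keep major >= minor > 0.
.particleStats <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(.emptyParticles())
  nr <- nrow(lab)
  g <- lab[idx]
  x <- (idx - 1L) %/% nr     # zero-based column
  y <- (idx - 1L) %% nr      # zero-based row
  area <- tabulate(g)
  sx <- rowsum(x, g); sy <- rowsum(y, g)
  sxx <- rowsum(x * x, g); syy <- rowsum(y * y, g); sxy <- rowsum(x * y, g)
  cx <- as.numeric(sx) / area
  cy <- as.numeric(sy) / area
  mxx <- as.numeric(sxx) / area - cx^2
  myy <- as.numeric(syy) / area - cy^2
  mxy <- as.numeric(sxy) / area - cx * cy
  tr <- mxx + myy
  dif <- mxx - myy
  disc <- sqrt(pmax(dif^2 + 4 * mxy^2, 0))
  l1 <- pmax((tr + disc) / 2, 1 / 12)
  l2 <- pmax((tr - disc) / 2, 1 / 12)
  ang <- (atan2(2 * mxy, dif) / 2) * 180 / pi
  ang <- ang %% 180
  xmin <- tapply(x, g, min); xmax <- tapply(x, g, max)
  ymin <- tapply(y, g, min); ymax <- tapply(y, g, max)
  data.frame(
    area = area, cx = cx, cy = cy,
    bbox_x = as.numeric(xmin), bbox_y = as.numeric(ymin),
    bbox_w = as.numeric(xmax - xmin + 1), bbox_h = as.numeric(ymax - ymin + 1),
    major = 4 * sqrt(l1), minor = 4 * sqrt(l2), angle_deg = ang
  )
}

.emptyParticles <- function() {
  data.frame(area = numeric(0), cx = numeric(0), cy = numeric(0),
             bbox_x = numeric(0), bbox_y = numeric(0),
             bbox_w = numeric(0), bbox_h = numeric(0),
             major = numeric(0), minor = numeric(0), angle_deg = numeric(0))
}

#' Thresholded particle analysis of one gray ROI
#'
#' Foreground is the set of pixels strictly below the threshold (dark fish
#' on a light background); particles are its 8-connected components, kept
#' only if their area lies within \code{[minArea, maxArea]}. Each particle
#' carries its pixel count, centroid (arithmetic mean of zero-based pixel
#' coordinates), tight axis-aligned bounding box, and the best-fitting
#' ellipse derived from second central moments (full major/minor axis
#' lengths and orientation in degrees, \code{[0, 180)}, measured from +x
#' with y pointing down).
#'
#' @param grayRoi numeric matrix of gray values in 0..255.
#' @param cfg a \code{\link{detectionConfig}}.
#' @return data.frame with columns \code{area}, \code{cx}, \code{cy},
#'   \code{bbox_x}, \code{bbox_y}, \code{bbox_w}, \code{bbox_h},
#'   \code{major}, \code{minor}, \code{angle_deg}; zero rows if nothing
#'   passes the filter.
#' @examples
#' roi <- matrix(230, 40, 60)
#' roi[10:20, 10:30] <- 30
#' segmentParticles(roi, detectionConfig())
#' @export
segmentParticles <- function(grayRoi, cfg = detectionConfig()) {
  if (!is.matrix(grayRoi) || length(grayRoi) == 0)
    stop("grayRoi must be a non-empty matrix")
  thr <- if (cfg@thresholdMode == "fixed") cfg@fixedThreshold
         else .otsuCut(grayRoi)
  fg <- grayRoi < thr
  if (!any(fg)) return(.emptyParticles())
  parts <- .particleStats(.labelComponents8(fg))
  parts[parts$area >= cfg@minArea & parts$area <= cfg@maxArea, , drop = FALSE]
}

#' Pick the fish among surviving particles
#'
#' One fish per tank by design: the largest-area particle wins; ties break
#' toward the smaller centroid y, then smaller centroid x.
#'
#' @param particles data.frame as returned by \code{\link{segmentParticles}}.
#' @return a one-row data.frame, or \code{NULL} when no particle survives
#'   (a missing detection).
#' @export
selectFish <- function(particles) {
  if (is.null(particles) || nrow(particles) == 0) return(NULL)
  o <- order(-particles$area, particles$cy, particles$cx)
  particles[o[1], , drop = FALSE]
}

# ---- frame sources ---------------------------------------------------------

#' Frame sources: uniform access to movie frames
#'
#' \code{frameSource} wraps the supported frame containers into a pair
#' \code{list(get = function(i), n)} where \code{get(i)} returns the 0-based
#' frame \code{i} as a \code{height x width x 3} array in 0..255:
#' \itemize{
#'   \item a list of arrays (in-memory movie);
#'   \item a directory of numbered \code{.png} / \code{.tif(f)} files, read
#'     in sorted name order;
#'   \item a function \code{function(i)} plus an explicit \code{nFrames}.
#' }
#'
#' @param x list of frames, directory path, or frame-generating function.
#' @param nFrames number of frames (required for a function source).
#' @return a list with elements \code{get} and \code{n}.
#' @export
frameSource <- function(x, nFrames = NULL) {
  if (is.list(x) && !is.function(x)) {
    return(list(get = function(i) x[[i + 1L]], n = length(x)))
  }
  if (is.character(x) && length(x) == 1) {
    if (!dir.exists(x)) stop("frame directory not found: ", x)
    files <- sort(list.files(x, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", x)
    return(list(get = function(i) readFrame(files[i + 1L]), n = length(files)))
  }
  if (is.function(x)) {
    if (is.null(nFrames)) stop("nFrames is required for a function frame source")
    return(list(get = x, n = as.integer(nFrames)))
  }
  stop("unsupported frame container")
}

#' Read one PNG or TIFF frame as a 0..255 RGB array
#'
#' @param path image file path.
#' @return numeric array \code{height x width x 3}, values in 0..255.
#' @export
readFrame <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  img * 255
}

#' Detect one fish per tank in every frame
#'
#' Runs red-channel extraction, per-ROI thresholded particle analysis and
#' largest-particle selection over all frames, producing exactly one
#' detection row per (frame, tank) in that order. Coordinates are tank-local
#' (ROI origin at its top-left corner). A frame that cannot be read yields
#' \code{missing} rows for all tanks and processing continues.
#'
#' @param frames a frame container accepted by \code{\link{frameSource}}.
#' @param rois list of \code{\link{tankROI}} objects.
#' @param cfg a \code{\link{detectionConfig}}.
#' @param intervalS seconds between frames (default 1, the canonical
#'   snapshot interval).
#' @param nFrames frame count, for function sources.
#' @return the detections table: a data.frame with columns \code{frame}
#'   (0-based), \code{time_s}, \code{tank}, \code{status}
#'   (\code{"found"}/\code{"missing"}), \code{cx}, \code{cy}, \code{bbox_x},
#'   \code{bbox_y}, \code{bbox_w}, \code{bbox_h}, \code{major}, \code{minor},
#'   \code{angle_deg}, \code{area}.
#' @export
analyzeMovie <- function(frames, rois, cfg = detectionConfig(),
                         intervalS = 1, nFrames = NULL) {
  src <- frameSource(frames, nFrames)
  if (src$n < 1) stop("need at least one frame")
  if (!length(rois)) stop("need at least one tank ROI")
  nT <- length(rois)
  nRow <- src$n * nT
  out <- data.frame(
    frame = rep(0:(src$n - 1L), each = nT),
    time_s = rep((0:(src$n - 1L)) * intervalS, each = nT),
    tank = rep(vapply(rois, tankId, integer(1)), times = src$n),
    status = rep("missing", nRow),
    cx = NA_real_, cy = NA_real_, bbox_x = NA_real_, bbox_y = NA_real_,
    bbox_w = NA_real_, bbox_h = NA_real_, major = NA_real_, minor = NA_real_,
    angle_deg = NA_real_, area = NA_real_,
    stringsAsFactors = FALSE
  )
  geomCols <- c("cx", "cy", "bbox_x", "bbox_y", "bbox_w", "bbox_h",
                "major", "minor", "angle_deg", "area")
  for (i in 0:(src$n - 1L)) {
    frame <- tryCatch(src$get(i), error = function(e) {
      warning(sprintf("frame %d unreadable (%s); marked missing",
                      i, conditionMessage(e)))
      NULL
    })
    if (is.null(frame)) next
    red <- if (is.matrix(frame)) frame else frame[, , 1]
    for (k in seq_len(nT)) {
      r <- rois[[k]]@rect
      sub <- red[(r[2] + 1):(r[2] + r[4]), (r[1] + 1):(r[1] + r[3]), drop = FALSE]
      fish <- selectFish(segmentParticles(sub, cfg))
      if (is.null(fish)) next
      row <- i * nT + k
      out$status[row] <- "found"
      out[row, geomCols] <- fish[, c("cx", "cy", "bbox_x", "bbox_y", "bbox_w",
                                     "bbox_h", "major", "minor", "angle_deg",
                                     "area")]
    }
  }
  out
}
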