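# Shared fixtures, built in code.

# Rasterize a solid ellipse into a light-background gray matrix using its
# own geometry (independent of the package's renderer): pixel (x, y) is
# foreground iff it lies inside the ellipse of semi-axes (a, b) rotated by
# angleDeg about (cx, cy). Coordinates are zero-based indices, y down.
rasterEllipse <- function(nrow, ncol, cx, cy, a, b, angleDeg,
                          bg = 230, fg = 30) {
  m <- matrix(bg, nrow, ncol)
  th <- angleDeg * pi / 180
  xs <- 0:(ncol - 1); ys <- 0:(nrow - 1)
  dx <- outer(rep(1, nrow), xs - cx)
  dy <- outer(ys - cy, rep(1, ncol))
  s <- dx * cos(th) + dy * sin(th)
  t_ <- -dx * sin(th) + dy * cos(th)
  m[(s / a)^2 + (t_ / b)^2 <= 1] <- fg
  m
}

# A minimal one-row "found" detection with explicit geometry.
makeDetection <- function(cx, cy, bboxCx, bboxCy, angleDeg,
                          bboxW = 28, bboxH = 8, major = 28, minor = 8) {
  data.frame(frame = 0, time_s = 0, tank = 1L, status = "found",
             cx = cx, cy = cy,
             bbox_x = bboxCx - (bboxW - 1) / 2,
             bbox_y = bboxCy - (bboxH - 1) / 2,
             bbox_w = bboxW, bbox_h = bboxH,
             major = major, minor = minor, angle_deg = angleDeg,
             area = pi * major * minor / 4, stringsAsFactors = FALSE)
}

# Detections table for a single tank from explicit positions; frame i is
# missing where x is NA.
makeTrackDetections <- function(x, y, tank = 1L, intervalS = 1) {
  n <- length(x)
  data.frame(
    frame = 0:(n - 1), time_s = (0:(n - 1)) * intervalS, tank = tank,
    status = ifelse(is.na(x), "missing", "found"),
    cx = x, cy = y,
    bbox_x = x - 13.5, bbox_y = y - 3.5, bbox_w = 28, bbox_h = 8,
    major = 28, minor = 8, angle_deg = 0, area = 176,
    stringsAsFactors = FALSE
  )
}

smallROI <- function() tankROI(1, 0, 0, 320, 240)
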