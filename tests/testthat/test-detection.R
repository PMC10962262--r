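test_that("red-channel extraction keeps fish contrast and hides red stimuli", {
  f <- array(255, c(4, 6, 3))
  f[2, 2, ] <- c(20, 20, 20)        # dark fish pixel
  f[, 5, ] <- rep(c(255, 0, 0), each = 4)  # pure-red stimulus column
  red <- extractRedChannel(f)
  expect_equal(dim(red), c(4, 6))
  expect_equal(red[2, 2], 20)
  expect_equal(red[1, 1], 255)
  expect_equal(red[, 5], rep(255, 4))      # stripe invisible on white
  expect_warning(extractRedChannel(matrix(0, 2, 2)), "single channel")
  expect_error(extractRedChannel(array(0, c(2, 2, 2))), "3 array")
})

test_that("adding a pure-red pattern to a white frame is pixel-exact invisible", {
  base <- array(255, c(30, 40, 3))
  base[10:14, 10:20, ] <- 25
  withRed <- base
  withRed[, seq(1, 40, by = 4), 2] <- 0
  withRed[, seq(1, 40, by = 4), 3] <- 0
  expect_identical(extractRedChannel(withRed), extractRedChannel(base))
  cfg <- detectionConfig()
  expect_equal(segmentParticles(extractRedChannel(withRed), cfg),
               segmentParticles(extractRedChannel(base), cfg))
})

test_that("particle analysis recovers rendered ellipse geometry", {
  cfg <- detectionConfig()
  expect_equal(nrow(segmentParticles(matrix(255, 40, 40), cfg)), 0)
  for (ang in c(0, 20, 45, 77, 120, 160)) {
    m <- rasterEllipse(120, 160, cx = 80.4, cy = 60.2, a = 14, b = 4,
                       angleDeg = ang)
    p <- segmentParticles(m, cfg)
    expect_equal(nrow(p), 1)
    expect_lt(sqrt((p$cx - 80.4)^2 + (p$cy - 60.2)^2), 0.5)
    d <- abs(p$angle_deg - ang %% 180)
    expect_lt(min(d, 180 - d), 2)
    # moment ellipse area is consistent with the pixel count
    expect_lt(abs(pi * p$major * p$minor / 4 - p$area) / p$area, 0.15)
    expect_gte(p$major, p$minor)
    # aspect ratio of the same shape is rotation-stable within 5%
    if (ang == 0) ar0 <- p$major / p$minor
    expect_lt(abs(p$major / p$minor - ar0) / ar0, 0.05)
  }
})

test_that("the size filter drops specks and keeps the fish", {
  m <- rasterEllipse(120, 160, 80, 60, 14, 5, 30)
  m[5, 5:9] <- 10   # 5-px speck
  p <- segmentParticles(m, detectionConfig())
  expect_equal(nrow(p), 1)
  expect_gt(p$area, 100)
  # with a permissive lower bound both survive
  p2 <- segmentParticles(m, detectionConfig(minArea = 2, maxArea = 2000))
  expect_equal(nrow(p2), 2)
})

test_that("8-connectivity joins diagonally touching pixels", {
  m <- matrix(255, 10, 10)
  m[cbind(2:5, 2:5)] <- 10   # diagonal chain
  p <- segmentParticles(m, detectionConfig(minArea = 1, maxArea = 100))
  expect_equal(nrow(p), 1)
  expect_equal(p$area, 4)
})

test_that("thresholding agrees with an independent image-analysis oracle", {
  set.seed(42)
  m <- rasterEllipse(80, 120, 60.5, 40.5, 12, 5, 35)
  m <- m + matrix(rnorm(length(m), 0, 4), nrow(m))
  m <- pmin(pmax(m, 0), 255)
  ours <- zebrafishOMR:::.otsuCut(m)
  ref <- EBImage::otsu(EBImage::Image(t(m) / 255), range = c(0, 1)) * 255
  # both thresholds must induce the same foreground segmentation
  expect_identical(m < ours, m < ref)
  # same solid blob -> same component count and area
  fg <- m < ours
  lab <- EBImage::bwlabel(EBImage::Image(t(fg)))
  p <- segmentParticles(m, detectionConfig(minArea = 1, maxArea = 1e5))
  expect_equal(nrow(p), max(lab))
  expect_equal(sort(p$area), sort(as.numeric(table(lab[lab > 0]))))
})

test_that("selectFish keeps the largest particle with deterministic ties", {
  expect_null(selectFish(NULL))
  expect_null(selectFish(data.frame(area = numeric(0), cx = numeric(0),
                                    cy = numeric(0))))
  p <- data.frame(area = c(120, 300), cx = c(5, 50), cy = c(5, 50))
  expect_equal(selectFish(p)$area, 300)
  tie <- data.frame(area = c(100, 100, 100), cx = c(9, 3, 5), cy = c(4, 4, 2))
  expect_equal(unlist(selectFish(tie)[c("cy", "cx")], use.names = FALSE), c(2, 5))
})

test_that("analyzeMovie yields one row per frame and tank, missing allowed", {
  rois <- list(tankROI(1, 0, 0, 40, 30), tankROI(2, 40, 0, 40, 30))
  blank <- array(255, c(30, 80, 3))
  det <- analyzeMovie(rep(list(blank), 10), rois)
  expect_equal(nrow(det), 20)
  expect_true(all(det$status == "missing"))
  expect_equal(det$frame, rep(0:9, each = 2))
  # one fish drawn in tank 2 only
  f <- blank
  f[10:16, 50:70, ] <- 20
  det2 <- analyzeMovie(list(f), rois)
  expect_equal(det2$status, c("missing", "found"))
  # tank-local coordinates: ROI origin subtracted (zero-based indices)
  expect_equal(det2$cx[2], 59 - 40, tolerance = 1e-9)
  expect_equal(det2$cy[2], 12, tolerance = 1e-9)
})

test_that("unreadable frames are logged and skipped, not fatal", {
  rois <- list(tankROI(1, 0, 0, 40, 30))
  src <- function(i) {
    if (i == 1) stop("corrupt frame")
    arr <- array(255, c(30, 40, 3)); arr[10:16, 10:26, ] <- 20; arr
  }
  expect_warning(det <- analyzeMovie(src, rois, nFrames = 3), "unreadable")
  expect_equal(det$status, c("found", "missing", "found"))
})

test_that("frame files round-trip through PNG", {
  dir <- withr::local_tempdir()
  arr <- array(230 / 255, c(30, 40, 3))
  arr[5:10, 5:20, ] <- 20 / 255
  png::writePNG(arr, file.path(dir, "frame_000.png"))
  png::writePNG(arr, file.path(dir, "frame_001.png"))
  src <- frameSource(dir)
  expect_equal(src$n, 2)
  f <- src$get(0)
  expect_equal(dim(f), c(30, 40, 3))
  expect_equal(f[1, 1, 1], 230, tolerance = 0.5)
  det <- analyzeMovie(dir, list(tankROI(1, 0, 0, 40, 30)))
  expect_equal(det$status, rep("found", 2))
})
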