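test_that("simulation is deterministic given the seed", {
  roi <- smallROI()
  sched <- defaultSchedule(periodS = 20)
  a <- simulateTrajectory(behaviorParams(seed = 99), sched, roi)
  b <- simulateTrajectory(behaviorParams(seed = 99), sched, roi)
  expect_identical(a, b)
  c_ <- simulateTrajectory(behaviorParams(seed = 100), sched, roi)
  expect_false(identical(a$x, c_$x))
  src1 <- renderFrames(list(a), list(roi), sched)
  src2 <- renderFrames(list(b), list(roi), sched)
  expect_identical(src1$get(5), src2$get(5))
})

test_that("a fish with pMove = 0 never moves", {
  roi <- smallROI()
  sched <- defaultSchedule(periodS = 20)
  tr <- simulateTrajectory(behaviorParams(pMove = 0, seed = 1), sched, roi)
  expect_equal(length(unique(tr$x)), 1)
  expect_equal(length(unique(tr$y)), 1)
  expect_equal(tr$speed_cm_s[-1], rep(0, nrow(tr) - 1))
  expect_false(any(tr$moving[-1]))
})

test_that("an unbiased walk spends about half its time on the right", {
  roi <- smallROI()
  sched <- defaultSchedule()   # full 10,800 frames
  tr <- simulateTrajectory(
    behaviorParams(omrGain = 0, endBias = 0, wallBias = 0, seed = 11),
    sched, roi)
  expect_lt(abs(100 * mean(tr$in_right_half) - 50), 5)
})

test_that("strong negative optomotor drift produces the location switch", {
  roi <- smallROI()
  sched <- defaultSchedule()
  tr <- simulateTrajectory(behaviorParams(omrGain = -2.5, seed = 3), sched, roi)
  s <- summarizePeriods(expectedFlags(tr, roi), sched)
  expect_gt(s$pct_right[s$period == 7], 70)   # leftward lines: fish right
  expect_lt(s$pct_right[s$period == 8], 30)   # rightward lines: fish left
})

test_that("trajectories stay inside the tank and flags match positions", {
  roi <- smallROI()
  sched <- defaultSchedule(periodS = 40)
  tr <- simulateTrajectory(behaviorParams(seed = 17), sched, roi)
  expect_true(all(tr$x >= 0 & tr$x < roiWidth(roi)))
  expect_true(all(tr$y >= 0 & tr$y < roiHeight(roi)))
  zf <- zoneFlags(tr$x, roi)
  expect_equal(tr$in_end, zf$in_end)
  expect_equal(tr$in_right_half, zf$in_right_half)
  ef <- expectedFlags(tr, roi)
  expect_equal(tr$speed_cm_s, ef$speed_cm_s)
  # mirrored track: orientation flags negate
  trM <- tr
  trM$x <- roiWidth(roi) - tr$x
  trM$heading_deg <- (180 - tr$heading_deg) %% 360
  efM <- expectedFlags(trM, roi)
  expect_equal(efM$in_right_half, !ef$in_right_half)
  expect_equal(efM$oriented_right, !ef$oriented_right)
  expect_equal(efM$rfc_cw, !ef$rfc_cw)
})

test_that("rendered frames carry red stripes only during line periods", {
  rois <- defaultTankROIs()
  sched <- defaultSchedule(periodS = 20)
  tracks <- lapply(rois, function(r)
    simulateTrajectory(behaviorParams(seed = tankId(r)), sched, r))
  src <- renderFrames(tracks, rois, sched)
  blank <- src$get(10)           # period 1
  expect_false(any(blank[, , 1] == 255 & blank[, , 2] == 0))
  # exactly 8 dark blobs
  det <- analyzeMovie(list(blank), rois)
  expect_equal(sum(det$status == "found"), 8)
  lines <- src$get(7 * 20 - 10)  # inside period 7
  red <- extractRedChannel(lines)
  expect_true(any(lines[, , 1] == 255 & lines[, , 2] == 0))
  # stripes are brighter than background in the red channel, never darker
  # than the fish
  expect_true(all(red[lines[, , 1] == 255 & lines[, , 2] == 0] == 255))
  expect_gt(min(red[red != 30]), 200)
})

test_that("detection recovers rendered ground truth to sub-pixel accuracy", {
  rois <- defaultTankROIs()[1:2]
  sched <- defaultSchedule(periodS = 20)
  tracks <- lapply(seq_along(rois), function(i)
    simulateTrajectory(behaviorParams(seed = 40 + i), sched, rois[[i]]))
  sub <- lapply(tracks, function(t) t[120:160, ])   # spans the p6 -> p7 onset
  src <- renderFrames(sub, rois, sched)
  det <- analyzeMovie(src$get, rois, nFrames = src$n)
  expect_true(all(det$status == "found"))
  for (i in seq_along(rois)) {
    d <- det[det$tank == i, ]
    expect_lt(sqrt(mean((d$cx - sub[[i]]$x)^2 + (d$cy - sub[[i]]$y)^2)), 1)
    angErr <- abs(d$angle_deg - sub[[i]]$heading_deg %% 180)
    expect_lt(max(pmin(angErr, 180 - angErr)), 2)
  }
})

test_that("profiles from rendered frames match ground-truth profiles closely", {
  rois <- defaultTankROIs()[1:2]
  sched <- defaultSchedule(periodS = 60)   # 1080-frame compressed trial
  tracks <- lapply(seq_along(rois), function(i)
    simulateTrajectory(behaviorParams(seed = 60 + i), sched, rois[[i]]))
  src <- renderFrames(tracks, rois, sched)
  det <- analyzeMovie(src$get, rois, nFrames = src$n)
  profPipe <- buildProfiles(summarizePeriods(
    metricsSeries(det, rois), sched))
  profTruth <- buildProfiles(do.call(rbind, lapply(seq_along(rois), function(i)
    summarizePeriods(expectedFlags(tracks[[i]], rois[[i]]), sched))))
  for (m in profileMeasureNames()) {
    expect_lt(max(abs(profPipe[[m]] - profTruth[[m]])), 2)
  }
})

test_that("cohorts give one track per tank and a well-formed detection table", {
  rois <- defaultTankROIs()
  sched <- defaultSchedule(periodS = 10)
  tracks <- simulateCohort(behaviorParams(seed = 5), rois, sched)
  expect_length(tracks, 8)
  expect_equal(vapply(tracks, function(t) t$tank[1], numeric(1)), 1:8)
  # distinct seeds produce distinct walks
  expect_false(identical(tracks[[1]]$x, tracks[[2]]$x))
  det <- cohortDetections(tracks, rois)
  expect_equal(nrow(det), 8 * 180)
  expect_equal(det$tank[1:8], 1:8)
  expect_true(!is.unsorted(det$frame))
})
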