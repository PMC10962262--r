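test_that("period summaries are exact fractions over defined frames", {
  roi <- smallROI()
  sched <- defaultSchedule(periodS = 10)   # 18 periods of 10 frames
  # constructed fish: always in the right half, half the frames in an end zone
  x <- rep(c(300, 170), length.out = 180)
  det <- makeTrackDetections(x, rep(120, 180))
  m <- metricsSeries(det, list(roi))
  s <- summarizePeriods(m, sched)
  expect_equal(nrow(s), 18)
  expect_equal(s$pct_right, rep(100, 18))
  expect_equal(s$pct_end, rep(50, 18))
  expect_equal(s$n_frames, rep(10, 18))
  # first period loses one speed denominator to the trial start
  expect_equal(s$n_valid_speed, c(9, rep(10, 17)))
  # summaries of a simulated track equal the generator's own bookkeeping
  tr <- simulateTrajectory(behaviorParams(seed = 4), sched, roi)
  s2 <- summarizePeriods(expectedFlags(tr, roi), sched)
  per <- tr$period
  expect_equal(s2$pct_right,
               as.numeric(100 * tapply(tr$in_right_half, per, mean)))
  expect_equal(s2$pct_move, as.numeric(
    tapply(tr$moving, per, function(v) 100 * mean(v, na.rm = TRUE))))
  expect_error(summarizePeriods(transform(m, time_s = time_s + 1e5), sched),
               "time_s")
})

test_that("empty denominators yield NA rather than zero percentages", {
  roi <- smallROI()
  sched <- defaultSchedule(periodS = 10)
  x <- rep(100, 180); x[1:10] <- NA   # period 1 entirely missing
  m <- metricsSeries(makeTrackDetections(x, rep(50, 180)), list(roi))
  s <- summarizePeriods(m, sched)
  expect_true(is.na(s$pct_right[s$period == 1]))
  expect_true(is.na(s$mean_speed_cm_s[s$period == 1]))
  expect_equal(s$pct_right[s$period == 2], 0)
})

test_that("delta takes means over period sets with the stated sign", {
  s <- data.frame(fish = 1, period = 1:18,
                  pct_move = c(50, 50, 50, 46, 46, 46, 72, rep(40, 11)))
  s$pct_move[6] <- 40
  expect_equal(delta(s, "pct_move", 6, 7), 40 - 72)
  expect_equal(delta(s, "pct_move", 1:3, 4:6), 50 - mean(c(46, 46, 40)))
  expect_equal(delta(s, "pct_move", 7, 7), 0)
  s$pct_move[9] <- NA
  expect_true(is.na(delta(s, "pct_move", 7, 9)))
})

test_that("buildProfile assembles the 24 measures with the field conventions", {
  base <- data.frame(fish = 1L, period = 1:18, pct_move = 50, pct_end = 60,
                     pct_right = 50, pct_oriented_right = 50, pct_cw = 52,
                     mean_speed_cm_s = 3, n_frames = 600,
                     n_valid_speed = 600, n_valid_orient = 600)
  p <- buildProfile(base)
  expect_equal(names(p), c("fish", profileMeasureNames()))
  # identical periods: all 13 contrast measures are 0
  contrasts <- c("M_Accl", "M_St", "M_Hab_7_9", "M_Hab_9_11", "E_Accl",
                 "E_St", "E_Hab_7_9", "E_Hab_9_11", "OMRL_7_8", "OMRL_9_10",
                 "OMRL_11_12", "OMRLHab_7_9", "OMRLHab_9_11")
  expect_equal(unlist(p[contrasts], use.names = FALSE), rep(0, 13))
  expect_equal(p$Speed_p1_6, 3)
  expect_equal(p$CW_p1_6, 52)
  # a strong negative optomotor fish: 85% right under leftward lines,
  # 15% under rightward lines
  s <- base
  s$pct_right[s$period == 7] <- 85
  s$pct_right[s$period == 8] <- 15
  s$pct_right[s$period == 9] <- 58
  p2 <- buildProfile(s)
  expect_equal(p2$OMRL_7_8, 15 - 85)
  expect_equal(p2$OMRLHab_7_9, 85 - 58)
  # startle: activity jumping from 40 (p6) to 72 (p7) scores -32
  s2 <- base
  s2$pct_move[s2$period == 6] <- 40
  s2$pct_move[s2$period == 7] <- 72
  expect_equal(buildProfile(s2)$M_St, -32)
  expect_error(buildProfile(base[-7, ]), "missing")
})

test_that("group summary reproduces printed Table 1 speed statistics", {
  speeds <- c(3.327608132, 2.830924367, 2.48269152, 2.207779949, 3.08552068,
              2.81435937, 1.437875412, 2.577432247, 2.440140508, 2.625247097,
              2.892485765, 3.295731215, 3.854794279, 3.569697566, 5.812450811,
              3.4106223)
  profs <- as.data.frame(setNames(
    lapply(profileMeasureNames(), function(m) if (m == "Speed_p1_6") speeds else 0),
    profileMeasureNames()))
  g <- groupSummary(profs)
  expect_equal(g$avg[g$measure == "Speed_p1_6"], 3.041585076, tolerance = 1e-9)
  expect_equal(g$sem[g$measure == "Speed_p1_6"], 0.23585532, tolerance = 1e-7)
  expect_equal(unique(g$n), 16)
  # k identical profiles reconstruct the profile with zero SEM
  same <- profs[rep(1, 5), ]
  g2 <- groupSummary(same)
  expect_equal(g2$avg, unlist(profs[1, profileMeasureNames()],
                              use.names = FALSE))
  expect_equal(g2$sem, rep(0, 24))
  expect_warning(groupSummary(profs[1, , drop = FALSE]), "SEM")
})

test_that("profile measures obey mirror anti-symmetry", {
  roi <- smallROI()
  sched <- defaultSchedule(periodS = 50)
  tr <- simulateTrajectory(behaviorParams(seed = 31), sched, roi)
  det <- trackDetections(tr, roi)
  p <- buildProfile(summarizePeriods(metricsSeries(det, list(roi)), sched))
  pm <- buildProfile(summarizePeriods(
    metricsSeries(mirrorDetections(det, roi), list(roi)), sched))
  omr <- grep("^OMR", profileMeasureNames(), value = TRUE)
  for (m in omr) expect_equal(pm[[m]], -p[[m]], tolerance = 1e-9, label = m)
  keep <- c("Speed_p1_6", "M_1h", "M_Accl", "M_Vis", "M_St", "M_Hab_7_9",
            "M_Hab_9_11", "E_1h", "E_Accl", "E_Vis", "E_St", "E_Hab_7_9",
            "E_Hab_9_11")
  for (m in keep) expect_equal(pm[[m]], p[[m]], tolerance = 1e-9, label = m)
  expect_equal(pm$CW_p1_6, 100 - p$CW_p1_6, tolerance = 1e-9)
})

test_that("hexbin conserves counts and respects the lattice", {
  h1 <- hexbin(rep(12.3, 100), rep(45.6, 100), circumradius = 10)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 100)
  set.seed(8)
  x <- runif(500, 0, 300); y <- runif(500, 0, 200)
  h <- hexbin(x, y, circumradius = 12)
  expect_equal(sum(h$count), 500)
  expect_true(all(h$count > 0))
  # every point is within the circumradius of its assigned hexagon center
  hAll <- hexbin(x, y, circumradius = 12)
  expect_true(all(vapply(seq_along(x), function(i) {
    min(sqrt((hAll$hex_cx - x[i])^2 + (hAll$hex_cy - y[i])^2)) <= 12 + 1e-9
  }, logical(1))))
  # a radius dwarfing the extent collects everything into one hexagon
  g <- expand.grid(x = seq(0, 10, 2), y = seq(0, 10, 2))
  hBig <- hexbin(g$x, g$y, circumradius = 1000)
  expect_equal(nrow(hBig), 1)
  expect_equal(hBig$count, nrow(g))
  expect_equal(nrow(hexbin(numeric(0), numeric(0))), 0)
  expect_error(hexbin(1, 1, circumradius = 0))
})
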