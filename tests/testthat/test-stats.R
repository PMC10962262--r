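test_that("Friedman statistic matches the classical rank-sum formula", {
  # three subjects ranking three conditions identically
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(10, 20, 30))
  # independent oracle: untied classical formula computed from scratch
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  chi <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  expect_equal(chi, 6.0)
  res <- friedmanTest(m)
  expect_equal(unname(res$statistic), 6.0)
  expect_equal(unname(res$parameter), 2)
  expect_equal(res$p.value, pchisq(6, 2, lower.tail = FALSE))
  # fully tied table degenerates to 0 / p = 1
  flat <- matrix(5, 4, 3)
  expect_equal(unname(friedmanTest(flat)$statistic), 0)
  expect_equal(friedmanTest(flat)$p.value, 1)
  expect_error(friedmanTest(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("Friedman agrees with the base-R implementation and is rank-invariant", {
  set.seed(14)
  m <- matrix(rnorm(16 * 4), 16, 4)
  ours <- friedmanTest(m)
  ref <- stats::friedman.test(m)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value)
  # invariant under any strictly monotone transform
  expect_equal(unname(friedmanTest(exp(m))$statistic),
               unname(ours$statistic))
  expect_equal(unname(friedmanTest(m^3)$statistic), unname(ours$statistic))
})

test_that("Wilcoxon signed-rank matches sign-flip enumeration at tiny n", {
  # oracle: enumerate all 2^3 sign assignments of |d| = (1, 2, 3)
  ranks <- 1:3
  wdist <- apply(expand.grid(c(0, 1), c(0, 1), c(0, 1)), 1,
                 function(s) sum(ranks[s == 1]))
  expect_equal(mean(wdist <= 0), 1 / 8)   # one-sided exact p at W = 0
  res <- wilcoxonSignedRank(c(3, 5, 8), c(2, 3, 5))   # d = +1, +2, +3
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 2 / 8)
  # degenerate: no nonzero differences
  same <- wilcoxonSignedRank(1:4, 1:4)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_match(same$note, "degenerate")
  # negating differences swaps W+ and W- but not the two-sided p
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12)
  a <- wilcoxonSignedRank(x, y); b <- wilcoxonSignedRank(y, x)
  expect_equal(unname(a$statistic), unname(b$statistic))
  expect_equal(a$p.value, b$p.value)
})

test_that("Wilcoxon p-values agree with the base-R implementation", {
  set.seed(6)
  x <- rnorm(15); y <- rnorm(15)
  ours <- wilcoxonSignedRank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p.value, ref$p.value)
  # approximate path with ties
  xt <- round(rnorm(40), 0); yt <- round(rnorm(40), 0)
  keep <- xt != yt
  ours2 <- wilcoxonSignedRank(xt[keep], yt[keep])
  ref2 <- stats::wilcox.test(xt[keep], yt[keep], paired = TRUE,
                             exact = FALSE, correct = TRUE)
  expect_equal(ours2$p.value, ref2$p.value, tolerance = 1e-9)
})

test_that("repeated-measures ANOVA decomposes within-subject variance", {
  # equal condition means with within-subject variation: F = 0
  m <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)) + c(10, 20, 30)
  expect_equal(unname(rmAnova(m)$statistic), 0)
  # two conditions: F equals the squared paired t statistic
  set.seed(10)
  m2 <- matrix(rnorm(20), 10, 2)
  f <- rmAnova(m2)
  tt <- t.test(m2[, 1], m2[, 2], paired = TRUE)
  expect_equal(unname(f$statistic), unname(tt$statistic)^2)
  expect_equal(f$p.value, tt$p.value)
  # adding a constant to one subject's row only moves SS_subjects
  m3 <- matrix(rnorm(24), 6, 4)
  m4 <- m3; m4[2, ] <- m4[2, ] + 100
  expect_equal(unname(rmAnova(m4)$statistic), unname(rmAnova(m3)$statistic))
  # degenerate flat table is flagged
  expect_true(is.na(rmAnova(matrix(3, 4, 3))$statistic))
})

test_that("repeated-measures ANOVA agrees with aov(Error())", {
  set.seed(18)
  n <- 12; k <- 5
  m <- matrix(rnorm(n * k), n, k) + rnorm(n)
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:n, times = k)),
                     cond = factor(rep(1:k, each = n)))
  fit <- stats::aov(y ~ cond + Error(subj/cond), data = long)
  tab <- summary(fit)[["Error: subj:cond"]][[1]]
  ours <- rmAnova(m)
  expect_equal(unname(ours$statistic), tab["cond", "F value"], tolerance = 1e-8)
  expect_equal(ours$p.value, tab["cond", "Pr(>F)"], tolerance = 1e-8)
  # the Greenhouse-Geisser option reduces the df and keeps F
  gg <- rmAnova(m, sphericityCorrection = "greenhouse-geisser")
  expect_equal(unname(gg$statistic), unname(ours$statistic))
  expect_lte(unname(gg$parameter["df1"]), k - 1)
})

test_that("Bonferroni post-hocs scale and cap p-values over all pairs", {
  set.seed(4)
  m <- matrix(rnorm(8 * 4), 8, 4)
  colnames(m) <- paste0("c", 1:4)
  res <- bonferroniPairwise(m, baseTest = "paired_t")
  expect_equal(nrow(res), 6)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 6))
  expect_equal(res$p_adjusted,
               unname(p.adjust(res$p_raw, method = "bonferroni")))
  expect_true(all(res$p_adjusted >= res$p_raw))
  # adjusted p-values stay monotone in the raw ones
  o <- order(res$p_raw)
  expect_true(!is.unsorted(res$p_adjusted[o]))
  # 18 conditions give 153 pairwise comparisons
  m18 <- matrix(rnorm(3 * 18), 3, 18)
  expect_equal(nrow(bonferroniPairwise(m18, baseTest = "paired_t")), 153)
})

test_that("assumption checks recommend the nonparametric path when violated", {
  set.seed(33)
  normal <- rnorm(50)
  expo <- rexp(200)
  rep1 <- assumptionChecks(c(normal, rnorm(50, 2)),
                           rep(c("a", "b"), each = 50))
  expect_true(all(rep1$normality$shapiro_p > 0.05))
  expect_equal(rep1$recommendation, "parametric")
  rep2 <- assumptionChecks(c(expo, rnorm(200)), rep(c("e", "n"), each = 200))
  expect_lt(rep2$normality$shapiro_p[rep2$normality$group == "e"], 0.05)
  expect_equal(rep2$recommendation, "nonparametric")
  # degenerate constant groups are flagged, not fatal
  rep3 <- assumptionChecks(rep(c(1, 1, 1, 2, 2, 2)), rep(c("a", "b"), each = 3))
  expect_true(length(rep3$notes) > 0)
})

test_that("condition tables reshape summaries for both canonical groupings", {
  sched <- defaultSchedule()
  s <- expand.grid(fish = 1:3, period = 1:18)
  s$pct_move <- s$period + 100 * s$fish
  tblP <- conditionTable(s, "pct_move", "periods")
  expect_equal(dim(tblP), c(3, 18))
  expect_equal(tblP[2, "7"], 207)
  tblS <- conditionTable(s, "pct_move", "stimuli", sched)
  expect_equal(colnames(tblS),
               c("blank_hour1", "lines_RL", "lines_LR", "blank_hour3"))
  expect_equal(tblS[1, "lines_RL"], mean(c(7, 9, 11)) + 100)
  expect_equal(tblS[3, "blank_hour3"], mean(13:18) + 300)
  expect_equal(stimulusGrouping(sched)[c(1, 7, 8, 13)],
               c("blank_hour1", "lines_RL", "lines_LR", "blank_hour3"))
})
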