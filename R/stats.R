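.checkRMTable <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (!is.numeric(tbl)) stop("table must be numeric (subjects x conditions)")
  if (any(is.na(tbl))) stop("repeated-measures table has missing cells")
  if (nrow(tbl) < 2 || ncol(tbl) < 2)
    stop("need at least 2 subjects and 2 conditions")
  tbl
}

.htest <- function(statistic, parameter, p.value, method, note = NULL) {
  structure(
    list(statistic = statistic, parameter = parameter,
         p.value = p.value, method = method,
         note = note, data.name = "subjects x conditions table"),
    class = "htest")
}

#' Friedman rank-sum test for a complete repeated-measures table
#'
#' Values are mid-ranked within each subject; the chi-square statistic uses
#' the general tie-corrected form
#' \deqn{\chi^2_F = \frac{(k-1)\sum_j (R_j - n(k+1)/2)^2}
#'   {\sum_{ij} r_{ij}^2 - nk(k+1)^2/4}}{
#'   chi2 = (k-1) sum_j (R_j - n(k+1)/2)^2 / (sum r_ij^2 - n k (k+1)^2 / 4)}
#' which reduces to the classical \eqn{12/(nk(k+1)) \sum R_j^2 - 3n(k+1)}
#' without ties. The p-value comes from the chi-square distribution with
#' \code{k - 1} degrees of freedom. A fully tied table (all cells equal)
#' gives statistic 0 and p = 1.
#'
#' @param tbl numeric matrix or data.frame, subjects in rows, conditions in
#'   columns, no missing cells.
#' @return an object of class \code{"htest"}.
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 4, 6), c(10, 20, 30))
#' friedmanTest(m)   # statistic 6 on 2 df
#' @export
friedmanTest <- function(tbl) {
  tbl <- .checkRMTable(tbl)
  n <- nrow(tbl); k <- ncol(tbl)
  r <- t(apply(tbl, 1, rank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  stat <- if (den <= 0) 0 else num / den
  p <- if (den <= 0) 1 else stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  .htest(c("Friedman chi-squared" = stat), c(df = k - 1), p,
         "Friedman rank sum test (tie-corrected)")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (the original zero policy); the absolute
#' differences are mid-ranked and the statistic is
#' \code{W = min(W+, W-)}. For n <= 25 untied differences the p-value is
#' exact (signed-rank distribution); otherwise a normal approximation with
#' tie correction and continuity correction is used. Reported p-values are
#' two-sided. All-zero differences give the degenerate result W = 0, p = 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exactMax largest n for which the exact distribution is used
#'   (default 25).
#' @return an object of class \code{"htest"}.
#' @examples
#' wilcoxonSignedRank(c(3, 5, 8), c(2, 3, 5))
#' @export
wilcoxonSignedRank <- function(x, y, exactMax = 25) {
  if (length(x) != length(y) || length(x) < 1)
    stop("x and y must be paired vectors of equal length >= 1")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(.htest(c(W = 0), c(n = 0), 1,
                  "Wilcoxon signed rank test", note = "degenerate: all differences zero"))
  rk <- rank(abs(d))
  Wp <- sum(rk[d > 0])
  Wm <- sum(rk) - Wp
  W <- min(Wp, Wm)
  ties <- any(duplicated(abs(d)))
  if (n <= exactMax && !ties) {
    p <- min(1, 2 * stats::psignrank(W, n))
    method <- "Wilcoxon signed rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu + 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "Wilcoxon signed rank test (normal approximation)"
  }
  .htest(c(W = W), c(n = n), p, method)
}

#' One-way repeated-measures ANOVA
#'
#' Decomposes the total sum of squares of a complete subjects-by-conditions
#' table as \code{SS_total = SS_subjects + SS_conditions + SS_error} and
#' tests \code{F = MS_conditions / MS_error} on \code{(k-1, (k-1)(n-1))}
#' degrees of freedom. No sphericity correction is applied by default; a
#' Greenhouse-Geisser adjustment of the degrees of freedom is available.
#'
#' @param tbl numeric matrix or data.frame, subjects in rows, conditions in
#'   columns, no missing cells.
#' @param sphericityCorrection \code{"none"} (default) or
#'   \code{"greenhouse-geisser"}.
#' @return an object of class \code{"htest"} (statistic F, parameter the
#'   two df; the note records the GG epsilon when applied). A table with
#'   both zero condition variance and zero error variance yields an
#'   undefined F flagged in the note.
#' @export
rmAnova <- function(tbl, sphericityCorrection = c("none", "greenhouse-geisser")) {
  sphericityCorrection <- match.arg(sphericityCorrection)
  tbl <- .checkRMTable(tbl)
  n <- nrow(tbl); k <- ncol(tbl)
  grand <- mean(tbl)
  ssSub <- k * sum((rowMeans(tbl) - grand)^2)
  ssCond <- n * sum((colMeans(tbl) - grand)^2)
  ssTot <- sum((tbl - grand)^2)
  ssErr <- max(ssTot - ssSub - ssCond, 0)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  msCond <- ssCond / df1
  msErr <- ssErr / df2
  if (msErr == 0 && msCond == 0)
    return(.htest(c(F = NA_real_), c(df1 = df1, df2 = df2), NA_real_,
                  "one-way repeated-measures ANOVA",
                  note = "degenerate: zero condition and error variance"))
  note <- NULL
  eps <- 1
  if (sphericityCorrection == "greenhouse-geisser") {
    S <- stats::cov(tbl)
    C <- diag(k) - matrix(1 / k, k, k)
    Sc <- C %*% S %*% C
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
    note <- sprintf("Greenhouse-Geisser epsilon = %.4f", eps)
  }
  f <- msCond / msErr
  p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  .htest(c(F = f), c(df1 = df1 * eps, df2 = df2 * eps), p,
         "one-way repeated-measures ANOVA", note = note)
}

#' Bonferroni-adjusted pairwise post-hoc tests
#'
#' Tests every pair of conditions with a paired base test and multiplies the
#' raw p-values by the number of pairs \code{m = k(k-1)/2}, capped at 1.
#'
#' @param tbl numeric matrix or data.frame, subjects in rows, conditions in
#'   columns.
#' @param baseTest \code{"wilcoxon"} (signed rank) or \code{"paired_t"}.
#' @return data.frame with one row per pair: \code{cond_a}, \code{cond_b},
#'   \code{statistic}, \code{p_raw}, \code{p_adjusted}, \code{method}.
#' @export
bonferroniPairwise <- function(tbl, baseTest = c("wilcoxon", "paired_t")) {
  baseTest <- match.arg(baseTest)
  tbl <- .checkRMTable(tbl)
  k <- ncol(tbl)
  labels <- colnames(tbl)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- if (baseTest == "wilcoxon") {
      wilcoxonSignedRank(tbl[, a], tbl[, b])
    } else {
      tt <- stats::t.test(tbl[, a], tbl[, b], paired = TRUE)
      .htest(tt$statistic, tt$parameter, tt$p.value, "paired t-test")
    }
    data.frame(cond_a = labels[a], cond_b = labels[b],
               statistic = unname(res$statistic), p_raw = res$p.value,
               method = res$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out[, c("cond_a", "cond_b", "statistic", "p_raw", "p_adjusted", "method")]
}

#' Normality and equal-variance checks
#'
#' Shapiro-Wilk normality per group (skipped with a notice for groups
#' smaller than 3) and a Levene-type (Brown-Forsythe, median-centered)
#' equal-variance test across groups. The report recommends the
#' nonparametric path when any p-value falls below \code{alpha}.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as \code{values}.
#' @param alpha decision level (default 0.05).
#' @return list with \code{normality} (data.frame group/n/p), \code{levene_p},
#'   \code{recommendation} (\code{"parametric"} / \code{"nonparametric"})
#'   and \code{notes}.
#' @export
assumptionChecks <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  notes <- character()
  norm <- do.call(rbind, lapply(levels(g), function(lev) {
    v <- values[g == lev]
    p <- NA_real_
    if (length(v) < 3) {
      notes <<- c(notes, sprintf("group '%s' too small for normality check", lev))
    } else if (length(unique(v)) == 1) {
      notes <<- c(notes, sprintf("group '%s' is constant; normality check degenerate", lev))
    } else {
      p <- stats::shapiro.test(v)$p.value
    }
    data.frame(group = lev, n = length(v), shapiro_p = p,
               stringsAsFactors = FALSE)
  }))
  levene_p <- NA_real_
  if (nlevels(g) >= 2 && all(tabulate(g) >= 2)) {
    lv <- tryCatch(car::leveneTest(values ~ g, center = stats::median),
                   error = function(e) NULL,
                   warning = function(w) suppressWarnings(
                     car::leveneTest(values ~ g, center = stats::median)))
    if (!is.null(lv) && is.finite(lv[["Pr(>F)"]][1])) {
      levene_p <- lv[["Pr(>F)"]][1]
    } else {
      notes <- c(notes, "variance check degenerate (e.g. identical constant groups)")
    }
  } else {
    notes <- c(notes, "too few observations per group for the variance check")
  }
  ps <- c(norm$shapiro_p, levene_p)
  rec <- if (any(ps < alpha, na.rm = TRUE)) "nonparametric" else "parametric"
  list(normality = norm, levene_p = levene_p,
       recommendation = rec, notes = notes)
}

#' Map periods to canonical stimulus classes
#'
#' Collapses the 18 periods into the four stimulus classes used for the
#' stimulus-level analysis: the blank first hour, lines moving right to left
#' (leftward; periods 7, 9, 11), lines moving left to right (rightward;
#' periods 8, 10, 12), and the blank third hour.
#'
#' @param sched an \code{ExperimentSchedule}; defaults to the canonical one.
#' @return character vector, one class label per period.
#' @export
stimulusGrouping <- function(sched = defaultSchedule()) {
  p <- periods(sched)
  ifelse(p$phase == "baseline", "blank_hour1",
  ifelse(p$phase == "post", "blank_hour3",
  ifelse(p$direction == "leftward", "lines_RL", "lines_LR")))
}

#' Subjects-by-conditions table of a summary measure
#'
#' Reshapes a period-summary table into the complete repeated-measures
#' matrix the tests consume, with conditions either the individual periods
#' or the four stimulus classes (values averaged within class per fish).
#'
#' @param summaries period-summary table (several fish).
#' @param measure summary column, e.g. \code{"pct_move"}.
#' @param grouping \code{"periods"} or \code{"stimuli"}.
#' @param sched schedule used for the stimulus classes.
#' @return numeric matrix, rows = fish, columns = conditions.
#' @export
conditionTable <- function(summaries, measure,
                           grouping = c("periods", "stimuli"),
                           sched = defaultSchedule()) {
  grouping <- match.arg(grouping)
  cond <- if (grouping == "periods") {
    as.character(summaries$period)
  } else {
    stimulusGrouping(sched)[summaries$period]
  }
  agg <- stats::aggregate(summaries[[measure]],
                          by = list(fish = summaries$fish, cond = cond),
                          FUN = mean)
  condLevels <- if (grouping == "periods") {
    as.character(sort(unique(summaries$period)))
  } else {
    c("blank_hour1", "lines_RL", "lines_LR", "blank_hour3")
  }
  fishIds <- sort(unique(summaries$fish))
  m <- matrix(NA_real_, length(fishIds), length(condLevels),
              dimnames = list(fishIds, condLevels))
  m[cbind(match(agg$fish, fishIds), match(agg$cond, condLevels))] <- agg$x
  m
}
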