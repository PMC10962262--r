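#' Canonical names of the 24 profile measures
#'
#' Column order matches the standard behavioral-profile table: baseline
#' speed; six movement measures; six end-zone measures; the clockwise
#' (right-flank-to-center) baseline; three optomotor location indices with
#' two habituation contrasts; and the same five built on orientation.
#'
#' @return character vector of length 24.
#' @export
profileMeasureNames <- function() {
  c("Speed_p1_6",
    "M_1h", "M_Accl", "M_Vis", "M_St", "M_Hab_7_9", "M_Hab_9_11",
    "E_1h", "E_Accl", "E_Vis", "E_St", "E_Hab_7_9", "E_Hab_9_11",
    "CW_p1_6",
    "OMRL_7_8", "OMRL_9_10", "OMRL_11_12", "OMRLHab_7_9", "OMRLHab_9_11",
    "OMRO_7_8", "OMRO_9_10", "OMRO_11_12", "OMROHab_7_9", "OMROHab_9_11")
}

.pct <- function(flag) {
  n <- sum(!is.na(flag))
  if (n == 0) return(NA_real_)
  100 * sum(flag, na.rm = TRUE) / n
}

#' Per-period behavioral summaries
#'
#' Aggregates the per-frame metrics of each fish into one row per period:
#' percentage of frames moving (over speed-defined frames), in an end zone
#' and in the right half (over detection-found frames), oriented right and
#' right-flank-to-center (over heading-defined frames), plus the mean speed
#' and the denominators used. Percentages are computed over defined frames
#' only, so missing detections shrink the denominator instead of biasing
#' toward zero; a period with an empty denominator yields NA.
#'
#' @param metrics metrics table from \code{\link{metricsSeries}}; one fish
#'   per tank, \code{time_s} within the schedule span.
#' @param sched the \code{\link[=ExperimentSchedule-class]{ExperimentSchedule}}.
#' @return data.frame with columns \code{fish}, \code{period},
#'   \code{pct_move}, \code{pct_end}, \code{pct_right},
#'   \code{pct_oriented_right}, \code{pct_cw}, \code{mean_speed_cm_s},
#'   \code{n_frames}, \code{n_valid_speed}, \code{n_valid_orient}, ordered
#'   by (fish, period).
#' @export
summarizePeriods <- function(metrics, sched) {
  p <- periods(sched)
  total <- p$end_s[nrow(p)]
  if (any(metrics$time_s < 0 | metrics$time_s >= total))
    stop(sprintf("metrics time_s must lie in [0, %g)", total))
  per <- findInterval(metrics$time_s, p$start_s)
  fish <- metrics$tank
  key <- split(seq_len(nrow(metrics)), list(fish = fish, period = per),
               drop = TRUE)
  rows <- lapply(key, function(i) {
    m <- metrics[i, ]
    data.frame(
      fish = m$tank[1], period = per[i[1]],
      pct_move = .pct(m$moving),
      pct_end = .pct(ifelse(m$valid, m$in_end, NA)),
      pct_right = .pct(ifelse(m$valid, m$in_right_half, NA)),
      pct_oriented_right = .pct(m$oriented_right),
      pct_cw = .pct(m$rfc_cw),
      mean_speed_cm_s = if (all(is.na(m$speed_cm_s))) NA_real_
                        else mean(m$speed_cm_s, na.rm = TRUE),
      n_frames = nrow(m),
      n_valid_speed = sum(!is.na(m$speed_cm_s)),
      n_valid_orient = sum(!is.na(m$oriented_right))
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fish, out$period), ]
  rownames(out) <- NULL
  out
}

#' Difference of a summary measure between two period sets
#'
#' Mean of the measure over periods \code{a} minus its mean over periods
#' \code{b}. All contrast measures of the profile use this with the
#' convention earlier-minus-later (habituation, acclimation) or
#' pre-minus-post (startle).
#'
#' @param s period-summary table for one fish.
#' @param measure summary column name, e.g. \code{"pct_move"}.
#' @param a,b integer vectors of period indices.
#' @return difference in the measure's units (percentage points for the
#'   occupancy measures); NA if any involved summary is undefined.
#' @examples
#' s <- data.frame(fish = 1, period = 1:18, pct_move = c(50, 50, 50, 46,
#'   46, 46, rep(60, 6), rep(40, 6)))
#' delta(s, "pct_move", 1:3, 4:6)   # acclimation: 4
#' @export
delta <- function(s, measure, a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  va <- s[[measure]][match(a, s$period)]
  vb <- s[[measure]][match(b, s$period)]
  if (any(is.na(va)) || any(is.na(vb))) return(NA_real_)
  mean(va) - mean(vb)
}

#' Build the 24-measure behavioral profile of one fish
#'
#' Combines the 18 period summaries into the canonical profile (see
#' \code{\link{profileMeasureNames}}):
#' \itemize{
#'   \item \code{Speed_p1_6}: mean speed over the baseline hour (cm/s).
#'   \item \code{M_1h}, \code{M_Vis}: mean \%move over periods 1-6 / 7-12.
#'   \item \code{M_Accl}: \%move(periods 1-3) - \%move(periods 4-6).
#'   \item \code{M_St}: \%move(period 6) - \%move(period 7), the startle
#'     contrast (negative when stimulus onset raises activity).
#'   \item \code{M_Hab_7_9}, \code{M_Hab_9_11}: earlier-minus-later
#'     habituation contrasts between same-direction stimulus periods.
#'   \item \code{E_*}: the same six constructions on end-zone occupancy.
#'   \item \code{CW_p1_6}: mean right-flank-to-center \% over the baseline
#'     hour (persistent values above 50 indicate clockwise circling).
#'   \item \code{OMRL_a_b}: \%right(rightward-lines period b) -
#'     \%right(leftward-lines period a) for (7,8), (9,10), (11,12);
#'     negative values mean the fish locates against the lines.
#'   \item \code{OMRLHab_7_9}, \code{OMRLHab_9_11}: \%right(earlier
#'     leftward period) - \%right(later leftward period).
#'   \item \code{OMRO_*}, \code{OMROHab_*}: identical constructions on the
#'     oriented-right percentage.
#' }
#'
#' @param s period-summary table for one fish covering periods 1..18.
#' @return one-row data.frame: \code{fish} plus the 24 measures.
#' @export
buildProfile <- function(s) {
  if (length(unique(s$fish)) != 1)
    stop("buildProfile expects the summaries of exactly one fish")
  if (!all(1:18 %in% s$period))
    stop("periods missing from summary: ",
         paste(setdiff(1:18, s$period), collapse = ", "))
  avg <- function(measure, idx) mean(s[[measure]][match(idx, s$period)])
  out <- data.frame(
    fish = s$fish[1],
    Speed_p1_6 = avg("mean_speed_cm_s", 1:6),
    M_1h = avg("pct_move", 1:6),
    M_Accl = delta(s, "pct_move", 1:3, 4:6),
    M_Vis = avg("pct_move", 7:12),
    M_St = delta(s, "pct_move", 6, 7),
    M_Hab_7_9 = delta(s, "pct_move", 7, 9),
    M_Hab_9_11 = delta(s, "pct_move", 9, 11),
    E_1h = avg("pct_end", 1:6),
    E_Accl = delta(s, "pct_end", 1:3, 4:6),
    E_Vis = avg("pct_end", 7:12),
    E_St = delta(s, "pct_end", 6, 7),
    E_Hab_7_9 = delta(s, "pct_end", 7, 9),
    E_Hab_9_11 = delta(s, "pct_end", 9, 11),
    CW_p1_6 = avg("pct_cw", 1:6),
    OMRL_7_8 = delta(s, "pct_right", 8, 7),
    OMRL_9_10 = delta(s, "pct_right", 10, 9),
    OMRL_11_12 = delta(s, "pct_right", 12, 11),
    OMRLHab_7_9 = delta(s, "pct_right", 7, 9),
    OMRLHab_9_11 = delta(s, "pct_right", 9, 11),
    OMRO_7_8 = delta(s, "pct_oriented_right", 8, 7),
    OMRO_9_10 = delta(s, "pct_oriented_right", 10, 9),
    OMRO_11_12 = delta(s, "pct_oriented_right", 12, 11),
    OMROHab_7_9 = delta(s, "pct_oriented_right", 7, 9),
    OMROHab_9_11 = delta(s, "pct_oriented_right", 9, 11)
  )
  rownames(out) <- NULL
  out
}

#' Build profiles for every fish in a summary table
#'
#' @param summaries period-summary table covering several fish.
#' @return data.frame with one profile row per fish.
#' @export
buildProfiles <- function(summaries) {
  out <- do.call(rbind, lapply(split(summaries, summaries$fish), buildProfile))
  rownames(out) <- NULL
  out
}

#' Group mean, SEM and N of behavioral profiles
#'
#' Per measure: the arithmetic mean, the standard error of the mean using
#' the sample (n-1) standard deviation, and the profile count.
#'
#' @param profiles data.frame of profiles (rows = fish) containing the 24
#'   canonical measure columns.
#' @return data.frame with columns \code{measure}, \code{avg}, \code{sem},
#'   \code{n}, one row per measure in canonical order.
#' @export
groupSummary <- function(profiles) {
  meas <- profileMeasureNames()
  missing <- setdiff(meas, names(profiles))
  if (length(missing))
    stop("profiles lack measure columns: ", paste(missing, collapse = ", "))
  n <- nrow(profiles)
  if (n < 2) warning("fewer than 2 profiles: SEM undefined")
  data.frame(
    measure = factor(meas, levels = meas),
    avg = vapply(meas, function(m) mean(profiles[[m]]), numeric(1)),
    sem = vapply(meas, function(m) {
      if (n < 2) NA_real_ else stats::sd(profiles[[m]]) / sqrt(n)
    }, numeric(1)),
    n = n,
    row.names = NULL
  )
}

# ---- hexagonal binning -----------------------------------------------------

# flat-top axial lattice: center(q, r) = (1.5 R q, sqrt(3) R (r + q/2));
# axial neighbor offsets of a flat-top hexagon
.hexNeighborOffsets <- matrix(c(0, 0, 1, 0, 1, -1, 0, -1, -1, 0, -1, 1, 0, 1),
                              ncol = 2, byrow = TRUE)

#' Hexagonal occupancy density
#'
#' Assigns each position to exactly one regular flat-top hexagon of the
#' lattice anchored at the ROI origin (a hexagon center sits at (0, 0)) and
#' counts occupancies. Assignment is nearest hexagon center; points
#' equidistant from several centers go to the lexicographically smallest
#' \code{(hex_cx, hex_cy)}.
#'
#' @param x,y positions in px.
#' @param circumradius hexagon circumradius (center to vertex), px; default
#'   10.
#' @return data.frame with columns \code{hex_cx}, \code{hex_cy},
#'   \code{count}, one row per occupied hexagon, counts summing to the
#'   number of positions.
#' @examples
#' h <- hexbin(runif(500, 0, 100), runif(500, 0, 100), circumradius = 15)
#' sum(h$count)
#' @export
hexbin <- function(x, y, circumradius = 10) {
  stopifnot(circumradius > 0, length(x) == length(y))
  if (!length(x))
    return(data.frame(hex_cx = numeric(0), hex_cy = numeric(0),
                      count = numeric(0)))
  R <- circumradius
  qf <- (2 / 3) * x / R
  rf <- (-x / 3 + sqrt(3) / 3 * y) / R
  # cube rounding
  xr <- round(qf); zr <- round(rf); yr <- round(-qf - rf)
  dx <- abs(xr - qf); dz <- abs(zr - rf); dy <- abs(yr + qf + rf)
  fixX <- dx > dy & dx > dz
  fixZ <- !fixX & dz > dy
  xr[fixX] <- -yr[fixX] - zr[fixX]
  zr[fixZ] <- -xr[fixZ] - yr[fixZ]
  q <- xr; r <- zr
  # nearest-center refinement over the hexagon and its 6 neighbors with a
  # lexicographic tie-break on (cx, cy)
  best <- rep(Inf, length(x))
  bq <- q; br <- r
  bcx <- rep(Inf, length(x)); bcy <- rep(Inf, length(x))
  for (k in seq_len(nrow(.hexNeighborOffsets))) {
    cq <- q + .hexNeighborOffsets[k, 1]
    cr <- r + .hexNeighborOffsets[k, 2]
    cx <- 1.5 * R * cq
    cy <- sqrt(3) * R * (cr + cq / 2)
    d2 <- (x - cx)^2 + (y - cy)^2
    eps <- 1e-9 * R^2
    take <- d2 < best - eps |
      (abs(d2 - best) <= eps & (cx < bcx - 1e-12 |
                                  (abs(cx - bcx) <= 1e-12 & cy < bcy)))
    bq[take] <- cq[take]; br[take] <- cr[take]
    bcx[take] <- cx[take]; bcy[take] <- cy[take]
    best[take] <- pmin(best[take], d2[take])
  }
  key <- paste(bq, br)
  agg <- table(key)
  first <- !duplicated(key)
  map <- data.frame(key = key[first], cx = bcx[first], cy = bcy[first])
  out <- data.frame(
    hex_cx = map$cx[match(names(agg), map$key)],
    hex_cy = map$cy[match(names(agg), map$key)],
    count = as.numeric(agg)
  )
  out <- out[order(out$hex_cx, out$hex_cy), ]
  rownames(out) <- NULL
  out
}
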