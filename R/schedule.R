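#' Canonical 3-hour stimulus schedule
#'
#' Builds the standard trial timeline: 18 equal periods, of which 1-6 are a
#' blank baseline hour, 7-12 present moving red lines and 13-18 are a blank
#' post hour. Thin lines (1 mm, 7 mm apart, 10.8 cm/s) run in periods 7-8,
#' medium lines (10 mm, 10 mm, 13.8 cm/s) in 9-10 and thick lines (20 mm,
#' 20 mm, 27.6 cm/s) in 11-12; odd stimulus periods move leftward (right to
#' left on screen), even ones rightward.
#'
#' @param periodS length of one period in seconds. 600 s is the canonical
#'   value; shorter periods give a compressed trial with identical structure,
#'   convenient for small worked examples.
#' @return an \code{\link[=ExperimentSchedule-class]{ExperimentSchedule}}.
#' @examples
#' sched <- defaultSchedule()
#' periods(sched)[7, ]
#' @export
defaultSchedule <- function(periodS = 600) {
  stopifnot(is.numeric(periodS), length(periodS) == 1, periodS > 0)
  idx <- 1:18
  kind <- ifelse(idx >= 7 & idx <= 12, "moving_lines", "blank")
  direction <- rep("none", 18)
  direction[idx %in% c(7, 9, 11)] <- "leftward"
  direction[idx %in% c(8, 10, 12)] <- "rightward"
  thickness <- c(rep(0, 6), 1, 1, 10, 10, 20, 20, rep(0, 6))
  spacing <- c(rep(0, 6), 7, 7, 10, 10, 20, 20, rep(0, 6))
  speed <- c(rep(0, 6), 10.8, 10.8, 13.8, 13.8, 27.6, 27.6, rep(0, 6))
  p <- data.frame(
    index = idx,
    start_s = (idx - 1) * periodS,
    end_s = idx * periodS,
    phase = rep(c("baseline", "stimulus", "post"), each = 6),
    kind = kind, direction = direction,
    thickness_mm = thickness, spacing_mm = spacing, speed_cm_s = speed,
    stringsAsFactors = FALSE
  )
  new("ExperimentSchedule", periods = p)
}

#' Build a schedule from a period table or config list
#'
#' Accepts either a data.frame with the full period columns or a list of
#' per-period entries (as produced by parsing a YAML/JSON schedule file).
#' Missing \code{index}/\code{start_s}/\code{end_s}/\code{phase} fields are
#' filled from the row order and \code{periodS}; blank periods may omit line
#' geometry.
#'
#' @param x data.frame or list of lists describing the periods in order.
#' @param periodS period length used when start/end times are not given.
#' @return an \code{ExperimentSchedule}.
#' @seealso \code{\link{readSchedule}}
#' @export
scheduleFromConfig <- function(x, periodS = 600) {
  if (is.data.frame(x)) {
    p <- x
  } else if (is.list(x)) {
    rows <- lapply(x, function(e) {
      kind <- if (is.null(e$kind)) "blank" else e$kind
      data.frame(
        kind = kind,
        direction = if (is.null(e$direction)) "none" else e$direction,
        thickness_mm = if (is.null(e$thickness_mm)) 0 else e$thickness_mm,
        spacing_mm = if (is.null(e$spacing_mm)) 0 else e$spacing_mm,
        speed_cm_s = if (is.null(e$speed_cm_s)) 0 else e$speed_cm_s,
        stringsAsFactors = FALSE
      )
    })
    p <- do.call(rbind, rows)
  } else {
    stop("x must be a data.frame or a list of period entries")
  }
  n <- nrow(p)
  if (is.null(p$index)) p$index <- seq_len(n)
  if (is.null(p$start_s)) p$start_s <- (seq_len(n) - 1) * periodS
  if (is.null(p$end_s)) p$end_s <- seq_len(n) * periodS
  if (is.null(p$phase)) p$phase <- rep(c("baseline", "stimulus", "post"), each = n / 3)
  new("ExperimentSchedule", periods = p[, .scheduleColumns])
}

#' Map a timestamp to its period
#'
#' Periods are half-open \code{[start_s, end_s)}, so every in-range time
#' belongs to exactly one period.
#'
#' @param sched an \code{ExperimentSchedule}.
#' @param t time in seconds from trial start; vectorized.
#' @return the matching row(s) of \code{periods(sched)} (one row per time).
#' @examples
#' sched <- defaultSchedule()
#' periodOf(sched, 3600)$index   # first stimulus period
#' @export
setGeneric("periodOf", function(sched, t) standardGeneric("periodOf"))

#' @rdname periodOf
#' @export
setMethod("periodOf", "ExperimentSchedule", function(sched, t) {
  p <- sched@periods
  total <- p$end_s[nrow(p)]
  if (any(!is.finite(t)) || any(t < 0) || any(t >= total))
    stop(sprintf("t must lie in [0, %g)", total))
  idx <- findInterval(t, p$start_s)
  p[idx, , drop = FALSE]
})

#' Phase of a canonical period index
#'
#' For the canonical 18-period trial: indices 1-6 are \code{baseline},
#' 7-12 \code{stimulus} and 13-18 \code{post}.
#'
#' @param index integer period index in 1..18; vectorized.
#' @return character vector of phases.
#' @examples
#' phaseOf(c(1, 7, 18))
#' @export
phaseOf <- function(index) {
  if (any(index != as.integer(index)) || any(index < 1) || any(index > 18))
    stop("index must be an integer in 1..18")
  .PHASES[(as.integer(index) - 1L) %/% 6L + 1L]
}

#' Read / write a schedule as YAML or JSON
#'
#' The on-disk format is a mapping with an optional scalar \code{period_s}
#' and a \code{periods} sequence whose entries carry \code{kind},
#' \code{direction}, \code{thickness_mm}, \code{spacing_mm} and
#' \code{speed_cm_s}. Files ending in \code{.json} are parsed as JSON,
#' anything else as YAML.
#'
#' @param path file path.
#' @param sched an \code{ExperimentSchedule} (for writing).
#' @return \code{readSchedule} returns an \code{ExperimentSchedule};
#'   \code{writeSchedule} returns \code{path} invisibly.
#' @export
readSchedule <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  periodS <- if (is.null(cfg$period_s)) 600 else cfg$period_s
  entries <- if (!is.null(cfg$periods)) cfg$periods else cfg
  scheduleFromConfig(entries, periodS = periodS)
}

#' @rdname readSchedule
#' @export
writeSchedule <- function(sched, path) {
  stopifnot(is(sched, "ExperimentSchedule"))
  p <- sched@periods
  entries <- lapply(seq_len(nrow(p)), function(i) list(
    kind = p$kind[i], direction = p$direction[i],
    thickness_mm = p$thickness_mm[i], spacing_mm = p$spacing_mm[i],
    speed_cm_s = p$speed_cm_s[i]
  ))
  out <- list(period_s = p$end_s[1] - p$start_s[1], periods = entries)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
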