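#' Assemble and validate a pipeline configuration
#'
#' A configuration names the input (exactly one of a frame directory /
#' in-memory frame container, a detections CSV, or \code{synthetic = TRUE}),
#' the geometry and schedule, and the analysis settings. Input paths are
#' checked at validation time, before any computation.
#'
#' @param outDir output directory (created if needed).
#' @param frames frame container (directory path, list, or function) or NULL.
#' @param detections path to a detections CSV, or a detections data.frame,
#'   or NULL.
#' @param synthetic if TRUE, simulate a cohort instead of reading input.
#' @param render for synthetic runs: render frames and run detection on
#'   them (slow but end-to-end) instead of using perfect track geometry.
#' @param rois list of \code{\link{tankROI}} or a ROI YAML path.
#' @param sched an \code{ExperimentSchedule} or a schedule YAML/JSON path.
#' @param detection a \code{\link{detectionConfig}}.
#' @param params a \code{\link{behaviorParams}} for synthetic runs.
#' @param intervalS frame interval, seconds.
#' @param hexRadius hexagon circumradius for the density map, px.
#' @param statsMeasure summary measure tested by the stats stage.
#' @param statsGrouping \code{"periods"} or \code{"stimuli"}.
#' @param seed seed for synthetic runs (overrides \code{params@seed}).
#' @param nFrames frame count for function frame sources.
#' @return a validated config list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(outDir,
                           frames = NULL, detections = NULL,
                           synthetic = FALSE, render = FALSE,
                           rois = defaultTankROIs(),
                           sched = defaultSchedule(),
                           detection = detectionConfig(),
                           params = behaviorParams(),
                           intervalS = 1, hexRadius = 10,
                           statsMeasure = "pct_move",
                           statsGrouping = c("periods", "stimuli"),
                           seed = NULL, nFrames = NULL) {
  statsGrouping <- match.arg(statsGrouping)
  nInputs <- sum(!is.null(frames), !is.null(detections), isTRUE(synthetic))
  if (nInputs != 1)
    stop("exactly one input must be given: frames, detections or synthetic")
  if (is.character(frames) && !dir.exists(frames))
    stop("frame directory not found: ", frames)
  if (is.character(detections) && !file.exists(detections))
    stop("detections file not found: ", detections)
  if (is.character(rois)) {
    if (!file.exists(rois)) stop("ROI file not found: ", rois)
    rois <- readTankROIs(rois)
  }
  if (is.character(sched)) {
    if (!file.exists(sched)) stop("schedule file not found: ", sched)
    sched <- readSchedule(sched)
  }
  if (intervalS <= 0) stop("intervalS must be positive")
  if (!is.null(seed)) params@seed <- as.integer(seed)
  structure(list(
    outDir = outDir, frames = frames, detections = detections,
    synthetic = isTRUE(synthetic), render = isTRUE(render),
    rois = rois, sched = sched, detection = detection, params = params,
    intervalS = intervalS, hexRadius = hexRadius,
    statsMeasure = statsMeasure, statsGrouping = statsGrouping,
    nFrames = nFrames
  ), class = "pipelineConfig")
}

.logStage <- function(...) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes detection (or loads/simulates detections), per-frame metrics,
#' period summaries, behavioral profiles, the group summary, the hexagonal
#' density map and the statistical stage, writing each table as CSV into
#' \code{outDir} together with a JSON run manifest (config echo, package
#' version, seed, row counts, and the failed stage on error). A stage
#' failure aborts with a stage-tagged error; tables already written are
#' retained.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the computed tables and output paths.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  manifest <- list(
    package = "zebrafishOMR",
    version = as.character(utils::packageVersion("zebrafishOMR")),
    seed = cfg$params@seed, interval_s = cfg$intervalS,
    synthetic = cfg$synthetic, render = cfg$render,
    counts = list(), failed_stage = NULL
  )
  writeManifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      writeManifest()
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  det <- stage("detect", {
    if (cfg$synthetic) {
      tracks <- simulateCohort(cfg$params, cfg$rois, cfg$sched,
                               intervalS = cfg$intervalS)
      if (cfg$render) {
        src <- renderFrames(tracks, cfg$rois, cfg$sched)
        analyzeMovie(src$get, cfg$rois, cfg$detection,
                     intervalS = cfg$intervalS, nFrames = src$n)
      } else {
        cohortDetections(tracks, cfg$rois)
      }
    } else if (!is.null(cfg$detections)) {
      if (is.character(cfg$detections)) readDetections(cfg$detections)
      else .checkCols(cfg$detections, .detectionCols, "detections")
    } else {
      analyzeMovie(cfg$frames, cfg$rois, cfg$detection,
                   intervalS = cfg$intervalS, nFrames = cfg$nFrames)
    }
  })
  paths$detections <- file.path(cfg$outDir, "detections.csv")
  writeDetections(det, paths$detections)
  manifest$counts$detections <- nrow(det)
  .logStage("detect: %d rows (%d missing)", nrow(det),
            sum(det$status == "missing"))

  met <- stage("metrics", metricsSeries(det, cfg$rois, cfg$intervalS))
  paths$metrics <- file.path(cfg$outDir, "metrics.csv")
  writeMetrics(met, paths$metrics)
  manifest$counts$metrics <- nrow(met)
  .logStage("metrics: %d rows (%d with defined speed)", nrow(met),
            sum(!is.na(met$speed_cm_s)))

  summ <- stage("summarize", summarizePeriods(met, cfg$sched))
  lowCover <- summ$n_valid_speed < 0.5 * pmax(summ$n_frames - 1, 1)
  if (any(lowCover))
    warning(sprintf("%d fish-periods have < 50%% valid-speed coverage",
                    sum(lowCover)))
  paths$summaries <- file.path(cfg$outDir, "period_summaries.csv")
  utils::write.csv(summ, paths$summaries, row.names = FALSE)
  manifest$counts$fish_periods <- nrow(summ)

  prof <- stage("profile", buildProfiles(summ))
  paths$profiles <- file.path(cfg$outDir, "profiles.csv")
  writeProfileTable(prof, paths$profiles)
  grp <- stage("group_summary", groupSummary(prof))
  paths$group_summary <- file.path(cfg$outDir, "group_summary.csv")
  utils::write.csv(grp, paths$group_summary, row.names = FALSE)
  manifest$counts$profiles <- nrow(prof)
  .logStage("profile: %d fish x %d measures", nrow(prof),
            length(profileMeasureNames()))

  hx <- stage("hexbin", {
    f <- det$status == "found"
    hexbin(det$cx[f], det$cy[f], circumradius = cfg$hexRadius)
  })
  paths$hexbin <- file.path(cfg$outDir, "hexbin.csv")
  utils::write.csv(hx, paths$hexbin, row.names = FALSE)

  st <- stage("stats", {
    tbl <- conditionTable(summ, cfg$statsMeasure,
                          grouping = cfg$statsGrouping, sched = cfg$sched)
    omnibus <- rbind(
      data.frame(method = "friedman",
                 statistic = unname(friedmanTest(tbl)$statistic),
                 p = friedmanTest(tbl)$p.value),
      data.frame(method = "rm_anova",
                 statistic = unname(rmAnova(tbl)$statistic),
                 p = rmAnova(tbl)$p.value)
    )
    list(omnibus = omnibus, pairwise = bonferroniPairwise(tbl))
  })
  paths$stats_omnibus <- file.path(cfg$outDir, "stats_omnibus.csv")
  utils::write.csv(st$omnibus, paths$stats_omnibus, row.names = FALSE)
  paths$stats_pairwise <- file.path(cfg$outDir, "stats_pairwise.csv")
  utils::write.csv(st$pairwise, paths$stats_pairwise, row.names = FALSE)
  .logStage("stats: omnibus + %d pairwise comparisons", nrow(st$pairwise))

  writeManifest()
  invisible(list(detections = det, metrics = met, summaries = summ,
                 profiles = prof, group_summary = grp, hexbin = hx,
                 stats = st, paths = paths))
}
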