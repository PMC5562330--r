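## Reproducible pipeline entry points over the package's modules, plus the
## run configuration they share. All outputs are plain text (TSV/JSON/YAML)
## except the stack itself (float32 TIFF); every output directory receives
## the exact configuration used, and files are written atomically (temp
## file + rename), so a failed run leaves no partial outputs.

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the detection/tracking pipeline
#' with its default. All values are validated; the configuration is
#' serialised (YAML) alongside every pipeline output.
#'
#' @param nBins number of intensity bins per frame (default 50).
#' @param clusterConnectivity 4 or 8 for intensity clusters (default 4:
#'   only edge-sharing voxels have a common border).
#' @param peakNeighborhood 4 or 8 for peak suppression (default 8).
#' @param dtMs frame interval in ms (default 5).
#' @param voxelEdgeNm voxel edge in nm (default 100).
#' @param periodicX wrap-around in the column dimension (default FALSE).
#' @param thresholdMv analysis-window voltage threshold, mV (default -50).
#' @param cycle 1-based action-potential cycle to analyse (default 1).
#' @param excludeFrame0Births exclude first-frame births from birth-time
#'   statistics (default TRUE).
#' @param complexCollisionRule "survivor" (default) or "either"; see
#'   \code{\link{summarizeLCRs}}.
#' @param birthTimeBinMs birth-time histogram bin width, ms (default 25).
#' @return a validated list of class \code{lcrConfig}.
#' @export
lcrConfig <- function(nBins = 50, clusterConnectivity = 4,
                      peakNeighborhood = 8, dtMs = 5, voxelEdgeNm = 100,
                      periodicX = FALSE, thresholdMv = -50, cycle = 1,
                      excludeFrame0Births = TRUE,
                      complexCollisionRule = "survivor",
                      birthTimeBinMs = 25) {
  stopifnot(nBins >= 1, clusterConnectivity %in% c(4, 8),
            peakNeighborhood %in% c(4, 8), dtMs > 0, voxelEdgeNm > 0,
            is.logical(periodicX), is.finite(thresholdMv), cycle >= 1,
            is.logical(excludeFrame0Births),
            complexCollisionRule %in% c("survivor", "either"),
            birthTimeBinMs > 0)
  structure(
    list(nBins = as.integer(nBins),
         clusterConnectivity = as.integer(clusterConnectivity),
         peakNeighborhood = as.integer(peakNeighborhood),
         dtMs = dtMs, voxelEdgeNm = voxelEdgeNm,
         periodicX = isTRUE(periodicX), thresholdMv = thresholdMv,
         cycle = as.integer(cycle),
         excludeFrame0Births = isTRUE(excludeFrame0Births),
         complexCollisionRule = complexCollisionRule,
         birthTimeBinMs = birthTimeBinMs),
    class = "lcrConfig")
}

#' @export
print.lcrConfig <- function(x, ...) {
  cat("lcrConfig:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#' @param path YAML file with a subset of \code{\link{lcrConfig}} fields.
#' @return an \code{lcrConfig}.
#' @export
readLcrConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(lcrConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(lcrConfig, vals)
}

#' Write a run configuration as YAML
#' @param config an \code{\link{lcrConfig}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeLcrConfig <- function(config, path) {
  stopifnot(inherits(config, "lcrConfig"))
  .writeAtomic(path, function(p) yaml::write_yaml(unclass(config), p))
}

.writeAtomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  ok <- FALSE
  tryCatch({ writer(tmp); ok <- TRUE },
           finally = if (!ok && file.exists(tmp)) unlink(tmp))
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

.writeTsv <- function(df, path) {
  .writeAtomic(path, function(p)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE))
}

.writeJson <- function(x, path) {
  .writeAtomic(path, function(p)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE))
}

#' Subset the frames of a stack
#' @param stack a \code{\link{FrameStack}}.
#' @param startFrame,endFrame 1-based inclusive frame range.
#' @return a \code{FrameStack} with the selected frames.
#' @export
subsetFrames <- function(stack, startFrame, endFrame) {
  stopifnot(is(stack, "FrameStack"))
  nf <- dim(stack@data)[3]
  startFrame <- as.integer(startFrame); endFrame <- as.integer(endFrame)
  if (startFrame < 1L || endFrame > nf || startFrame > endFrame)
    stop("frame range out of bounds")
  FrameStack(stack@data[, , startFrame:endFrame, drop = FALSE],
             dtMs = stack@dtMs, voxelEdgeNm = stack@voxelEdgeNm,
             periodicX = stack@periodicX)
}

## Build an lcrScenario from a YAML description (fields of lcrScenario,
## with events given as lists of gaussianEvent arguments).
.scenarioFromYaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$events)) vals$events <- list()
  vals$events <- lapply(vals$events, function(e) do.call(gaussianEvent, e))
  do.call(lcrScenario, vals)
}

#' Render a scenario and write stack plus ground truth
#'
#' Renders an \code{\link{lcrScenario}} (or a YAML description of one, or
#' one of the named builders \code{"merge"}, \code{"split"},
#' \code{"population"}) and writes \code{stack.tif} (float32 multi-page
#' TIFF), \code{ground_truth.json} and \code{scenario.yaml} into
#' \code{outDir}.
#'
#' @param scenario an \code{lcrScenario}, a YAML file path, or one of
#'   "merge", "split", "population".
#' @param outDir output directory (created if needed).
#' @param seed optional integer overriding the scenario's seed.
#' @return invisibly, the list from \code{\link{renderScenario}}.
#' @export
runSynth <- function(scenario, outDir, seed = NULL) {
  if (is.character(scenario) && length(scenario) == 1L) {
    scenario <- switch(scenario,
      merge = makeMergeScenario(),
      split = makeSplitScenario(),
      population = makePopulationScenario(
        seed = if (is.null(seed)) 1L else seed),
      .scenarioFromYaml(scenario))
  }
  stopifnot(inherits(scenario, "lcrScenario"))
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- renderScenario(scenario)
  .writeAtomic(file.path(outDir, "stack.tif"),
               function(p) writeStack(out$stack, p))
  truth <- out$truth
  truth$footprints <- lapply(truth$footprints, function(fp)
    lapply(fp, as.integer))
  .writeJson(truth, file.path(outDir, "ground_truth.json"))
  scnOut <- unclass(scenario)
  scnOut$events <- lapply(scenario$events, unclass)
  .writeAtomic(file.path(outDir, "scenario.yaml"),
               function(p) yaml::write_yaml(scnOut, p))
  invisible(out)
}

#' Detect LCR images in a stack file and write the per-frame image table
#'
#' @param stackPath multi-page TIFF or delimited-text stack.
#' @param outDir output directory; receives \code{images.tsv} and
#'   \code{config.yaml}.
#' @param config an \code{\link{lcrConfig}}.
#' @return invisibly, the \code{\link{LCRImageSet}}.
#' @export
runDetect <- function(stackPath, outDir, config = lcrConfig()) {
  stack <- loadStack(stackPath, dtMs = config$dtMs,
                     voxelEdgeNm = config$voxelEdgeNm,
                     periodicX = config$periodicX)
  imageSet <- detectLCRImages(stack, config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeTsv(imageTable(imageSet), file.path(outDir, "images.tsv"))
  writeLcrConfig(config, file.path(outDir, "config.yaml"))
  invisible(imageSet)
}

#' Run the full detection/tracking/statistics pipeline on a stack file
#'
#' Loads the stack, optionally restricts it to the diastolic analysis
#' window selected from a voltage trace (MDP to the threshold crossing),
#' detects and tracks LCRs, computes per-LCR metrics and the ensemble
#' summary, and writes \code{images.tsv}, \code{tracks.tsv},
#' \code{events.tsv}, \code{metrics.tsv}, \code{summary.json},
#' \code{config.yaml} and (if windowed) \code{window.json} into
#' \code{outDir}. Everything is computed before anything is written, and
#' each file is written atomically, so a failing run leaves no partial
#' outputs. Reruns on identical inputs produce byte-identical files.
#'
#' @param stackPath multi-page TIFF or delimited-text stack.
#' @param outDir output directory (created if needed).
#' @param config an \code{\link{lcrConfig}}.
#' @param voltagePath optional two-column (t_ms, vm_mV) text file.
#' @return invisibly, a list with the trackSet, metrics, summary and
#'   (possibly NULL) window.
#' @export
runTrack <- function(stackPath, outDir, config = lcrConfig(),
                     voltagePath = NULL) {
  stack <- loadStack(stackPath, dtMs = config$dtMs,
                     voxelEdgeNm = config$voxelEdgeNm,
                     periodicX = config$periodicX)
  win <- NULL
  if (!is.null(voltagePath)) {
    trace <- loadVoltage(voltagePath)
    win <- selectWindow(trace, thresholdMv = config$thresholdMv,
                        stackDtMs = config$dtMs,
                        nFramesStack = dim(stack@data)[3],
                        cycle = config$cycle)
    stack <- subsetFrames(stack, win@startFrame, win@endFrame)
  }
  trackSet <- trackLCRs(stack, config)
  metrics <- lcrMetrics(trackSet)
  summ <- summarizeLCRs(metrics, eventLog(trackSet),
                        excludeFrame0Births = config$excludeFrame0Births,
                        complexCollisionRule = config$complexCollisionRule,
                        birthTimeBinMs = config$birthTimeBinMs)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeTsv(imageTable(trackSet), file.path(outDir, "images.tsv"))
  .writeTsv(trackTable(trackSet), file.path(outDir, "tracks.tsv"))
  .writeTsv(eventLog(trackSet), file.path(outDir, "events.tsv"))
  .writeTsv(metrics, file.path(outDir, "metrics.tsv"))
  .writeJson(list(summary = summ$summary,
                  totalComplexCollisions = summ$totalComplexCollisions),
             file.path(outDir, "summary.json"))
  if (!is.null(win))
    .writeJson(list(startFrame = win@startFrame, endFrame = win@endFrame,
                    tMdpMs = win@tMdpMs, tThresholdMs = win@tThresholdMs,
                    thresholdMv = win@thresholdMv),
               file.path(outDir, "window.json"))
  writeLcrConfig(config, file.path(outDir, "config.yaml"))
  invisible(list(trackSet = trackSet, metrics = metrics, summary = summ,
                 window = win))
}

#' Summarise a metrics table file
#'
#' Reads a \code{metrics.tsv} written by \code{\link{runTrack}}, recomputes
#' the ensemble summary and histograms, and writes \code{summary.json}
#' plus per-class histogram tables
#' (\code{hist_birth_time_<class>.tsv}, \code{hist_signal_mass_<class>.tsv}).
#'
#' @param metricsPath metrics TSV file.
#' @param outDir output directory (created if needed).
#' @param config an \code{\link{lcrConfig}}.
#' @return invisibly, the summary list.
#' @export
runStats <- function(metricsPath, outDir, config = lcrConfig()) {
  metrics <- utils::read.delim(metricsPath, stringsAsFactors = FALSE)
  summ <- summarizeLCRs(metrics,
                        excludeFrame0Births = config$excludeFrame0Births,
                        complexCollisionRule = config$complexCollisionRule,
                        birthTimeBinMs = config$birthTimeBinMs)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeJson(list(summary = summ$summary,
                  totalComplexCollisions = summ$totalComplexCollisions),
             file.path(outDir, "summary.json"))
  for (cl in names(summ$histograms)) {
    .writeTsv(summ$histograms[[cl]]$birthTime,
              file.path(outDir, sprintf("hist_birth_time_%s.tsv", cl)))
    .writeTsv(summ$histograms[[cl]]$signalMass,
              file.path(outDir, sprintf("hist_signal_mass_%s.tsv", cl)))
  }
  writeLcrConfig(config, file.path(outDir, "config.yaml"))
  invisible(summ)
}

#' Select and report the diastolic analysis window of a voltage trace
#'
#' @param voltagePath two-column (t_ms, vm_mV) text file.
#' @param outDir output directory; receives \code{window.json}.
#' @param config an \code{\link{lcrConfig}}.
#' @param nFramesStack number of frames of the stack the window is for
#'   (Inf to skip the bounds check).
#' @param stackT0Ms time of the stack's first frame on the trace clock.
#' @return invisibly, the \code{\link{AnalysisWindow}}.
#' @export
runWindow <- function(voltagePath, outDir, config = lcrConfig(),
                      nFramesStack = Inf, stackT0Ms = 0) {
  trace <- loadVoltage(voltagePath)
  win <- selectWindow(trace, thresholdMv = config$thresholdMv,
                      stackDtMs = config$dtMs, stackT0Ms = stackT0Ms,
                      nFramesStack = nFramesStack, cycle = config$cycle)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeJson(list(startFrame = win@startFrame, endFrame = win@endFrame,
                  tMdpMs = win@tMdpMs, tThresholdMs = win@tThresholdMs,
                  thresholdMv = win@thresholdMv),
             file.path(outDir, "window.json"))
  writeLcrConfig(config, file.path(outDir, "config.yaml"))
  invisible(win)
}
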