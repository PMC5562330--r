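## Per-LCR statistics and ensemble summaries.

#' Signal mass of a dynamic LCR
#'
#' The sum of the signal masses (nmol) of all the track's member
#' single-frame images, multiplied by the frame interval: nmol*ms.
#'
#' @param trackSet an \code{\link{LCRTrackSet}}.
#' @param lcrId track id.
#' @param dtMs frame interval in ms (default: the interval recorded at
#'   detection).
#' @return signal mass in nmol*ms.
#' @export
lcrSignalMass <- function(trackSet, lcrId, dtMs = NULL) {
  stopifnot(is(trackSet, "LCRTrackSet"))
  if (is.null(dtMs)) dtMs <- trackSet@imageSet@params$dtMs
  gids <- trackImages(trackSet, lcrId)
  sum(trackSet@imageSet@images$signalMassNmol[gids]) * dtMs
}

#' Path area of a dynamic LCR
#'
#' The area of the union of all voxels the LCR ever occupied (not the sum
#' over frames: a static release has the same path area regardless of how
#' long it lives), in square micrometres.
#'
#' @param trackSet an \code{\link{LCRTrackSet}}.
#' @param lcrId track id.
#' @param voxelEdgeNm voxel edge in nm (default: recorded at detection).
#' @return path area in um^2.
#' @export
lcrPathArea <- function(trackSet, lcrId, voxelEdgeNm = NULL) {
  stopifnot(is(trackSet, "LCRTrackSet"))
  if (is.null(voxelEdgeNm)) voxelEdgeNm <- trackSet@imageSet@params$voxelEdgeNm
  gids <- trackImages(trackSet, lcrId)
  vox <- unique(unlist(trackSet@imageSet@voxels[gids], use.names = FALSE))
  length(vox) * (voxelEdgeNm / 1000)^2
}

#' Maximum amplitude of a dynamic LCR
#'
#' The highest [Ca] (uM) reached in any voxel of any member image during
#' the track's lifetime.
#'
#' @param trackSet an \code{\link{LCRTrackSet}}.
#' @param lcrId track id.
#' @return maximum amplitude in uM.
#' @export
lcrMaxAmplitude <- function(trackSet, lcrId) {
  stopifnot(is(trackSet, "LCRTrackSet"))
  gids <- trackImages(trackSet, lcrId)
  max(trackSet@imageSet@images$maxAmplitudeUM[gids])
}

#' Duration and birth time of a dynamic LCR
#'
#' Duration counts frames inclusively: a track alive in frames b..d lives
#' \code{(d - b + 1) * dtMs} ms, so a single-frame LCR has the duration of
#' one frame interval, not zero. Birth time is counted from the start of
#' the analysis window (frame \code{windowStartFrame} = time 0).
#'
#' @param trackSet an \code{\link{LCRTrackSet}}.
#' @param lcrId track id.
#' @param dtMs frame interval in ms (default: recorded at detection).
#' @param windowStartFrame 1-based frame index of the window start
#'   (default 1).
#' @return list with \code{durationMs} and \code{birthTimeMs}.
#' @export
lcrDurationBirth <- function(trackSet, lcrId, dtMs = NULL,
                             windowStartFrame = 1) {
  stopifnot(is(trackSet, "LCRTrackSet"))
  if (is.null(dtMs)) dtMs <- trackSet@imageSet@params$dtMs
  tr <- trackSet@tracks
  i <- match(as.integer(lcrId), tr$lcrId)
  if (is.na(i)) stop("unknown lcrId")
  lastAlive <- if (is.na(tr$deathFrame[i])) tr$lastFrame[i] else
    tr$deathFrame[i]
  list(durationMs = (lastAlive - tr$birthFrame[i] + 1) * dtMs,
       birthTimeMs = (tr$birthFrame[i] - windowStartFrame) * dtMs)
}

#' Per-LCR metrics table
#'
#' Computes, for every dynamic LCR of a track set, the statistics used in
#' the ensemble summaries: class, signal mass (nmol*ms), path area (um^2),
#' maximum amplitude (uM), duration (ms), birth time (ms), thread and
#' separation counts and termination type.
#'
#' @param trackSet an \code{\link{LCRTrackSet}}.
#' @param windowStartFrame 1-based frame index from which birth times are
#'   counted (default 1, the first frame of the analysed stack).
#' @return data.frame with one row per LCR.
#' @examples
#' scn <- makePopulationScenario(nEvents = 4, height = 32, width = 32,
#'                               nFrames = 40, seed = 1)
#' ts <- trackLCRs(renderScenario(scn)$stack)
#' lcrMetrics(ts)
#' @export
lcrMetrics <- function(trackSet, windowStartFrame = 1) {
  stopifnot(is(trackSet, "LCRTrackSet"))
  tr <- trackSet@tracks
  p <- trackSet@imageSet@params
  im <- trackSet@imageSet@images
  n <- nrow(tr)
  sm <- pa <- ma <- du <- bt <- numeric(n)
  for (k in seq_len(n)) {
    id <- tr$lcrId[k]
    gids <- trackSet@trackImages[[as.character(id)]]
    sm[k] <- sum(im$signalMassNmol[gids]) * p$dtMs
    vox <- unique(unlist(trackSet@imageSet@voxels[gids], use.names = FALSE))
    pa[k] <- length(vox) * (p$voxelEdgeNm / 1000)^2
    ma[k] <- max(im$maxAmplitudeUM[gids])
    lastAlive <- if (is.na(tr$deathFrame[k])) tr$lastFrame[k] else
      tr$deathFrame[k]
    du[k] <- (lastAlive - tr$birthFrame[k] + 1) * p$dtMs
    bt[k] <- (tr$birthFrame[k] - windowStartFrame) * p$dtMs
  }
  out <- data.frame(
    lcrId = tr$lcrId, class = tr$class,
    signalMassNmolMs = sm, pathAreaUm2 = pa, maxAmplitudeUM = ma,
    durationMs = du, birthTimeMs = bt,
    birthFrame = tr$birthFrame,
    nThreads = tr$nThreads, nSeparations = tr$nSeparations,
    termination = tr$termination)
  if (n == 0L) out <- out[0, , drop = FALSE]
  out
}

.logDecadeBreaks <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0L) return(10^(0:1))
  lo <- floor(log10(min(x))); hi <- ceiling(log10(max(x)))
  if (hi <= lo) hi <- lo + 1L
  10^seq(lo, hi)
}

## counts per [breaks[i], breaks[i+1]) bin, last bin right-closed; quiet
## on empty input
.binCounts <- function(x, breaks) {
  nb <- length(breaks) - 1L
  if (length(x) == 0L) return(integer(nb))
  x <- x[x >= breaks[1] & x <= breaks[nb + 1L]]
  if (length(x) == 0L) return(integer(nb))
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  tabulate(idx, nbins = nb)
}

.classHistograms <- function(metrics, btKeep, birthTimeBinMs,
                             signalMassBreaks) {
  classSel <- list(all = rep(TRUE, nrow(metrics)),
                   complex = metrics$class == "complex",
                   simple = metrics$class == "simple")
  lapply(classSel, function(sel) {
    m <- metrics[sel, , drop = FALSE]
    bt <- metrics$birthTimeMs[sel & btKeep]
    btBreaks <- seq(0, max(c(bt, 0)) + birthTimeBinMs, by = birthTimeBinMs)
    smBreaks <- if (is.null(signalMassBreaks))
      .logDecadeBreaks(m$signalMassNmolMs) else signalMassBreaks
    list(
      birthTime = data.frame(binStartMs = utils::head(btBreaks, -1),
                             binEndMs = utils::tail(btBreaks, -1),
                             count = .binCounts(bt, btBreaks)),
      signalMass = data.frame(binStartNmolMs = utils::head(smBreaks, -1),
                              binEndNmolMs = utils::tail(smBreaks, -1),
                              count = .binCounts(m$signalMassNmolMs,
                                                 smBreaks)))
  })
}

#' Ensemble summary of LCR metrics
#'
#' Aggregates a per-LCR metrics table into the standard summary: for each
#' class (all / complex / simple) the LCR count, total signal mass, signal
#' mass per LCR, average path area, average maximum amplitude, average
#' duration and average birth time; plus the complex-collision count and
#' histogram data for birth times and signal masses. Counts and total
#' masses are additive by construction: all = simple + complex.
#'
#' Births in the very first window frame are pre-existing releases rather
#' than genuine births; with \code{excludeFrame0Births = TRUE} (default)
#' they are excluded from the birth-time averages and histograms (only;
#' they still count everywhere else).
#'
#' @param metrics data.frame from \code{\link{lcrMetrics}}.
#' @param events event log from \code{\link{eventLog}}, used to count
#'   complex collisions; may be NULL.
#' @param excludeFrame0Births drop first-frame births from birth-time
#'   statistics (default TRUE).
#' @param windowStartFrame 1-based frame index of the window start.
#' @param complexCollisionRule count a collision as complex when the
#'   surviving LCR is complex (\code{"survivor"}, default) or when either
#'   participant is (\code{"either"}).
#' @param birthTimeBinMs histogram bin width for birth times (default 25).
#' @param signalMassBreaks explicit histogram breaks for signal mass, or
#'   NULL for log-spaced decades.
#' @return list with \code{summary} (data.frame, rows all/complex/simple),
#'   \code{totalComplexCollisions} and \code{histograms}.
#' @export
summarizeLCRs <- function(metrics, events = NULL,
                          excludeFrame0Births = TRUE,
                          windowStartFrame = 1,
                          complexCollisionRule = c("survivor", "either"),
                          birthTimeBinMs = 25,
                          signalMassBreaks = NULL) {
  complexCollisionRule <- match.arg(complexCollisionRule)
  stopifnot(is.data.frame(metrics))
  classes <- list(all = rep(TRUE, nrow(metrics)),
                  complex = metrics$class == "complex",
                  simple = metrics$class == "simple")
  btKeep <- if (excludeFrame0Births && "birthFrame" %in% names(metrics))
    metrics$birthFrame != windowStartFrame else rep(TRUE, nrow(metrics))
  rows <- lapply(names(classes), function(cl) {
    m <- metrics[classes[[cl]], , drop = FALSE]
    bt <- metrics$birthTimeMs[classes[[cl]] & btKeep]
    n <- nrow(m)
    data.frame(
      class = cl,
      count = n,
      totalSignalMassNmolMs = sum(m$signalMassNmolMs),
      signalMassPerLcrNmolMs = if (n > 0) sum(m$signalMassNmolMs) / n else 0,
      avgPathAreaUm2 = if (n > 0) mean(m$pathAreaUm2) else 0,
      avgMaxAmplitudeUM = if (n > 0) mean(m$maxAmplitudeUM) else 0,
      avgDurationMs = if (n > 0) mean(m$durationMs) else 0,
      avgBirthTimeMs = if (length(bt) > 0) mean(bt) else 0)
  })
  summary <- do.call(rbind, rows)

  totalComplexCollisions <- 0L
  if (!is.null(events) && nrow(events) > 0L) {
    coll <- events[events$kind == "death_collision", , drop = FALSE]
    if (nrow(coll) > 0L) {
      cls <- metrics$class[match(coll$otherLcrId, metrics$lcrId)]
      hit <- cls == "complex"
      if (complexCollisionRule == "either") {
        clsLoser <- metrics$class[match(coll$lcrId, metrics$lcrId)]
        hit <- hit | clsLoser == "complex"
      }
      totalComplexCollisions <- sum(hit, na.rm = TRUE)
    }
  }

  list(summary = summary,
       totalComplexCollisions = totalComplexCollisions,
       histograms = .classHistograms(metrics, btKeep, birthTimeBinMs,
                                     signalMassBreaks))
}
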