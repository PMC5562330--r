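## Synthetic frame-stack generator: scripted isotropic Gaussian release
## events over an exponentially decaying uniform background, with exact
## ground truth. The blobs emulate the statistical appearance of local
## releases (births, drifts, merges, splits) for validating the detector
## and tracker; they are not a physical diffusion model.

#' Script one Gaussian release event
#'
#' Describes one isotropic Gaussian blob alive from \code{birthFrame} to
#' \code{endFrame}. Centre, amplitude and width are linearly interpolated
#' between their start and end values over the event's life, so a static
#' event needs only the start values.
#'
#' @param id event id (integer, unique within a scenario).
#' @param birthFrame,endFrame 1-based first and last live frame.
#' @param row,col centre at birth (may be fractional voxels).
#' @param amplitude peak amplitude above background at birth, uM (> 0).
#' @param sigma Gaussian width at birth, voxels (> 0).
#' @param rowEnd,colEnd,amplitudeEnd,sigmaEnd values at \code{endFrame}
#'   (default: constant trajectories).
#' @return an object of class \code{lcrEvent}.
#' @export
gaussianEvent <- function(id, birthFrame, endFrame, row, col,
                          amplitude, sigma,
                          rowEnd = row, colEnd = col,
                          amplitudeEnd = amplitude, sigmaEnd = sigma) {
  stopifnot(endFrame >= birthFrame, amplitude > 0, amplitudeEnd > 0,
            sigma > 0, sigmaEnd > 0)
  nLive <- endFrame - birthFrame + 1L
  lerp <- function(a, b) if (nLive == 1L) a else
    seq(a, b, length.out = nLive)
  structure(
    list(id = as.integer(id),
         birthFrame = as.integer(birthFrame),
         endFrame = as.integer(endFrame),
         row = lerp(row, rowEnd), col = lerp(col, colEnd),
         amplitude = lerp(amplitude, amplitudeEnd),
         sigma = lerp(sigma, sigmaEnd)),
    class = "lcrEvent")
}

#' Assemble a synthetic scenario
#'
#' A scenario fixes the grid, the number of frames, the calibration, the
#' uniform background time course
#' \code{B(t) = bRest + (b0 - bRest) * exp(-t / tau)} (a decaying global
#' calcium transient over a resting level), the scripted events and the
#' additive Gaussian noise level. Noise defaults to zero, matching
#' noise-free simulation output; rendering is reproducible given
#' \code{seed}.
#'
#' @param height,width grid size in voxels.
#' @param nFrames number of frames.
#' @param dtMs frame interval in ms (default 5).
#' @param voxelEdgeNm voxel edge in nm (default 100).
#' @param bRestUM resting background, uM (default 0.1, i.e. 100 nM).
#' @param b0UM background at frame 1, uM (default 0.6; decaying transient).
#' @param tauMs background decay time constant, ms (default 150).
#' @param events list of \code{\link{gaussianEvent}} scripts.
#' @param noiseSdUM additive Gaussian noise sd, uM (default 0).
#' @param seed integer seed used by \code{\link{renderScenario}}.
#' @param periodicX wrap-around in the column dimension (default FALSE).
#' @param meta optional list of scheduling metadata (e.g. expected merges
#'   or splits) carried into the ground truth.
#' @return an object of class \code{lcrScenario}.
#' @export
lcrScenario <- function(height, width, nFrames, dtMs = 5, voxelEdgeNm = 100,
                        bRestUM = 0.1, b0UM = 0.6, tauMs = 150,
                        events = list(), noiseSdUM = 0, seed = 1L,
                        periodicX = FALSE, meta = list()) {
  stopifnot(height >= 1, width >= 1, nFrames >= 1,
            bRestUM > 0, b0UM > 0, tauMs > 0, noiseSdUM >= 0)
  for (ev in events) {
    stopifnot(inherits(ev, "lcrEvent"))
    if (ev$endFrame > nFrames)
      stop("event ", ev$id, " outlives the scenario")
    if (any(ev$row < 1 | ev$row > height))
      stop("event ", ev$id, " leaves the grid (rows)")
    if (!periodicX && any(ev$col < 1 | ev$col > width))
      stop("event ", ev$id, " leaves the grid (columns)")
  }
  ids <- vapply(events, `[[`, 1L, "id")
  if (anyDuplicated(ids) > 0L) stop("event ids must be unique")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         nFrames = as.integer(nFrames), dtMs = dtMs,
         voxelEdgeNm = voxelEdgeNm, bRestUM = bRestUM, b0UM = b0UM,
         tauMs = tauMs, events = events, noiseSdUM = noiseSdUM,
         seed = as.integer(seed), periodicX = isTRUE(periodicX),
         meta = meta),
    class = "lcrScenario")
}

#' @export
print.lcrScenario <- function(x, ...) {
  cat(sprintf("lcrScenario: %d x %d voxels, %d frames, %d event(s)\n",
              x$height, x$width, x$nFrames, length(x$events)))
  cat(sprintf("  background %g -> %g uM (tau %g ms), noise sd %g uM, seed %d\n",
              x$b0UM, x$bRestUM, x$tauMs, x$noiseSdUM, x$seed))
  invisible(x)
}

## Gaussian contribution of one event at its live-frame index k, on the
## full grid (with optional periodic wrap of the column distance).
.eventField <- function(ev, k, height, width, periodicX) {
  dr <- outer(seq_len(height) - ev$row[k], rep(1, width))
  dcRow <- seq_len(width) - ev$col[k]
  if (periodicX)
    dcRow <- ((dcRow + width / 2) %% width) - width / 2
  dc <- outer(rep(1, height), dcRow)
  ev$amplitude[k] * exp(-(dr^2 + dc^2) / (2 * ev$sigma[k]^2))
}

#' Render a scenario into a frame stack with ground truth
#'
#' Each frame is the uniform background at that time plus the Gaussian
#' fields of all live events, plus optional Gaussian noise (clamped at 0).
#' Rendering is deterministic given the scenario's seed.
#'
#' The ground truth records, per event, its birth/end frames, its scripted
#' peak amplitude (above background) and the rendered per-frame footprint
#' (voxels where the event's own field exceeds
#' \code{footprintFraction * amplitude}), plus any scheduling metadata the
#' scenario carries.
#'
#' @param scenario an \code{\link{lcrScenario}}.
#' @param footprintFraction fraction of the momentary amplitude delimiting
#'   the ground-truth footprint (default 0.5).
#' @return list with \code{stack} (a \code{\link{FrameStack}}) and
#'   \code{truth} (list: \code{events} data.frame, \code{footprints},
#'   \code{meta}).
#' @examples
#' scn <- lcrScenario(16, 16, 5, events = list(
#'   gaussianEvent(1, 2, 4, row = 8, col = 8, amplitude = 3, sigma = 2)))
#' out <- renderScenario(scn)
#' out$truth$events
#' @export
renderScenario <- function(scenario, footprintFraction = 0.5) {
  stopifnot(inherits(scenario, "lcrScenario"))
  h <- scenario$height; w <- scenario$width; nf <- scenario$nFrames
  tMs <- (seq_len(nf) - 1) * scenario$dtMs
  bg <- scenario$bRestUM +
    (scenario$b0UM - scenario$bRestUM) * exp(-tMs / scenario$tauMs)
  data <- array(0, c(h, w, nf))
  footprints <- lapply(scenario$events, function(ev)
    vector("list", ev$endFrame - ev$birthFrame + 1L))
  names(footprints) <- vapply(scenario$events, function(ev)
    as.character(ev$id), "")
  set.seed(scenario$seed)
  for (f in seq_len(nf)) {
    fr <- matrix(bg[f], h, w)
    for (j in seq_along(scenario$events)) {
      ev <- scenario$events[[j]]
      if (f < ev$birthFrame || f > ev$endFrame) next
      k <- f - ev$birthFrame + 1L
      field <- .eventField(ev, k, h, w, scenario$periodicX)
      fr <- fr + field
      footprints[[j]][[k]] <-
        which(field >= footprintFraction * ev$amplitude[k])
    }
    if (scenario$noiseSdUM > 0)
      fr <- pmax(fr + matrix(stats::rnorm(h * w, sd = scenario$noiseSdUM),
                             h, w), 0)
    data[, , f] <- fr
  }
  truthEvents <- if (length(scenario$events) > 0L) data.frame(
    eventId = vapply(scenario$events, `[[`, 1L, "id"),
    birthFrame = vapply(scenario$events, `[[`, 1L, "birthFrame"),
    endFrame = vapply(scenario$events, `[[`, 1L, "endFrame"),
    peakAmplitudeUM = vapply(scenario$events, function(ev)
      max(ev$amplitude), 1.0),
    peakTotalUM = vapply(scenario$events, function(ev)
      max(ev$amplitude + bg[ev$birthFrame:ev$endFrame]), 1.0))
  else data.frame(eventId = integer(), birthFrame = integer(),
                  endFrame = integer(), peakAmplitudeUM = numeric(),
                  peakTotalUM = numeric())
  list(stack = FrameStack(data, dtMs = scenario$dtMs,
                          voxelEdgeNm = scenario$voxelEdgeNm,
                          periodicX = scenario$periodicX),
       truth = list(events = truthEvents, footprints = footprints,
                    background = data.frame(frame = seq_len(nf),
                                            tMs = tMs, bUM = bg),
                    meta = scenario$meta))
}

#' Scenario: two releases converging into a collision
#'
#' Two Gaussian events of unequal amplitude on one row; the smaller one
#' drifts toward the static larger one until their supra-mean footprints
#' fuse into a single image, which the tracker must resolve as a collision
#' won by the track with the larger previous-image signal mass.
#'
#' @param height,width,nFrames grid and length (defaults 32 x 48 x 25).
#' @param amplitudes amplitudes of the static (larger) and moving
#'   (smaller) event, uM.
#' @param sigma common Gaussian width, voxels.
#' @param seed scenario seed.
#' @return an \code{\link{lcrScenario}} whose \code{meta} names the
#'   expected surviving event.
#' @export
makeMergeScenario <- function(height = 32, width = 48, nFrames = 25,
                              amplitudes = c(3, 2), sigma = 1.5, seed = 1L) {
  stopifnot(length(amplitudes) == 2L, amplitudes[1] > amplitudes[2])
  r <- height / 2
  ev1 <- gaussianEvent(1, 1, nFrames, row = r, col = 16,
                       amplitude = amplitudes[1], sigma = sigma)
  ev2 <- gaussianEvent(2, 1, nFrames, row = r, col = 36,
                       amplitude = amplitudes[2], sigma = sigma,
                       colEnd = 22)
  lcrScenario(height, width, nFrames, events = list(ev1, ev2), seed = seed,
              meta = list(kind = "merge", expectedSurvivorEvent = 1L,
                          expectedLoserEvent = 2L))
}

#' Scenario: one release separating into two threads
#'
#' Two Gaussian components start at a common centre (one connected image)
#' and drift apart until the supra-mean footprint disconnects: the tracker
#' must record one separation, after which the single LCR continues with
#' two threads. The components end at different frames, so the track must
#' stay alive after the first thread fades and die only when the second
#' does.
#'
#' @param height,width,nFrames grid and length (defaults 32 x 56 x 30).
#' @param amplitudes amplitudes of the two components, uM.
#' @param sigma common Gaussian width, voxels.
#' @param seed scenario seed.
#' @return an \code{\link{lcrScenario}} with split metadata.
#' @export
makeSplitScenario <- function(height = 32, width = 56, nFrames = 30,
                              amplitudes = c(2.5, 2), sigma = 1.5,
                              seed = 1L) {
  r <- height / 2
  endA <- as.integer(round(nFrames * 2 / 3))
  endB <- nFrames - 2L
  evA <- gaussianEvent(1, 1, endA, row = r, col = 26,
                       amplitude = amplitudes[1], sigma = sigma,
                       colEnd = 14)
  evB <- gaussianEvent(2, 1, endB, row = r, col = 26,
                       amplitude = amplitudes[2], sigma = sigma,
                       colEnd = 40)
  lcrScenario(height, width, nFrames, events = list(evA, evB), seed = seed,
              meta = list(kind = "split", componentEvents = c(1L, 2L),
                          firstThreadEndsFrame = endA,
                          lastThreadEndsFrame = endB))
}

#' Scenario: a population of isolated releases with exact ground truth
#'
#' Places \code{nEvents} static Gaussian events on a regular grid (spaced
#' so that no two supra-mean footprints can touch), with seeded random
#' amplitudes, widths, birth frames and durations. With zero noise every
#' scripted event must be recovered by the detector and tracker with its
#' exact birth frame, as a simple single-thread LCR.
#'
#' @param nEvents number of events (default 30).
#' @param height,width,nFrames grid and length (defaults 64 x 64 x 200).
#' @param amplitudeRange,sigmaRange,durationRangeFrames uniform sampling
#'   ranges for amplitude (uM), width (voxels) and live span (frames).
#' @param noiseSdUM additive noise sd, uM (default 0).
#' @param seed scenario seed (drives all sampling).
#' @return an \code{\link{lcrScenario}}.
#' @export
makePopulationScenario <- function(nEvents = 30, height = 64, width = 64,
                                   nFrames = 200,
                                   amplitudeRange = c(1.5, 4),
                                   sigmaRange = c(0.9, 1.2),
                                   durationRangeFrames = c(20, 40),
                                   noiseSdUM = 0, seed = 1L) {
  nr <- ceiling(sqrt(nEvents))
  nc <- ceiling(nEvents / nr)
  ## events must be born after frame 1 and fade before the last frame;
  ## truncate the duration range so any sampled event fits the stack
  durationRangeFrames <- pmin(as.integer(durationRangeFrames), nFrames - 4L)
  stopifnot(durationRangeFrames[1] >= 1L)
  rows <- (seq_len(nr) - 0.5) * height / nr
  cols <- (seq_len(nc) - 0.5) * width / nc
  centres <- expand.grid(row = rows, col = cols)[seq_len(nEvents), ]
  set.seed(seed)
  amp <- stats::runif(nEvents, amplitudeRange[1], amplitudeRange[2])
  sig <- stats::runif(nEvents, sigmaRange[1], sigmaRange[2])
  dur <- sample(seq(durationRangeFrames[1], durationRangeFrames[2]),
                nEvents, replace = TRUE)
  birth <- vapply(dur, function(d)
    sample(seq(2L, nFrames - d - 1L), 1L), 1L)
  events <- lapply(seq_len(nEvents), function(i)
    gaussianEvent(i, birth[i], birth[i] + dur[i] - 1L,
                  row = centres$row[i], col = centres$col[i],
                  amplitude = amp[i], sigma = sig[i]))
  lcrScenario(height, width, nFrames, events = events,
              noiseSdUM = noiseSdUM, seed = seed,
              meta = list(kind = "population", nEvents = nEvents))
}
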