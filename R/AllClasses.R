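#' @import methods
NULL

#' FrameStack: a calibrated time series of submembrane [Ca] frames
#'
#' The sole required input of the LCR pipeline: an ordered series of 2D
#' matrices of instantaneous free calcium concentration (in micromolar, uM)
#' in the voxel layer directly under the cell membrane, with an explicit
#' frame interval and voxel edge length. Stored internally as a numeric
#' array of dimension height x width x frames.
#'
#' Conventions used everywhere downstream: rows, columns and frames are
#' 1-based; row 1 is the top of the frame; the time of frame k is
#' \code{(k - 1) * dtMs(x)} milliseconds relative to the start of the stack.
#' Units are fixed (uM, ms, nm) and never auto-detected.
#'
#' @slot data numeric array, height x width x nFrames, finite and >= 0 (uM).
#' @slot dtMs frame interval in milliseconds (> 0).
#' @slot voxelEdgeNm voxel edge length in nanometres (> 0).
#' @slot periodicX logical; if TRUE the column dimension wraps around
#'   (toroidal cell perimeter); affects cluster and peak neighbourhoods.
#'
#' @examples
#' fs <- FrameStack(array(0.1, c(4, 4, 3)))
#' nFrames(fs)
#' @export
setClass("FrameStack",
  representation(
    data = "array",
    dtMs = "numeric",
    voxelEdgeNm = "numeric",
    periodicX = "logical"
  )
)

setValidity("FrameStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3D array (height x width x frames)")
  if (dim(d)[1] < 1L || dim(d)[2] < 1L || dim(d)[3] < 1L)
    return("stack must contain at least one 1x1 frame")
  if (anyNA(d) || any(!is.finite(d)))
    return("all [Ca] values must be finite")
  if (any(d < 0))
    return("[Ca] values must be >= 0 uM")
  if (length(object@dtMs) != 1L || !is.finite(object@dtMs) || object@dtMs <= 0)
    return("dtMs must be a single positive number")
  if (length(object@voxelEdgeNm) != 1L || !is.finite(object@voxelEdgeNm) ||
      object@voxelEdgeNm <= 0)
    return("voxelEdgeNm must be a single positive number")
  if (length(object@periodicX) != 1L || is.na(object@periodicX))
    return("periodicX must be TRUE or FALSE")
  TRUE
})

#' Construct a FrameStack
#'
#' @param data a height x width x frames numeric array, or a list of equally
#'   sized matrices (one per frame), of [Ca] in uM.
#' @param dtMs frame interval in ms (default 5).
#' @param voxelEdgeNm voxel edge length in nm (default 100).
#' @param periodicX wrap-around in the column (perimeter) dimension
#'   (default FALSE).
#' @return a validated \code{FrameStack}.
#' @export
FrameStack <- function(data, dtMs = 5, voxelEdgeNm = 100, periodicX = FALSE) {
  if (is.list(data)) {
    if (length(data) == 0L)
      stop("FrameStack requires at least one frame")
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L || is.null(dims[[1]]))
      stop("all frames must be matrices of identical dimensions")
    data <- array(unlist(data, use.names = FALSE),
                  c(dims[[1]][1], dims[[1]][2], length(data)))
  }
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("FrameStack", data = data, dtMs = as.numeric(dtMs),
      voxelEdgeNm = as.numeric(voxelEdgeNm), periodicX = isTRUE(periodicX))
}

#' VoltageTrace: a sampled membrane-potential time course
#'
#' @slot tMs strictly increasing sample times in ms.
#' @slot vmMv membrane potential in mV, same length as \code{tMs}.
#' @export
setClass("VoltageTrace",
  representation(tMs = "numeric", vmMv = "numeric")
)

setValidity("VoltageTrace", function(object) {
  if (length(object@tMs) != length(object@vmMv))
    return("tMs and vmMv must have equal length")
  if (length(object@tMs) < 1L)
    return("trace must contain at least one sample")
  if (anyNA(object@tMs) || anyNA(object@vmMv) ||
      any(!is.finite(object@tMs)) || any(!is.finite(object@vmMv)))
    return("times and potentials must be finite")
  if (length(object@tMs) > 1L && any(diff(object@tMs) <= 0))
    return("sample times must be strictly increasing")
  TRUE
})

#' Construct a VoltageTrace
#' @param tMs sample times in ms, strictly increasing.
#' @param vmMv membrane potential in mV.
#' @return a validated \code{VoltageTrace}.
#' @export
VoltageTrace <- function(tMs, vmMv) {
  new("VoltageTrace", tMs = as.numeric(tMs), vmMv = as.numeric(vmMv))
}

#' LCRImageSet: all single-frame LCR images detected in a stack
#'
#' One LCR image is a connected component of the lowest intensity bin of a
#' frame (all voxels with [Ca] above the frame mean), carrying its intensity
#' peaks, complexity flag (>= 2 peaks) and signal mass. Images across all
#' frames are numbered by a global id (\code{gid}) used by the tracker.
#'
#' @slot images data.frame, one row per image: gid, frame, imageId (index
#'   within the frame), nVoxels, nPeaks, isComplex, signalMassNmol,
#'   maxAmplitudeUM, centroidRow, centroidCol.
#' @slot voxels list indexed by gid; each element an integer vector of
#'   linear voxel indices (column-major into a height x width frame).
#' @slot peaks list indexed by gid; each element a matrix with columns
#'   row, col, amplitudeUM (one row per intensity peak).
#' @slot frameDim integer height and width of the frames.
#' @slot nFrames number of frames scanned.
#' @slot params detection parameters used (nBins, connectivities, periodicX,
#'   dtMs, voxelEdgeNm).
#' @export
setClass("LCRImageSet",
  representation(
    images = "data.frame",
    voxels = "list",
    peaks = "list",
    frameDim = "integer",
    nFrames = "integer",
    params = "list"
  )
)

setValidity("LCRImageSet", function(object) {
  im <- object@images
  need <- c("gid", "frame", "imageId", "nVoxels", "nPeaks", "isComplex",
            "signalMassNmol", "maxAmplitudeUM", "centroidRow", "centroidCol")
  if (!all(need %in% names(im)))
    return(paste("images table must contain columns:",
                 paste(need, collapse = ", ")))
  if (nrow(im) != length(object@voxels) || nrow(im) != length(object@peaks))
    return("voxels and peaks lists must parallel the images table")
  if (nrow(im) > 0L) {
    if (!identical(im$gid, seq_len(nrow(im))))
      return("gid must be 1..nrow(images)")
    if (any(im$nPeaks < 1L))
      return("every LCR image must have at least one intensity peak")
    if (!identical(im$isComplex, im$nPeaks >= 2L))
      return("isComplex must equal (nPeaks >= 2)")
  }
  TRUE
})

#' LCRTrackSet: dynamic LCRs linked across frames, with their event log
#'
#' @slot tracks data.frame, one row per dynamic LCR: lcrId, class
#'   ("simple"/"complex"), birthFrame, lastFrame, deathFrame (NA while
#'   alive at end), termination ("attrition"/"collision"/"alive_at_end"),
#'   nThreads (peak concurrent thread count), nSeparations, nImages.
#' @slot events data.frame log: frame, kind ("birth", "death_attrition",
#'   "death_collision", "separation", "intra_thread_merge",
#'   "alive_at_end"), lcrId, otherLcrId (surviving LCR for collisions,
#'   else NA), imageIds (comma-separated gids involved).
#' @slot trackImages list keyed by as.character(lcrId): integer gids of all
#'   member images.
#' @slot imageSet the \code{LCRImageSet} the tracks were built from.
#' @export
setClass("LCRTrackSet",
  representation(
    tracks = "data.frame",
    events = "data.frame",
    trackImages = "list",
    imageSet = "LCRImageSet"
  )
)

setValidity("LCRTrackSet", function(object) {
  tr <- object@tracks
  need <- c("lcrId", "class", "birthFrame", "lastFrame", "deathFrame",
            "termination", "nThreads", "nSeparations", "nImages")
  if (!all(need %in% names(tr)))
    return(paste("tracks table must contain columns:",
                 paste(need, collapse = ", ")))
  if (nrow(tr) != length(object@trackImages))
    return("trackImages must parallel the tracks table")
  gids <- unlist(object@trackImages, use.names = FALSE)
  if (length(gids) != nrow(object@imageSet@images) ||
      anyDuplicated(gids) > 0L)
    return("every LCR image must belong to exactly one track")
  TRUE
})

#' AnalysisWindow: a diastolic analysis window in frames and times
#'
#' Delimits the portion of a stack between the maximal diastolic potential
#' (MDP) and the first upward crossing of a voltage threshold (by default
#' -50 mV, the L-type Ca channel activation threshold).
#'
#' @slot startFrame,endFrame 1-based frame indices into the stack.
#' @slot tMdpMs,tThresholdMs the corresponding times on the voltage trace.
#' @slot thresholdMv the voltage threshold used (mV).
#' @export
setClass("AnalysisWindow",
  representation(
    startFrame = "integer",
    endFrame = "integer",
    tMdpMs = "numeric",
    tThresholdMs = "numeric",
    thresholdMv = "numeric"
  )
)

setValidity("AnalysisWindow", function(object) {
  if (object@startFrame > object@endFrame)
    return("startFrame must be <= endFrame")
  if (object@startFrame < 1L)
    return("startFrame must be >= 1")
  TRUE
})
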