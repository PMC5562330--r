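#' Number of frames in an object
#' @param x a FrameStack or LCRImageSet.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame interval in milliseconds
#' @param x a FrameStack.
#' @return numeric, ms.
#' @export
setGeneric("dtMs", function(x) standardGeneric("dtMs"))

#' Voxel edge length in nanometres
#' @param x a FrameStack.
#' @return numeric, nm.
#' @export
setGeneric("voxelEdgeNm", function(x) standardGeneric("voxelEdgeNm"))

#' Periodic wrap-around flag for the column (perimeter) dimension
#' @param x a FrameStack.
#' @return logical.
#' @export
setGeneric("periodicX", function(x) standardGeneric("periodicX"))

#' Extract one frame as a matrix
#' @param x a FrameStack.
#' @param i 1-based frame index.
#' @return a height x width numeric matrix of [Ca] in uM.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Full data array of a FrameStack
#' @param x a FrameStack.
#' @return numeric array height x width x frames.
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))

#' Per-image table of an LCRImageSet
#' @param x an LCRImageSet or LCRTrackSet.
#' @return data.frame with one row per single-frame LCR image.
#' @export
setGeneric("imageTable", function(x) standardGeneric("imageTable"))

#' Voxel indices of one LCR image
#' @param x an LCRImageSet.
#' @param gid global image id.
#' @return matrix with columns row, col.
#' @export
setGeneric("imageVoxels", function(x, gid) standardGeneric("imageVoxels"))

#' Intensity peaks of one LCR image
#' @param x an LCRImageSet.
#' @param gid global image id.
#' @return matrix with columns row, col, amplitudeUM.
#' @export
setGeneric("imagePeaks", function(x, gid) standardGeneric("imagePeaks"))

#' Per-track table of an LCRTrackSet
#' @param x an LCRTrackSet.
#' @return data.frame with one row per dynamic LCR.
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))

#' The LCRImageSet underlying an LCRTrackSet
#' @param x an LCRTrackSet.
#' @return the \code{LCRImageSet} the tracks were built from.
#' @export
setGeneric("imageSet", function(x) standardGeneric("imageSet"))

#' Event log of an LCRTrackSet
#' @param x an LCRTrackSet.
#' @return data.frame of birth/death/collision/separation records.
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' Member image ids of one dynamic LCR
#' @param x an LCRTrackSet.
#' @param lcrId track id.
#' @return integer vector of global image ids.
#' @export
setGeneric("trackImages", function(x, lcrId) standardGeneric("trackImages"))

#' Classify each dynamic LCR as simple or complex
#'
#' A dynamic LCR is complex if at least one of its member single-frame
#' images has two or more intensity peaks; it is simple if every member
#' image has exactly one peak. The classification is independent of the
#' track's thread history.
#'
#' @param x an LCRTrackSet.
#' @return named character vector ("simple"/"complex"), names = lcrId.
#' @export
setGeneric("classifyTracks", function(x) standardGeneric("classifyTracks"))

## ---- FrameStack methods ----

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@data)[3])

#' @rdname dtMs
#' @export
setMethod("dtMs", "FrameStack", function(x) x@dtMs)

#' @rdname voxelEdgeNm
#' @export
setMethod("voxelEdgeNm", "FrameStack", function(x) x@voxelEdgeNm)

#' @rdname periodicX
#' @export
setMethod("periodicX", "FrameStack", function(x) x@periodicX)

#' @rdname getFrame
#' @export
setMethod("getFrame", "FrameStack", function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > dim(x@data)[3]) stop("frame index out of range")
  m <- x@data[, , i, drop = FALSE]
  dim(m) <- dim(x@data)[1:2]
  m
})

#' @rdname frameData
#' @export
setMethod("frameData", "FrameStack", function(x) x@data)

#' @describeIn FrameStack frame dimensions (height, width, frames).
#' @param x a FrameStack.
#' @export
setMethod("dim", "FrameStack", function(x) dim(x@data))

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "FrameStack: %d frame%s of %d x %d voxels\n", d[3],
    if (d[3] == 1L) "" else "s", d[1], d[2]))
  cat(sprintf("  dt = %g ms, voxel edge = %g nm, periodicX = %s\n",
              object@dtMs, object@voxelEdgeNm, object@periodicX))
  cat(sprintf("  [Ca] range: %.4g .. %.4g uM\n",
              min(object@data), max(object@data)))
})

setMethod("show", "VoltageTrace", function(object) {
  n <- length(object@tMs)
  cat(sprintf("VoltageTrace: %d samples, t = %g .. %g ms, Vm = %g .. %g mV\n",
              n, object@tMs[1], object@tMs[n],
              min(object@vmMv), max(object@vmMv)))
})

## ---- LCRImageSet methods ----

#' @rdname nFrames
#' @export
setMethod("nFrames", "LCRImageSet", function(x) x@nFrames)

#' @rdname imageTable
#' @export
setMethod("imageTable", "LCRImageSet", function(x) x@images)

#' @rdname imageVoxels
#' @export
setMethod("imageVoxels", "LCRImageSet", function(x, gid) {
  gid <- as.integer(gid)
  if (gid < 1L || gid > length(x@voxels)) stop("unknown image gid")
  idx <- x@voxels[[gid]]
  h <- x@frameDim[1]
  cbind(row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L)
})

#' @rdname imagePeaks
#' @export
setMethod("imagePeaks", "LCRImageSet", function(x, gid) {
  gid <- as.integer(gid)
  if (gid < 1L || gid > length(x@peaks)) stop("unknown image gid")
  x@peaks[[gid]]
})

setMethod("show", "LCRImageSet", function(object) {
  im <- object@images
  cat(sprintf("LCRImageSet: %d LCR image%s in %d frame%s (%d x %d voxels)\n",
              nrow(im), if (nrow(im) == 1L) "" else "s",
              object@nFrames, if (object@nFrames == 1L) "" else "s",
              object@frameDim[1], object@frameDim[2]))
  if (nrow(im) > 0L)
    cat(sprintf("  %d simple, %d complex; signal mass total %.4g nmol\n",
                sum(!im$isComplex), sum(im$isComplex),
                sum(im$signalMassNmol)))
  p <- object@params
  cat(sprintf("  nBins = %d, cluster connectivity = %d, peak neighbourhood = %d\n",
              p$nBins, p$clusterConnectivity, p$peakNeighborhood))
})

## ---- LCRTrackSet methods ----

#' @rdname imageTable
#' @export
setMethod("imageTable", "LCRTrackSet", function(x) x@imageSet@images)

#' @rdname trackTable
#' @export
setMethod("trackTable", "LCRTrackSet", function(x) x@tracks)

#' @rdname imageSet
#' @export
setMethod("imageSet", "LCRTrackSet", function(x) x@imageSet)

#' @rdname eventLog
#' @export
setMethod("eventLog", "LCRTrackSet", function(x) x@events)

#' @rdname trackImages
#' @export
setMethod("trackImages", "LCRTrackSet", function(x, lcrId) {
  key <- as.character(as.integer(lcrId))
  if (is.null(x@trackImages[[key]])) stop("unknown lcrId")
  x@trackImages[[key]]
})

#' @rdname classifyTracks
#' @export
setMethod("classifyTracks", "LCRTrackSet", function(x) {
  out <- x@tracks$class
  names(out) <- as.character(x@tracks$lcrId)
  out
})

setMethod("show", "LCRTrackSet", function(object) {
  tr <- object@tracks
  cat(sprintf("LCRTrackSet: %d dynamic LCR%s over %d frame%s\n",
              nrow(tr), if (nrow(tr) == 1L) "" else "s",
              object@imageSet@nFrames,
              if (object@imageSet@nFrames == 1L) "" else "s"))
  if (nrow(tr) > 0L) {
    cat(sprintf("  %d simple, %d complex\n",
                sum(tr$class == "simple"), sum(tr$class == "complex")))
    term <- table(tr$termination)
    cat("  terminations:",
        paste(sprintf("%s = %d", names(term), as.integer(term)),
              collapse = ", "), "\n")
  }
  ev <- object@events
  if (nrow(ev) > 0L) {
    kinds <- table(ev$kind)
    cat("  events:",
        paste(sprintf("%s = %d", names(kinds), as.integer(kinds)),
              collapse = ", "), "\n")
  }
})

setMethod("show", "AnalysisWindow", function(object) {
  cat(sprintf(
    "AnalysisWindow: frames %d .. %d (MDP at %g ms, %g mV crossed at %g ms)\n",
    object@startFrame, object@endFrame, object@tMdpMs,
    object@thresholdMv, object@tThresholdMs))
})
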