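## Frame-to-frame linking of LCR images into dynamic LCRs.
##
## Two images in consecutive frames are paired when their lowest-bin
## footprints share at least one voxel. Per frame, in order:
##   collisions   a current image paired with previous images of >= 2
##                distinct live tracks; the track whose paired previous
##                image has the largest signal mass survives and adopts the
##                image, every other participant is terminated by collision
##                and all of its pairs are deleted (collision has priority
##                over separation);
##   adoption     each remaining current image joins the unique live track
##                it pairs with; a previous image feeding >= 2 current
##                images is a separation (the track gains threads); a
##                current image fed by >= 2 previous images of the same
##                track merges threads;
##   births       unpaired current images start new tracks;
##   attrition    live tracks that adopted nothing are terminated.
## A multi-thread track stays alive while any thread continues; threads are
## identified with the track's current-frame images, so the live thread
## count of a frame is the number of images the track holds in it.

#' Pair overlapping LCR images of consecutive frames
#'
#' Returns all image pairs between frames \code{frame - 1} and
#' \code{frame} whose lowest-bin voxel sets share at least one voxel,
#' ordered by (previous gid, current gid).
#'
#' @param imageSet an \code{\link{LCRImageSet}}.
#' @param frame 1-based index of the current frame (>= 2).
#' @return data.frame with columns \code{prevGid}, \code{currGid}.
#' @export
pairImages <- function(imageSet, frame) {
  stopifnot(is(imageSet, "LCRImageSet"))
  frame <- as.integer(frame)
  if (frame < 2L || frame > imageSet@nFrames)
    stop("frame must be in 2..nFrames")
  im <- imageSet@images
  prevG <- im$gid[im$frame == frame - 1L]
  currG <- im$gid[im$frame == frame]
  .pairGids(imageSet, prevG, currG)
}

.pairGids <- function(imageSet, prevG, currG) {
  if (length(prevG) == 0L || length(currG) == 0L)
    return(data.frame(prevGid = integer(), currGid = integer()))
  npix <- prod(imageSet@frameDim)
  owner <- integer(npix)
  for (g in prevG) owner[imageSet@voxels[[g]]] <- g
  out <- vector("list", length(currG))
  for (k in seq_along(currG)) {
    g <- currG[k]
    hits <- unique(owner[imageSet@voxels[[g]]])
    hits <- sort(hits[hits > 0L])
    if (length(hits) > 0L)
      out[[k]] <- data.frame(prevGid = hits, currGid = g)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(prevGid = integer(), currGid = integer()))
  res <- do.call(rbind, out)
  res[order(res$prevGid, res$currGid), , drop = FALSE]
}

#' Track dynamic LCRs through a frame stack
#'
#' Links the single-frame LCR images of consecutive frames by spatial
#' overlap into dynamic LCRs, recording births, deaths by stochastic
#' attrition, collisions (resolved by the signal mass of the colliding
#' tracks' previous-frame images, priority over separations), separations
#' into threads and intra-track thread merges. Tracks still alive on the
#' last frame are labelled \code{alive_at_end}. Detection and tracking are
#' fully deterministic: identical input and configuration give identical
#' event logs.
#'
#' @param x a \code{\link{FrameStack}} (segmented first with
#'   \code{\link{detectLCRImages}}) or an \code{\link{LCRImageSet}}.
#' @param config an \code{\link{lcrConfig}}, used when \code{x} is a
#'   FrameStack.
#' @return an \code{\link{LCRTrackSet}}.
#' @examples
#' scn <- makeMergeScenario()
#' fs <- renderScenario(scn)$stack
#' ts <- trackLCRs(fs)
#' subset(eventLog(ts), kind == "death_collision")
#' @export
trackLCRs <- function(x, config = lcrConfig()) {
  imageSet <- if (is(x, "FrameStack")) detectLCRImages(x, config)
              else if (is(x, "LCRImageSet")) x
              else stop("x must be a FrameStack or LCRImageSet")
  im <- imageSet@images
  nf <- imageSet@nFrames
  nImages <- nrow(im)

  ## growing per-track state, indexed by lcrId
  birthFrame <- integer(0); lastFrame <- integer(0)
  deathFrame <- integer(0)                    # NA_integer_ while alive
  termination <- character(0)
  alive <- logical(0)
  nThreadsMax <- integer(0); nThreadsCur <- integer(0)
  nSeparations <- integer(0)
  isComplexTrack <- logical(0)
  memberGids <- list()
  trackOf <- integer(nImages)                 # gid -> owning lcrId

  events <- list()
  addEvent <- function(frame, kind, lcrId, otherLcrId = NA_integer_,
                       imageIds = integer(0)) {
    events[[length(events) + 1L]] <<- data.frame(
      frame = frame, kind = kind, lcrId = lcrId,
      otherLcrId = otherLcrId,
      imageIds = paste(imageIds, collapse = ","))
  }
  newTrack <- function(frame, gid) {
    id <- length(birthFrame) + 1L
    birthFrame[id] <<- frame; lastFrame[id] <<- frame
    deathFrame[id] <<- NA_integer_
    termination[id] <<- "none"
    alive[id] <<- TRUE
    nThreadsMax[id] <<- 1L; nThreadsCur[id] <<- 1L
    nSeparations[id] <<- 0L
    isComplexTrack[id] <<- im$isComplex[gid]
    memberGids[[id]] <<- gid
    trackOf[gid] <<- id
    addEvent(frame, "birth", id, imageIds = gid)
    id
  }

  frameGids <- split(im$gid, factor(im$frame, levels = seq_len(nf)))

  ## frame 1: every image starts a track (pre-existing releases are births)
  for (g in frameGids[[1]]) newTrack(1L, g)

  for (f in seq_len(nf)[-1]) {
    currG <- frameGids[[f]]
    pairs <- .pairGids(imageSet, frameGids[[f - 1L]], currG)
    if (nrow(pairs) > 0L)
      pairs$track <- trackOf[pairs$prevGid]

    ## ---- collisions (priority over separations) ----
    if (nrow(pairs) > 0L) {
      for (g in sort(unique(pairs$currGid))) {
        sel <- pairs$currGid == g & alive[pairs$track]
        cand <- unique(pairs$track[sel])
        if (length(cand) < 2L) next
        ## best previous-image signal mass per candidate track
        best <- vapply(cand, function(t) {
          max(im$signalMassNmol[pairs$prevGid[sel & pairs$track == t]])
        }, 1.0)
        ## survivor: largest mass; tie -> oldest track (smallest id)
        ord <- order(-best, cand)
        survivor <- cand[ord[1]]
        losers <- cand[ord[-1]]
        for (l in losers) {
          alive[l] <- FALSE
          termination[l] <- "collision"
          deathFrame[l] <- f - 1L
          nThreadsCur[l] <- 0L
          addEvent(f, "death_collision", l, otherLcrId = survivor,
                   imageIds = g)
        }
        ## drop every pair of the terminated tracks before separations
        pairs <- pairs[alive[pairs$track], , drop = FALSE]
      }
    }

    ## ---- adoption: continuation, separations, thread merges ----
    adopted <- integer(0)
    if (nrow(pairs) > 0L) {
      for (t in sort(unique(pairs$track))) {
        tp <- pairs[pairs$track == t, , drop = FALSE]
        currSet <- sort(unique(tp$currGid))
        ## separations: one previous image feeding several current images
        for (pg in sort(unique(tp$prevGid))) {
          cg <- tp$currGid[tp$prevGid == pg]
          if (length(cg) >= 2L) {
            nSeparations[t] <- nSeparations[t] + 1L
            addEvent(f, "separation", t, imageIds = c(pg, sort(cg)))
          }
        }
        ## thread merges: one current image fed by several previous images
        ## of this same track (not a collision: one LCR involved)
        for (cg in currSet) {
          pg <- tp$prevGid[tp$currGid == cg]
          if (length(pg) >= 2L)
            addEvent(f, "intra_thread_merge", t, imageIds = c(sort(pg), cg))
        }
        memberGids[[t]] <- c(memberGids[[t]], currSet)
        trackOf[currSet] <- t
        lastFrame[t] <- f
        nThreadsCur[t] <- length(currSet)
        nThreadsMax[t] <- max(nThreadsMax[t], length(currSet))
        isComplexTrack[t] <- isComplexTrack[t] || any(im$isComplex[currSet])
        adopted <- c(adopted, currSet)
      }
    }

    ## ---- births ----
    for (g in setdiff(currG, adopted)) newTrack(f, g)

    ## ---- attrition: live tracks that found no successor ----
    stale <- which(alive & lastFrame == f - 1L)
    for (t in stale) {
      alive[t] <- FALSE
      termination[t] <- "attrition"
      deathFrame[t] <- f - 1L
      nThreadsCur[t] <- 0L
      addEvent(f, "death_attrition", t,
               imageIds = intersect(memberGids[[t]],
                                    frameGids[[f - 1L]]))
    }
  }

  ## ---- finalize: tracks alive on the last frame ----
  for (t in which(alive)) {
    termination[t] <- "alive_at_end"
    addEvent(nf, "alive_at_end", t,
             imageIds = intersect(memberGids[[t]], frameGids[[nf]]))
  }

  nTracks <- length(birthFrame)
  tracks <- data.frame(
    lcrId = seq_len(nTracks),
    class = ifelse(isComplexTrack, "complex", "simple"),
    birthFrame = birthFrame,
    lastFrame = lastFrame,
    deathFrame = deathFrame,
    termination = termination,
    nThreads = nThreadsMax,
    nSeparations = nSeparations,
    nImages = vapply(memberGids, length, 1L))
  if (nTracks == 0L) tracks <- tracks[0, , drop = FALSE]
  eventsDf <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(frame = integer(), kind = character(), lcrId = integer(),
               otherLcrId = integer(), imageIds = character())
  names(memberGids) <- as.character(seq_len(nTracks))
  new("LCRTrackSet", tracks = tracks, events = eventsDf,
      trackImages = memberGids, imageSet = imageSet)
}
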