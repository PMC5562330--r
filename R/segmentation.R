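## Single-frame LCR detection: adaptive intensity binning, nested
## supra-threshold clusters, per-cluster intensity peaks, signal mass.
##
## The threshold ladder is recomputed for every frame: the intensity
## increment is (frame max - frame mean) / nBins and bin i (1-based) holds
## the voxels with [Ca] strictly above mean + increment * (i - 1). The
## lowest bin separates releases from background: every connected component
## of it is one LCR image.

#' Per-frame intensity increment
#'
#' Computes the arithmetic frame mean and the intensity increment
#' \code{delta = (max - mean) / nBins} used to slice the frame into nested
#' intensity bins. A spatially uniform frame has \code{delta = 0} and is
#' flagged degenerate (it contains no detectable release).
#'
#' @param frame numeric matrix of [Ca] in uM.
#' @param nBins number of intensity bins (default 50).
#' @return list with \code{mean}, \code{max}, \code{delta} (uM) and
#'   \code{degenerate} (logical).
#' @examples
#' f <- matrix(0, 3, 3); f[2, 2] <- 9
#' computeIncrement(f)   # mean 1, delta (9 - 1)/50 = 0.16
#' @export
computeIncrement <- function(frame, nBins = 50) {
  stopifnot(is.matrix(frame), is.numeric(frame), nBins >= 1)
  m <- mean(frame)
  mx <- max(frame)
  delta <- (mx - m) / nBins
  list(mean = m, max = mx, delta = delta, degenerate = delta <= 0)
}

#' Build the nested Boolean intensity bins of a frame
#'
#' Bin i (1-based) is the Boolean mask \code{frame > mean + delta*(i-1)}
#' (strict inequality at every level, including the mean level of bin 1).
#' Masks are nested by construction: each bin is a subset of the one below.
#'
#' @param frame numeric matrix of [Ca] in uM.
#' @param mean,delta frame mean and intensity increment (uM), normally from
#'   \code{\link{computeIncrement}}.
#' @param nBins number of bins (default 50).
#' @return an object of class \code{lcrBinSet}: list with \code{frameMean},
#'   \code{frameMax}, \code{delta}, \code{nBins} and \code{masks}, a
#'   height x width x nBins logical array (\code{masks[,,i]} = bin i).
#' @export
buildBins <- function(frame, mean, delta, nBins = 50) {
  stopifnot(is.matrix(frame), delta >= 0, nBins >= 1)
  levels <- mean + delta * (seq_len(nBins) - 1)
  masks <- array(FALSE, c(nrow(frame), ncol(frame), nBins))
  for (i in seq_len(nBins)) masks[, , i] <- frame > levels[i]
  structure(
    list(frameMean = mean, frameMax = mean + delta * nBins, delta = delta,
         nBins = as.integer(nBins), masks = masks),
    class = "lcrBinSet")
}

#' @export
print.lcrBinSet <- function(x, ...) {
  cat(sprintf("lcrBinSet: %d nested bins, mean %.4g uM, delta %.4g uM\n",
              x$nBins, x$frameMean, x$delta))
  cat(sprintf("  lowest bin: %d supra-mean voxels\n", sum(x$masks[, , 1])))
  invisible(x)
}

## Adjacency edge list between TRUE voxels of a mask (or between region
## voxels), as id pairs. ids: integer matrix with NA at excluded voxels.
.adjacencyEdges <- function(id, connectivity, periodicX) {
  h <- nrow(id); w <- ncol(id)
  pair <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    cbind(a[ok], b[ok])
  }
  edges <- list()
  if (h > 1L)
    edges[[length(edges) + 1L]] <- pair(id[-h, , drop = FALSE],
                                        id[-1, , drop = FALSE])
  if (w > 1L)
    edges[[length(edges) + 1L]] <- pair(id[, -w, drop = FALSE],
                                        id[, -1, drop = FALSE])
  if (connectivity == 8L && h > 1L && w > 1L) {
    edges[[length(edges) + 1L]] <- pair(id[-h, -w, drop = FALSE],
                                        id[-1, -1, drop = FALSE])
    edges[[length(edges) + 1L]] <- pair(id[-h, -1, drop = FALSE],
                                        id[-1, -w, drop = FALSE])
  }
  if (periodicX && w > 2L) {
    edges[[length(edges) + 1L]] <- pair(id[, w], id[, 1])
    if (connectivity == 8L && h > 1L) {
      edges[[length(edges) + 1L]] <- pair(id[-h, w], id[-1, 1])
      edges[[length(edges) + 1L]] <- pair(id[-1, w], id[-h, 1])
    }
  }
  if (length(edges) == 0L) return(matrix(integer(), 0, 2))
  do.call(rbind, edges)
}

## Label connected components of a logical mask. Returns an integer matrix
## (0 = background) with components numbered 1..k in order of their
## lexicographically smallest (row, col) member.
.labelMask <- function(mask, connectivity = 4L, periodicX = FALSE) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  id <- matrix(NA_integer_, h, w)
  id[idx] <- seq_len(n)
  e <- .adjacencyEdges(id, as.integer(connectivity), periodicX)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(e) > 0L) g <- igraph::add_edges(g, t(e))
  memb <- igraph::components(g)$membership
  ## renumber components by smallest (row, col) member
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  ord <- order(rows, cols)
  newId <- integer(max(memb))
  nextId <- 0L
  for (k in ord) {
    m <- memb[k]
    if (newId[m] == 0L) { nextId <- nextId + 1L; newId[m] <- nextId }
  }
  lab[idx] <- newId[memb]
  lab
}

#' Find the intensity clusters of a Boolean mask
#'
#' Partitions the TRUE voxels of an intensity-bin mask into maximal
#' connected components. Under the default 4-connectivity two voxels
#' belong to the same cluster only if they share an edge ("a common
#' border"); 8-connectivity additionally joins diagonal contacts.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 4).
#' @param periodicX if TRUE the column dimension wraps around.
#' @return list of clusters, ordered by their lexicographically smallest
#'   (row, col) member; each cluster is an integer matrix with columns
#'   \code{row}, \code{col}, rows ordered the same way.
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' length(findClusters(m, connectivity = 4))  # 2: diagonal contact splits
#' length(findClusters(m, connectivity = 8))  # 1
#' @export
findClusters <- function(mask, connectivity = 4, periodicX = FALSE) {
  stopifnot(is.logical(mask), is.matrix(mask),
            connectivity %in% c(4, 8))
  lab <- .labelMask(mask, connectivity, periodicX)
  k <- max(lab)
  if (k == 0L) return(list())
  h <- nrow(mask)
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  out <- vector("list", k)
  for (i in seq_len(k)) {
    sel <- lab[idx] == i
    r <- rows[sel]; cc <- cols[sel]
    o <- order(r, cc)
    out[[i]] <- cbind(row = r[o], col = cc[o])
  }
  out
}

## Region voxels as linear indices from either a 2-col matrix or a vector.
.regionIndices <- function(region, h) {
  if (is.matrix(region) && ncol(region) == 2L)
    return(as.integer((region[, 2] - 1L) * h + region[, 1]))
  as.integer(region)
}

#' Find the intensity peaks of a region of a frame
#'
#' An intensity peak is a voxel whose [Ca] is at least as high as every one
#' of its neighbours within the region, with no strictly higher neighbour.
#' A connected plateau of equal local-maximal values counts as a single
#' peak, represented by its lexicographically smallest (row, col) voxel
#' (prevents double counting on quantised data). A non-empty region always
#' contains at least one peak.
#'
#' @param frame numeric matrix of [Ca] in uM.
#' @param region voxels of the region: matrix with columns row, col, or a
#'   vector of linear (column-major) indices.
#' @param neighborhood 4 or 8 (default 8: diagonal neighbours suppress
#'   spurious twin peaks).
#' @param periodicX if TRUE the column dimension wraps around.
#' @return matrix with columns \code{row}, \code{col}, \code{amplitudeUM},
#'   one row per peak, ordered by (row, col).
#' @examples
#' f <- matrix(c(0, 4, 2, 3, 0, 0, 0), 1, 7)
#' findPeaks(f, cbind(1, 2:4))  # two peaks: columns 2 (4 uM) and 4 (3 uM)
#' @export
findPeaks <- function(frame, region, neighborhood = 8, periodicX = FALSE) {
  stopifnot(is.matrix(frame), neighborhood %in% c(4, 8))
  h <- nrow(frame); w <- ncol(frame)
  idx <- .regionIndices(region, h)
  n <- length(idx)
  if (n == 0L) stop("region must be non-empty")
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  vals <- frame[idx]
  pos <- matrix(NA_integer_, h, w)
  pos[idx] <- seq_len(n)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (neighborhood == 8)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  nbrMax <- rep(-Inf, n)
  eqEdges <- list()
  for (o in offs) {
    nr <- rows + o[1]
    nc <- cols + o[2]
    if (periodicX) nc <- ((nc - 1L) %% w) + 1L
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    if (!any(ok)) next
    p <- pos[cbind(nr[ok], nc[ok])]
    inReg <- !is.na(p)
    src <- which(ok)[inReg]
    dst <- p[inReg]
    if (length(src) == 0L) next
    nbrMax[src] <- pmax(nbrMax[src], vals[dst])
    eq <- vals[src] == vals[dst]
    if (any(eq)) eqEdges[[length(eqEdges) + 1L]] <- cbind(src[eq], dst[eq])
  }
  ## plateaus: components of the equal-value adjacency graph
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(eqEdges) > 0L) {
    e <- do.call(rbind, eqEdges)
    g <- igraph::add_edges(g, t(e))
  }
  plateau <- igraph::components(g)$membership
  isPeak <- logical(max(plateau))
  for (pl in seq_len(max(plateau))) {
    mem <- which(plateau == pl)
    ## a plateau is a peak iff no in-region neighbour exceeds its value
    isPeak[pl] <- all(nbrMax[mem] <= vals[mem][1])
  }
  reps <- vapply(which(isPeak), function(pl) {
    mem <- which(plateau == pl)
    mem[order(rows[mem], cols[mem])][1]
  }, 1L)
  reps <- reps[order(rows[reps], cols[reps])]
  cbind(row = rows[reps], col = cols[reps], amplitudeUM = vals[reps])
}

#' Signal mass of a single-frame LCR image
#'
#' The calcium content of the image in nmol: the sum of the voxel
#' concentrations (uM, converted to nmol/L) multiplied by the voxel volume
#' in litres. For the default 100 nm voxel edge the voxel volume is
#' 1e-18 L, so a single voxel at 1 uM carries 1e-15 nmol.
#'
#' @param frame numeric matrix of [Ca] in uM.
#' @param voxels image voxels: matrix with columns row, col, or linear
#'   indices.
#' @param voxelEdgeNm voxel edge length in nm (default 100).
#' @return signal mass in nmol.
#' @export
imageSignalMass <- function(frame, voxels, voxelEdgeNm = 100) {
  idx <- .regionIndices(voxels, nrow(frame))
  vVoxelL <- (voxelEdgeNm * 1e-9)^3 * 1000   # m^3 -> litres
  sum(frame[idx]) * 1000 * vVoxelL           # uM -> nmol/L, times litres
}

#' Construct the LCR images of one frame from its intensity bins
#'
#' Every connected component of the lowest intensity bin (all voxels with
#' [Ca] strictly above the frame mean) is one LCR image; its intensity
#' peaks are counted within the component, and an image with two or more
#' peaks is complex. A degenerate (uniform) frame yields no images. The
#' images are pairwise disjoint and their union is exactly the lowest bin.
#'
#' @param frame numeric matrix of [Ca] in uM.
#' @param bins an \code{lcrBinSet} built from this frame
#'   (\code{\link{buildBins}}).
#' @param frameIndex 1-based frame index recorded in the result.
#' @param clusterConnectivity 4 or 8 for the component search (default 4).
#' @param peakNeighborhood 4 or 8 for peak suppression (default 8).
#' @param periodicX wrap-around flag.
#' @param voxelEdgeNm voxel edge in nm for the signal mass (default 100).
#' @return list of LCR image records; each a list with \code{frame},
#'   \code{imageId}, \code{voxels} (row/col matrix), \code{peaks}
#'   (row/col/amplitudeUM matrix), \code{nPeaks}, \code{isComplex},
#'   \code{signalMassNmol}, \code{maxAmplitudeUM}, \code{centroidRow},
#'   \code{centroidCol}.
#' @export
buildLCRImages <- function(frame, bins, frameIndex = 1,
                           clusterConnectivity = 4, peakNeighborhood = 8,
                           periodicX = FALSE, voxelEdgeNm = 100) {
  stopifnot(inherits(bins, "lcrBinSet"))
  if (bins$delta <= 0) return(list())
  clusters <- findClusters(bins$masks[, , 1], clusterConnectivity, periodicX)
  lapply(seq_along(clusters), function(i) {
    vox <- clusters[[i]]
    pk <- findPeaks(frame, vox, peakNeighborhood, periodicX)
    vals <- frame[cbind(vox[, 1], vox[, 2])]
    list(frame = as.integer(frameIndex), imageId = i, voxels = vox,
         peaks = pk, nPeaks = nrow(pk), isComplex = nrow(pk) >= 2L,
         signalMassNmol = imageSignalMass(frame, vox, voxelEdgeNm),
         maxAmplitudeUM = max(vals),
         centroidRow = mean(vox[, 1]), centroidCol = mean(vox[, 2]))
  })
}

#' Detect all LCR images in a frame stack
#'
#' Runs the per-frame segmentation (adaptive mean threshold, connected
#' components, peak counting, signal mass) over every frame of the stack
#' and collects the results into an \code{\link{LCRImageSet}}. The mean and
#' intensity increment are recomputed for each frame, so segmentation
#' levels follow the global calcium transient.
#'
#' @param stack a \code{\link{FrameStack}}.
#' @param config an \code{\link{lcrConfig}} list of detection parameters.
#' @return an \code{\link{LCRImageSet}}.
#' @examples
#' scn <- makePopulationScenario(nEvents = 4, height = 32, width = 32,
#'                               nFrames = 40, seed = 1)
#' fs <- renderScenario(scn)$stack
#' detectLCRImages(fs)
#' @export
detectLCRImages <- function(stack, config = lcrConfig()) {
  stopifnot(is(stack, "FrameStack"))
  d <- stack@data
  h <- dim(d)[1]; w <- dim(d)[2]; nf <- dim(d)[3]
  per <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- matrix(d[, , f], h, w)
    inc <- computeIncrement(fr, config$nBins)
    if (inc$degenerate) { per[[f]] <- list(); next }
    ## only the lowest bin delimits images; higher bins are implied nested
    mask <- fr > inc$mean
    clusters <- findClusters(mask, config$clusterConnectivity,
                             stack@periodicX)
    per[[f]] <- lapply(seq_along(clusters), function(i) {
      vox <- clusters[[i]]
      pk <- findPeaks(fr, vox, config$peakNeighborhood, stack@periodicX)
      vals <- fr[cbind(vox[, 1], vox[, 2])]
      list(frame = f, imageId = i, voxels = vox, peaks = pk,
           nPeaks = nrow(pk), isComplex = nrow(pk) >= 2L,
           signalMassNmol = imageSignalMass(fr, vox, stack@voxelEdgeNm),
           maxAmplitudeUM = max(vals),
           centroidRow = mean(vox[, 1]), centroidCol = mean(vox[, 2]))
    })
  }
  recs <- unlist(per, recursive = FALSE)
  n <- length(recs)
  images <- data.frame(
    gid = seq_len(n),
    frame = vapply(recs, `[[`, 1L, "frame"),
    imageId = vapply(recs, function(r) as.integer(r$imageId), 1L),
    nVoxels = vapply(recs, function(r) nrow(r$voxels), 1L),
    nPeaks = vapply(recs, function(r) as.integer(r$nPeaks), 1L),
    isComplex = vapply(recs, `[[`, TRUE, "isComplex"),
    signalMassNmol = vapply(recs, `[[`, 1.0, "signalMassNmol"),
    maxAmplitudeUM = vapply(recs, `[[`, 1.0, "maxAmplitudeUM"),
    centroidRow = vapply(recs, `[[`, 1.0, "centroidRow"),
    centroidCol = vapply(recs, `[[`, 1.0, "centroidCol"))
  if (n == 0L)
    images <- images[0, , drop = FALSE]
  voxels <- lapply(recs, function(r)
    as.integer((r$voxels[, 2] - 1L) * h + r$voxels[, 1]))
  peaks <- lapply(recs, `[[`, "peaks")
  new("LCRImageSet", images = images, voxels = voxels, peaks = peaks,
      frameDim = c(h, w), nFrames = nf,
      params = list(nBins = config$nBins,
                    clusterConnectivity = config$clusterConnectivity,
                    peakNeighborhood = config$peakNeighborhood,
                    periodicX = stack@periodicX,
                    dtMs = stack@dtMs, voxelEdgeNm = stack@voxelEdgeNm))
}
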