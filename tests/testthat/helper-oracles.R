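## Independent oracles and fixture builders. Everything here is written
## from first principles (explicit loops, queue-based flood fill) so the
## package implementation is checked against independent code paths.

## Brute-force BFS flood fill labelling of a logical mask. Components are
## numbered in order of their lexicographically smallest (row, col) voxel.
oracleFloodFill <- function(mask, connectivity = 4, periodicX = FALSE) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  nextLab <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!mask[r, cc] || lab[r, cc] > 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- nextLab
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        nr <- v[1] + o[1]; nc <- v[2] + o[2]
        if (periodicX && w > 2) nc <- ((nc - 1) %% w) + 1
        if (nr < 1 || nr > h || nc < 1 || nc > w) next
        if (mask[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- nextLab
          queue[[length(queue) + 1L]] <- c(nr, nc)
        }
      }
    }
  }
  lab
}

## Exhaustive peak oracle: flood-fill the region into plateaus (maximal
## connected sets of equal value); a plateau is one peak iff no in-region
## neighbour of any of its voxels is strictly higher. Each peak is
## reported at its plateau's smallest (row, col) voxel.
oraclePeaks <- function(frame, region, neighborhood = 8) {
  h <- nrow(frame); w <- ncol(frame)
  inReg <- matrix(FALSE, h, w)
  inReg[region] <- TRUE
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (neighborhood == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  seen <- matrix(FALSE, h, w)
  peaks <- NULL
  for (k in seq_len(nrow(region))) {
    r0 <- region[k, 1]; c0 <- region[k, 2]
    if (seen[r0, c0]) next
    v0 <- frame[r0, c0]
    members <- matrix(c(r0, c0), 1, 2)
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    hasHigher <- FALSE
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        nr <- v[1] + o[1]; nc <- v[2] + o[2]
        if (nr < 1 || nr > h || nc < 1 || nc > w || !inReg[nr, nc]) next
        if (frame[nr, nc] > v0) hasHigher <- TRUE
        if (!seen[nr, nc] && frame[nr, nc] == v0) {
          seen[nr, nc] <- TRUE
          members <- rbind(members, c(nr, nc))
          queue[[length(queue) + 1L]] <- c(nr, nc)
        }
      }
    }
    if (!hasHigher) {
      rep <- members[order(members[, 1], members[, 2])[1], ]
      peaks <- rbind(peaks, c(rep[1], rep[2], v0))
    }
  }
  peaks <- peaks[order(peaks[, 1], peaks[, 2]), , drop = FALSE]
  colnames(peaks) <- c("row", "col", "amplitudeUM")
  peaks
}

## Random logical mask with tunable fill.
randomMask <- function(h, w, p = 0.4) {
  matrix(stats::runif(h * w) < p, h, w)
}

## Random non-negative frame with a few smooth bumps over noise.
randomFrame <- function(h, w, nBumps = 3) {
  f <- matrix(stats::runif(h * w, 0, 0.2), h, w)
  for (i in seq_len(nBumps)) {
    r0 <- stats::runif(1, 1, h); c0 <- stats::runif(1, 1, w)
    a <- stats::runif(1, 0.5, 3); s <- stats::runif(1, 1, 3)
    f <- f + a * exp(-(outer((seq_len(h) - r0)^2, (seq_len(w) - c0)^2,
                             "+")) / (2 * s^2))
  }
  f
}

## FrameStack from a list of plain value matrices (uM).
stackFromValues <- function(frames, dtMs = 5, voxelEdgeNm = 100) {
  FrameStack(frames, dtMs = dtMs, voxelEdgeNm = voxelEdgeNm)
}

## Blob helper for scripted tracking fixtures: returns a bg-filled matrix
## with the given voxels set to value.
blobFrame <- function(h, w, voxels, value, bg = 0.01) {
  f <- matrix(bg, h, w)
  f[voxels] <- value
  f
}

## Rectangle voxel index matrix (rows x cols), as cbind(row, col).
rectVoxels <- function(rows, cols) {
  as.matrix(expand.grid(row = rows, col = cols))
}

## Quantize doubles through IEEE float32, the precision of the TIFF dialect.
asFloat32 <- function(x) {
  readBin(writeBin(as.vector(x), raw(), size = 4), "numeric",
          size = 4, n = length(x))
}

## Independent per-track metric recomputation from the raw stack: scan all
## member images' voxels frame by frame.
oracleTrackMetrics <- function(trackSet, stack, lcrId) {
  im <- imageTable(trackSet)
  gids <- trackImages(trackSet, lcrId)
  d <- frameData(stack)
  h <- dim(d)[1]
  massSum <- 0; maxAmp <- -Inf; voxUnion <- integer(0)
  vVoxelL <- (voxelEdgeNm(stack) * 1e-9)^3 * 1000
  for (g in gids) {
    vox <- imageVoxels(imageSet(trackSet), g)
    f <- im$frame[im$gid == g]
    vals <- d[, , f][cbind(vox[, 1], vox[, 2])]
    massSum <- massSum + sum(vals) * 1000 * vVoxelL
    maxAmp <- max(maxAmp, max(vals))
    voxUnion <- union(voxUnion, (vox[, 2] - 1) * h + vox[, 1])
  }
  list(signalMassNmolMs = massSum * dtMs(stack),
       pathAreaUm2 = length(voxUnion) * (voxelEdgeNm(stack) / 1000)^2,
       maxAmplitudeUM = maxAmp)
}
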