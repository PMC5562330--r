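test_that("intensity increment follows the per-frame mean/max formula", {
  f <- matrix(0, 3, 3); f[2, 2] <- 9
  inc <- computeIncrement(f, 50)
  expect_equal(inc$mean, 1)
  expect_equal(inc$delta, (9 - 1) / 50)   # 0.16 uM
  expect_false(inc$degenerate)
  ## uniform frame is degenerate, not an error
  incU <- computeIncrement(matrix(0.1, 4, 4), 50)
  expect_equal(incU$delta, 0)
  expect_true(incU$degenerate)
  ## random frame equals direct arithmetic recomputation
  set.seed(1)
  g <- matrix(runif(256, 0, 5), 16, 16)
  incR <- computeIncrement(g, 50)
  expect_equal(incR$mean, sum(g) / length(g))
  expect_equal(incR$delta, (max(g) - sum(g) / length(g)) / 50)
})

test_that("intensity bins are strict supra-threshold masks and nest", {
  f <- matrix(0, 3, 3); f[2, 2] <- 9
  inc <- computeIncrement(f, 50)
  bins <- buildBins(f, inc$mean, inc$delta, 50)
  ## centre (9 uM) exceeds even the top level mean + 49*delta = 8.84
  for (i in c(1, 25, 50))
    expect_equal(which(bins$masks[, , i]), 5L)   # only the centre voxel
  ## 1x7 row example: mean 9/7, lowest bin = columns 2..4
  r <- matrix(c(0, 4, 2, 3, 0, 0, 0), 1, 7)
  incR <- computeIncrement(r, 50)
  expect_equal(incR$mean, 9 / 7)
  binsR <- buildBins(r, incR$mean, incR$delta, 50)
  expect_equal(which(binsR$masks[1, , 1]), c(2L, 3L, 4L))
  ## nesting on random frames, checked by brute force
  set.seed(7)
  for (rep in 1:20) {
    g <- randomFrame(12, 15)
    inc <- computeIncrement(g, 50)
    b <- buildBins(g, inc$mean, inc$delta, 50)
    for (i in 1:49)
      expect_true(all(b$masks[, , i][b$masks[, , i + 1]]))
    ## strict inequality at the mean level
    expect_identical(b$masks[, , 1], g > inc$mean)
  }
})

test_that("clusters are maximal connected components with a common border", {
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE      # diagonal contact only
  expect_length(findClusters(m, connectivity = 4), 2L)
  expect_length(findClusters(m, connectivity = 8), 1L)
  mL <- matrix(FALSE, 3, 3)
  mL[1, 1] <- mL[2, 1] <- mL[2, 2] <- TRUE   # L shape, edge-connected
  cl <- findClusters(mL, connectivity = 4)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 3L)
  expect_length(findClusters(matrix(FALSE, 2, 2)), 0L)
})

test_that("clustering matches the flood-fill oracle on random masks", {
  set.seed(11)
  for (rep in 1:100) {
    m <- randomMask(16, 16, p = runif(1, 0.2, 0.6))
    for (conn in c(4, 8)) {
      lab <- oracleFloodFill(m, conn)
      cl <- findClusters(m, connectivity = conn)
      expect_length(cl, max(lab))
      for (i in seq_along(cl)) {
        got <- cl[[i]]
        expect_true(all(lab[got] == i))
        expect_equal(nrow(got), sum(lab == i))
      }
    }
  }
  ## periodic wrap joins components touching across the seam
  mp <- matrix(FALSE, 4, 8)
  mp[2, 1] <- TRUE; mp[2, 8] <- TRUE
  expect_length(findClusters(mp, connectivity = 4), 2L)
  expect_length(findClusters(mp, connectivity = 4, periodicX = TRUE), 1L)
  set.seed(12)
  for (rep in 1:20) {
    m <- randomMask(10, 12, 0.45)
    labO <- oracleFloodFill(m, 4, periodicX = TRUE)
    cl <- findClusters(m, connectivity = 4, periodicX = TRUE)
    expect_length(cl, max(labO))
  }
})

test_that("peaks are plateau-grouped strict local maxima within a region", {
  r <- matrix(c(0, 4, 2, 3, 0, 0, 0), 1, 7)
  pk <- findPeaks(r, cbind(1, 2:4))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk[, "col"], c(2, 4))
  expect_equal(pk[, "amplitudeUM"], c(4, 3))
  ## single-voxel region: that voxel
  pk1 <- findPeaks(r, cbind(1, 3))
  expect_equal(nrow(pk1), 1L)
  expect_equal(unname(pk1[1, "col"]), 3)
  ## a connected plateau of equal maxima is one peak, smallest (row,col)
  pl <- matrix(c(1, 5, 5, 1), 1, 4)
  pkP <- findPeaks(pl, cbind(1, 1:4))
  expect_equal(nrow(pkP), 1L)
  expect_equal(unname(pkP[1, "col"]), 2)
  ## two separated equal plateaus are two peaks
  pl2 <- matrix(c(5, 1, 5), 1, 3)
  expect_equal(nrow(findPeaks(pl2, cbind(1, 1:3))), 2L)
  ## a plateau with a higher neighbour is not a peak
  pl3 <- matrix(c(2, 2, 3), 1, 3)
  pk3 <- findPeaks(pl3, cbind(1, 1:3))
  expect_equal(nrow(pk3), 1L)
  expect_equal(unname(pk3[1, "col"]), 3)
})

test_that("peak finding matches the exhaustive neighbour-comparison oracle", {
  set.seed(21)
  for (rep in 1:40) {
    g <- randomFrame(10, 10, nBumps = sample(1:3, 1))
    ## quantise to provoke plateaus
    g <- round(g, 1)
    inc <- computeIncrement(g, 50)
    cl <- findClusters(g > inc$mean, 4)
    for (region in cl) {
      for (nb in c(4, 8)) {
        got <- findPeaks(g, region, neighborhood = nb)
        want <- oraclePeaks(g, region, neighborhood = nb)
        expect_equal(unname(got), unname(want))
      }
      expect_gte(nrow(findPeaks(g, region)), 1L)
    }
  }
  ## one smooth Gaussian bump has exactly one peak at its maximum
  h <- 15; w <- 15
  g <- 3 * exp(-(outer((seq_len(h) - 8)^2, (seq_len(w) - 8)^2, "+")) / 8)
  region <- which(g > mean(g), arr.ind = TRUE)
  pk <- findPeaks(g, region)
  expect_equal(nrow(pk), 1L)
  expect_equal(unname(pk[1, c("row", "col")]), c(8, 8))
})

test_that("LCR images partition the lowest bin and count peaks", {
  ## single Gaussian blob: one simple image
  h <- 16; w <- 16
  g1 <- 0.05 + 3 * exp(-(outer((seq_len(h) - 8)^2,
                               (seq_len(w) - 8)^2, "+")) / 8)
  inc <- computeIncrement(g1, 50)
  ims <- buildLCRImages(g1, buildBins(g1, inc$mean, inc$delta, 50))
  expect_length(ims, 1L)
  expect_equal(ims[[1]]$nPeaks, 1L)
  expect_false(ims[[1]]$isComplex)
  ## two peaks on a shared supra-mean base: one complex image
  g2 <- 0.05 +
    2.5 * exp(-(outer((seq_len(h) - 8)^2, (seq_len(w) - 5)^2, "+")) / 5) +
    2.0 * exp(-(outer((seq_len(h) - 8)^2, (seq_len(w) - 11)^2, "+")) / 5)
  inc2 <- computeIncrement(g2, 50)
  ims2 <- buildLCRImages(g2, buildBins(g2, inc2$mean, inc2$delta, 50))
  expect_length(ims2, 1L)
  expect_equal(ims2[[1]]$nPeaks, 2L)
  expect_true(ims2[[1]]$isComplex)
  ## two blobs separated by sub-mean background: two simple images
  g3 <- matrix(0.01, h, w)
  g3[4:5, 4:5] <- 2; g3[12:13, 12:13] <- 1.5
  inc3 <- computeIncrement(g3, 50)
  ims3 <- buildLCRImages(g3, buildBins(g3, inc3$mean, inc3$delta, 50))
  expect_length(ims3, 2L)
  expect_false(any(vapply(ims3, `[[`, TRUE, "isComplex")))
  ## degenerate uniform frame: no images
  gU <- matrix(0.1, 4, 4)
  incU <- computeIncrement(gU, 50)
  expect_length(buildLCRImages(gU, buildBins(gU, incU$mean, incU$delta, 50)),
                0L)
})

test_that("images are disjoint, cover the lowest bin, and conserve mass", {
  set.seed(31)
  for (rep in 1:15) {
    g <- randomFrame(14, 18)
    inc <- computeIncrement(g, 50)
    bins <- buildBins(g, inc$mean, inc$delta, 50)
    ims <- buildLCRImages(g, bins)
    cover <- matrix(0L, nrow(g), ncol(g))
    for (im in ims) cover[im$voxels] <- cover[im$voxels] + 1L
    expect_true(all(cover[bins$masks[, , 1]] == 1L))   # partition
    expect_true(all(cover[!bins$masks[, , 1]] == 0L))  # nothing outside
    ## conservation: summed image mass = direct supra-mean sum * V_voxel
    total <- sum(vapply(ims, `[[`, 1.0, "signalMassNmol"))
    direct <- sum(g[g > inc$mean]) * 1000 * 1e-18
    expect_equal(total, direct, tolerance = 1e-12)
  }
})

test_that("signal mass uses nmol/L times voxel volume in litres", {
  f <- matrix(0, 3, 3); f[2, 2] <- 1     # one voxel at 1 uM
  expect_equal(imageSignalMass(f, cbind(2, 2), voxelEdgeNm = 100), 1e-15)
  ## voxel volume for a 100 nm edge is 1e-18 L (1 uM = 1000 nmol/L)
  expect_equal((100e-9)^3 * 1000, 1e-18)
  ## doubling the edge multiplies the mass by 8
  expect_equal(imageSignalMass(f, cbind(2, 2), voxelEdgeNm = 200), 8e-15)
  ## random image equals direct summation
  set.seed(5)
  g <- matrix(runif(100, 0, 10), 10, 10)
  vox <- rectVoxels(2:5, 3:7)
  expect_equal(imageSignalMass(g, vox),
               sum(g[vox]) * 1000 * 1e-18, tolerance = 1e-14)
})
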