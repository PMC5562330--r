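## Scripted-mask fixtures: frames are built directly as value matrices so
## every linking decision is forced by construction.

test_that("a transient blob yields one birth and one attrition death", {
  h <- 12; w <- 12
  blob <- rectVoxels(5:7, 5:7)
  frames <- c(list(blobFrame(h, w, rectVoxels(1, 1), 0.02)),  # no event yet
              replicate(4, blobFrame(h, w, blob, 2), simplify = FALSE),
              list(blobFrame(h, w, rectVoxels(1, 1), 0.02)))
  ts <- trackLCRs(stackFromValues(frames))
  tr <- trackTable(ts)
  tr <- tr[tr$nImages > 1, ]            # the blob track
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$birthFrame, 2L)
  expect_equal(tr$deathFrame, 5L)
  expect_equal(tr$termination, "attrition")
  expect_equal(tr$nThreads, 1L)
  ev <- eventLog(ts)
  expect_equal(sum(ev$kind == "birth" & ev$lcrId == tr$lcrId), 1L)
  expect_equal(ev$frame[ev$kind == "death_attrition" & ev$lcrId == tr$lcrId],
               6L)
})

test_that("a collision kills the track with the smaller previous image mass", {
  h <- 16; w <- 24
  ## two single-voxel images with masses 5 and 2 (x1e-15 nmol) ...
  f1 <- blobFrame(h, w, rectVoxels(8, 6), 5)
  f1[8, 18] <- 2
  ## ... both overlapping one strip image in the next frame
  f2 <- blobFrame(h, w, rectVoxels(8, 5:19), 3)
  ts <- trackLCRs(stackFromValues(list(f1, f2)))
  tr <- trackTable(ts)
  expect_equal(nrow(tr), 2L)
  big <- tr[tr$lcrId == 1, ]; small <- tr[tr$lcrId == 2, ]
  expect_equal(small$termination, "collision")
  expect_equal(small$deathFrame, 1L)
  expect_equal(big$termination, "alive_at_end")
  ev <- eventLog(ts)
  coll <- ev[ev$kind == "death_collision", ]
  expect_equal(nrow(coll), 1L)
  expect_equal(coll$lcrId, 2L)          # loser: the 2e-15 nmol image
  expect_equal(coll$otherLcrId, 1L)     # survivor adopts the merged image
  expect_equal(sort(trackImages(ts, 1)), c(1L, 3L))
})

test_that("collision masses compare previous images; ties keep the older track", {
  h <- 16; w <- 24
  f1 <- blobFrame(h, w, rectVoxels(8, 6), 3)
  f1[8, 18] <- 3                        # equal masses
  f2 <- blobFrame(h, w, rectVoxels(8, 5:19), 3)
  ts <- trackLCRs(stackFromValues(list(f1, f2)))
  ev <- eventLog(ts)
  coll <- ev[ev$kind == "death_collision", ]
  expect_equal(coll$lcrId, 2L)
  expect_equal(coll$otherLcrId, 1L)
})

test_that("a three-way collision leaves a single largest-mass survivor", {
  h <- 20; w <- 24
  f1 <- blobFrame(h, w, rectVoxels(6, 12), 2)
  f1[10, 12] <- 4; f1[14, 12] <- 3
  f2 <- blobFrame(h, w, rectVoxels(5:15, 12), 2.5)
  ts <- trackLCRs(stackFromValues(list(f1, f2)))
  tr <- trackTable(ts)
  expect_equal(sum(tr$termination == "collision"), 2L)
  expect_equal(tr$termination[tr$lcrId == 2], "alive_at_end")  # 4e-15 nmol
  ev <- eventLog(ts)
  expect_equal(sort(ev$lcrId[ev$kind == "death_collision"]), c(1L, 3L))
  expect_equal(unique(ev$otherLcrId[ev$kind == "death_collision"]), 2L)
})

test_that("a separation keeps one track and grows threads", {
  h <- 12; w <- 20
  f1 <- blobFrame(h, w, rectVoxels(6, 5:15), 2)
  f2 <- blobFrame(h, w, rectVoxels(6, 4:8), 2)
  f2[6, 12:16] <- 2
  ts <- trackLCRs(stackFromValues(list(f1, f2)))
  tr <- trackTable(ts)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$nThreads, 2L)
  expect_equal(tr$nSeparations, 1L)
  ev <- eventLog(ts)
  expect_equal(sum(ev$kind == "separation"), 1L)
  expect_equal(sum(ev$kind == "birth"), 1L)
  expect_equal(length(trackImages(ts, 1)), 3L)
})

test_that("collision priority strips the loser's pairs before separations", {
  ## Track B (small) overlaps both the collision image X (shared with the
  ## larger track A) and a second image Y. B loses the collision, so its
  ## B-Y pair must be deleted: Y becomes a birth, not a separation of B.
  h <- 16; w <- 28
  f1 <- blobFrame(h, w, rectVoxels(8, 5), 5)      # A: one voxel, mass 5
  f1[8, 12:14] <- 1                               # B: three voxels, mass 3
  ## X spans cols 4..12 (overlaps A at col 5 and B at col 12); Y sits at
  ## col 14 (overlaps B only), with col 13 background keeping X and Y apart
  f2 <- blobFrame(h, w, rectVoxels(8, 4:12), 2)
  f2[8, 14] <- 2
  ts <- trackLCRs(stackFromValues(list(f1, f2)))
  ev <- eventLog(ts)
  expect_equal(sum(ev$kind == "death_collision"), 1L)
  expect_equal(ev$lcrId[ev$kind == "death_collision"], 2L)
  expect_equal(sum(ev$kind == "separation"), 0L)
  ## Y (the image at (8,14)) starts a new track at frame 2
  births2 <- ev[ev$kind == "birth" & ev$frame == 2L, ]
  expect_equal(nrow(births2), 1L)
})

test_that("threads of one track merge without a death", {
  ## split into two threads, then re-merge: one intra-track merge event,
  ## no collision, track survives throughout
  h <- 12; w <- 20
  f1 <- blobFrame(h, w, rectVoxels(6, 5:15), 2)
  f2 <- blobFrame(h, w, rectVoxels(6, 4:8), 2); f2[6, 12:16] <- 2
  f3 <- blobFrame(h, w, rectVoxels(6, 5:15), 2)
  ts <- trackLCRs(stackFromValues(list(f1, f2, f3)))
  tr <- trackTable(ts)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$termination, "alive_at_end")
  ev <- eventLog(ts)
  expect_equal(sum(ev$kind == "separation"), 1L)
  expect_equal(sum(ev$kind == "intra_thread_merge"), 1L)
  expect_equal(sum(ev$kind == "death_collision"), 0L)
})

test_that("a multi-thread track lives until all threads end", {
  out <- renderScenario(makeSplitScenario())
  ts <- trackLCRs(out$stack)
  tr <- trackTable(ts)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$nThreads, 2L)
  expect_equal(tr$nSeparations, 1L)
  ## first thread fades mid-run; the track must survive it
  firstEnd <- out$truth$meta$firstThreadEndsFrame
  lastEnd <- out$truth$meta$lastThreadEndsFrame
  expect_gt(tr$deathFrame, firstEnd)
  expect_equal(tr$deathFrame, lastEnd)
  expect_equal(tr$termination, "attrition")
})

test_that("every image belongs to exactly one track, lifetimes contiguous", {
  scn <- makePopulationScenario(nEvents = 9, height = 36, width = 36,
                                nFrames = 60, seed = 3)
  ts <- trackLCRs(renderScenario(scn)$stack)
  im <- imageTable(ts)
  tr <- trackTable(ts)
  allGids <- sort(unlist(lapply(tr$lcrId, function(id) trackImages(ts, id))))
  expect_identical(allGids, im$gid)          # conservation, no duplicates
  for (id in tr$lcrId) {
    frames <- sort(unique(im$frame[im$gid %in% trackImages(ts, id)]))
    expect_identical(frames, seq(min(frames), max(frames)))  # contiguous
    expect_equal(min(frames), tr$birthFrame[tr$lcrId == id])
  }
})

test_that("tracking is deterministic and classification matches a full scan", {
  scn <- makePopulationScenario(nEvents = 6, height = 30, width = 30,
                                nFrames = 50, seed = 9)
  st <- renderScenario(scn)$stack
  a <- trackLCRs(st); b <- trackLCRs(st)
  expect_identical(trackTable(a), trackTable(b))
  expect_identical(eventLog(a), eventLog(b))
  ## class equals exhaustive scan of member images (incl. merge scenario,
  ## which produces a complex track)
  for (ts in list(a, trackLCRs(renderScenario(makeMergeScenario())$stack))) {
    im <- imageTable(ts)
    want <- vapply(trackTable(ts)$lcrId, function(id)
      if (any(im$isComplex[im$gid %in% trackImages(ts, id)])) "complex"
      else "simple", "")
    expect_identical(unname(classifyTracks(ts)), want)
  }
})

test_that("image pairs require a shared lowest-bin voxel", {
  h <- 8; w <- 8
  f1 <- blobFrame(h, w, rbind(c(2, 2), c(2, 3)), 2)
  f2 <- blobFrame(h, w, rbind(c(2, 3), c(2, 4)), 2)
  is <- detectLCRImages(stackFromValues(list(f1, f2)))
  p <- pairImages(is, 2)
  expect_equal(nrow(p), 1L)              # shared voxel (2,3)
  f3 <- blobFrame(h, w, rbind(c(6, 6), c(6, 7)), 2)
  is2 <- detectLCRImages(stackFromValues(list(f1, f3)))
  expect_equal(nrow(pairImages(is2, 2)), 0L)   # disjoint: no pairs
})
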