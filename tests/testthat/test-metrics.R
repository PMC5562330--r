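test_that("LCR signal mass sums image masses times the frame interval", {
  ## three single-voxel images of 1, 2, 1 uM -> 1, 2, 1 x1e-15 nmol
  h <- 8; w <- 8
  frames <- lapply(c(1, 2, 1), function(v) blobFrame(h, w, rectVoxels(4, 4), v))
  ts <- trackLCRs(stackFromValues(frames, dtMs = 5))
  expect_equal(lcrSignalMass(ts, 1), (1 + 2 + 1) * 1e-15 * 5)  # 2e-14 nmol*ms
  ## single-image track: image mass x dt
  ts1 <- trackLCRs(stackFromValues(frames[2], dtMs = 5))
  im <- imageTable(ts1)
  expect_equal(lcrSignalMass(ts1, 1), im$signalMassNmol[1] * 5)
})

test_that("path area is the union of occupied voxels, not the sum", {
  h <- 12; w <- 14
  ## static 5x10 = 50-voxel blob over 10 frames: 0.5 um^2 at 100 nm edge
  blob <- rectVoxels(4:8, 3:12)
  frames <- replicate(10, blobFrame(h, w, blob, 2), simplify = FALSE)
  ts <- trackLCRs(stackFromValues(frames))
  expect_equal(lcrPathArea(ts, 1), 50 * 0.01)
  ## 120 distinct voxels -> 1.2 um^2
  f1 <- blobFrame(h, w, rectVoxels(2:11, 2:7), 2)     # 60 voxels
  f2 <- blobFrame(h, w, rectVoxels(2:11, 7:13), 2)    # 70, overlap 10
  ts2 <- trackLCRs(stackFromValues(list(f1, f2)))
  expect_equal(lcrPathArea(ts2, 1), 120 * 0.01)
})

test_that("duration counts frames inclusively; birth time from window start", {
  h <- 8; w <- 8
  frames <- c(replicate(4, blobFrame(h, w, rectVoxels(4, 4), 2),
                        simplify = FALSE),
              list(matrix(0.01, h, w)))
  ts <- trackLCRs(stackFromValues(frames, dtMs = 5))
  db <- lcrDurationBirth(ts, 1)
  expect_equal(db$durationMs, 4 * 5)       # alive frames 1..4
  expect_equal(db$birthTimeMs, 0)          # born at window start
  ## single-frame LCR lasts one frame interval, not zero
  fr1 <- list(blobFrame(h, w, rectVoxels(4, 4), 2), matrix(0.01, h, w))
  ts1 <- trackLCRs(stackFromValues(fr1, dtMs = 5))
  expect_equal(lcrDurationBirth(ts1, 1)$durationMs, 5)
})

test_that("per-track metrics match independent recomputation from the stack", {
  scn <- makePopulationScenario(nEvents = 6, height = 30, width = 30,
                                nFrames = 50, seed = 17)
  st <- renderScenario(scn)$stack
  ts <- trackLCRs(st)
  met <- lcrMetrics(ts)
  for (id in met$lcrId) {
    want <- oracleTrackMetrics(ts, st, id)
    row <- met[met$lcrId == id, ]
    expect_equal(row$signalMassNmolMs, want$signalMassNmolMs)
    expect_equal(row$pathAreaUm2, want$pathAreaUm2)
    expect_equal(row$maxAmplitudeUM, want$maxAmplitudeUM)
    expect_equal(lcrMaxAmplitude(ts, id), want$maxAmplitudeUM)
  }
})

test_that("voxel-edge rescaling scales areas and masses, not counts/durations", {
  scn <- makePopulationScenario(nEvents = 4, height = 24, width = 24,
                                nFrames = 40, seed = 23)
  arr <- frameData(renderScenario(scn)$stack)
  m100 <- lcrMetrics(trackLCRs(FrameStack(arr, voxelEdgeNm = 100)))
  m200 <- lcrMetrics(trackLCRs(FrameStack(arr, voxelEdgeNm = 200)))
  expect_equal(nrow(m200), nrow(m100))
  expect_equal(m200$durationMs, m100$durationMs)
  expect_equal(m200$pathAreaUm2, 4 * m100$pathAreaUm2)
  expect_equal(m200$signalMassNmolMs, 8 * m100$signalMassNmolMs)
})

test_that("summaries are additive across classes and match recomputation", {
  met <- data.frame(
    lcrId = 1:3, class = c("simple", "simple", "complex"),
    signalMassNmolMs = c(1e-15, 2e-15, 9e-15),
    pathAreaUm2 = c(0.1, 0.2, 1.5), maxAmplitudeUM = c(1, 2, 8),
    durationMs = c(5, 10, 60), birthTimeMs = c(0, 25, 40),
    birthFrame = c(1, 6, 9), nThreads = c(1, 1, 2),
    nSeparations = c(0, 0, 1),
    termination = c("attrition", "attrition", "alive_at_end"))
  s <- summarizeLCRs(met, excludeFrame0Births = FALSE)$summary
  expect_equal(s$count[s$class == "all"], 3)
  expect_equal(s$count[s$class == "all"],
               s$count[s$class == "simple"] + s$count[s$class == "complex"])
  expect_equal(s$totalSignalMassNmolMs[s$class == "all"],
               s$totalSignalMassNmolMs[s$class == "simple"] +
               s$totalSignalMassNmolMs[s$class == "complex"])
  expect_equal(s$signalMassPerLcrNmolMs[s$class == "all"], 12e-15 / 3)
  expect_equal(s$avgDurationMs[s$class == "simple"], 7.5)
  ## frame-1 births excluded from birth-time stats only
  s2 <- summarizeLCRs(met, excludeFrame0Births = TRUE)$summary
  expect_equal(s2$count[s2$class == "all"], 3)               # still counted
  expect_equal(s2$avgBirthTimeMs[s2$class == "simple"], 25)  # lcr 1 dropped
  ## empty input: zero-count table, no error
  s0 <- summarizeLCRs(met[0, ], excludeFrame0Births = FALSE)$summary
  expect_equal(s0$count, c(0, 0, 0))
})

test_that("histogram counts agree with the summarized population", {
  scn <- makePopulationScenario(nEvents = 8, height = 36, width = 36,
                                nFrames = 60, seed = 29)
  ts <- trackLCRs(renderScenario(scn)$stack)
  met <- lcrMetrics(ts)
  out <- summarizeLCRs(met, eventLog(ts), excludeFrame0Births = FALSE)
  hAll <- out$histograms$all
  expect_equal(sum(hAll$birthTime$count), nrow(met))
  expect_equal(sum(out$histograms$simple$birthTime$count),
               sum(met$class == "simple"))
  ## birth-time bins are 25 ms wide by default
  expect_equal(unique(diff(hAll$birthTime$binStartMs)), 25)
})

test_that("complex collision counting follows the configured rule", {
  ts <- trackLCRs(renderScenario(makeMergeScenario())$stack)
  met <- lcrMetrics(ts)
  outS <- summarizeLCRs(met, eventLog(ts), complexCollisionRule = "survivor")
  ## the merged survivor carries two peaks, so the collision is complex
  expect_equal(outS$totalComplexCollisions, 1L)
  outE <- summarizeLCRs(met, eventLog(ts), complexCollisionRule = "either")
  expect_gte(outE$totalComplexCollisions, outS$totalComplexCollisions)
})
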