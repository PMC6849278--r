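test_that("a clean template beat is detected at its construction time", {
  g <- ElectrodeGrid(2, 2, 5)
  # uniform wave: every channel activates 200 ms after the stimulus
  rec <- simulateRecording(g, focalWave(1e9, c(2.5, 2.5), onsetDelay = 200),
                           beatTrainSpec(pacingRate = 60, nBeats = 2),
                           fs = 500)
  maps <- detectActivationTimes(bandpassFilter(rec),
                                segmentBeats(rec, window = 500))
  for (m in maps)
    expect_equal(activationTimes(m), rep(200, 4), tolerance = 2 / 500)
})

test_that("a planar wave along columns yields the 5 ms column delay on every row", {
  rec <- cleanPlanarRecording()  # 11x11, 5 mm, 100 cm/s along x, 2048 Hz
  maps <- detectActivationTimes(bandpassFilter(rec), segmentBeats(rec))
  atm <- atMatrix(maps[[1]])
  expect_equal(as.numeric(diff(t(atm))), rep(5, 110), tolerance = 0.1)
})

test_that("listed bad channels are invalid in every beat; dead channels fail the floor", {
  g <- ElectrodeGrid(6, 8, 5, badChannels = c(2, 6))
  rec <- cleanPlanarRecording(grid = g, fs = 500, nBeats = 3,
                              noiseSd = 0.02, seed = 4)
  maps <- detectActivationTimes(bandpassFilter(rec), segmentBeats(rec))
  dead <- (2 - 1) * 8 + 6
  for (m in maps) {
    expect_false(validChannels(m)[dead])
    expect_true(is.na(activationTimes(m)[dead]))
    expect_true(all(validChannels(m)[-dead]))
  }
  # a channel that is pure noise (not listed) must fail the amplitude floor
  x <- samples(rec)
  set.seed(8)
  x[, 1] <- rnorm(nrow(x), sd = 0.02)
  noisy <- UegRecording(x, 500, electrodeGrid(rec),
                        pacingTimes = pacingTimes(rec))
  m <- detectActivationTimes(bandpassFilter(noisy),
                             segmentBeats(noisy))[[1]]
  expect_false(validChannels(m)[1])
})

test_that("shifting all stimulus times leaves relative activation times unchanged", {
  rec <- cleanPlanarRecording(grid = ElectrodeGrid(6, 8, 5), fs = 500,
                              nBeats = 2)
  shifted <- shiftRecording(rec, 500)
  m0 <- detectActivationTimes(bandpassFilter(rec), segmentBeats(rec))[[1]]
  m1 <- detectActivationTimes(bandpassFilter(shifted),
                              segmentBeats(shifted))[[1]]
  expect_equal(activationTimes(m1), activationTimes(m0),
               tolerance = 1e-6)
})

test_that("activation detection tolerates realistic noise", {
  # noise at 5% of QRS amplitude: median AT error stays below 2 samples
  rec <- cleanPlanarRecording(noiseSd = 0.05, seed = 99)
  maps <- detectActivationTimes(bandpassFilter(rec), segmentBeats(rec))
  errs <- unlist(lapply(maps, function(m)
    abs(activationTimes(m) - groundTruth(rec))))
  expect_lt(median(errs, na.rm = TRUE), 2 * 1000 / 2048)
})

test_that("arrival delays growing across recordings are seen as monotone arrival times", {
  arr <- vapply(c(130, 140, 152), function(onset) {
    rec <- cleanPlanarRecording(onsetDelay = onset,
                                grid = ElectrodeGrid(6, 8, 5), fs = 500,
                                nBeats = 1)
    m <- detectActivationTimes(bandpassFilter(rec), segmentBeats(rec))[[1]]
    arrivalTime(m)
  }, numeric(1))
  expect_true(all(diff(arr) > 0))
})

test_that("isochrone level assignment is the analytic one", {
  g <- ElectrodeGrid(6, 8, 5)
  # all electrodes simultaneous: a single level containing everything
  iso0 <- buildIsochrones(mapFromAT(g, rep(150, 48)), interval = 10)
  expect_length(isochroneLevels(iso0), 1L)
  expect_equal(arrivalTime(iso0), 150)
  expect_true(all(regionAssignment(iso0) == 1L))

  # linear ramp 130 -> 180 ms along columns, 10 ms interval -> 5 levels,
  # boundaries parallel to the rows of constant AT
  ramp <- 130 + (channelLabels(g)[, "col"] - 1) / 7 * 50
  iso <- buildIsochrones(mapFromAT(g, ramp), interval = 10)
  expect_length(isochroneLevels(iso), 5L)
  ra <- matrix(regionAssignment(iso), 6, 8, byrow = TRUE)
  # each column falls in exactly one level; levels increase along x
  expect_true(all(apply(ra, 2, function(v) length(unique(v)) == 1L)))
  expect_true(!is.unsorted(ra[1, ]))
  expect_equal(ceiling((max(ramp) - min(ramp)) / 10), 5)
})

test_that("isochrones of a planar wave run orthogonal to propagation", {
  g <- ElectrodeGrid(11, 11, 5)
  dir <- c(1, 1) / sqrt(2)
  at <- groundTruthAT(planarWave(80, dir, onsetDelay = 150), g)
  iso <- buildIsochrones(mapFromAT(g, at), interval = 10)
  ra <- regionAssignment(iso)
  pos <- electrodePositions(g)
  # within a level, positions project onto a narrow band along `dir`
  for (lev in unique(ra)) {
    proj <- pos[ra == lev, , drop = FALSE] %*% dir
    expect_lte(diff(range(proj)), 10 * 80 / 100 + 1e-9)  # interval * speed
  }
})

test_that("maps with fewer than 3 valid electrodes are not constructible", {
  g <- ElectrodeGrid(2, 2, 5)
  at <- c(100, 105, NA, NA)
  expect_error(buildIsochrones(mapFromAT(g, at)), "fewer than 3")
})
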