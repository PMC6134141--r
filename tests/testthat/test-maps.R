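mkMovie <- function(arr, fps = 10)
  new("Movie", frames = arr, frameRateHz = fps, channel = "green")

test_that("pixel correlations match the centroid and flag constants", {
  fps <- 10
  sp <- stimulusWindowSpec(preS = 1, postS = 2)  # 30-frame window
  ctr <- sin(seq(0, 4 * pi, length.out = 30))
  arr <- array(1, c(100, 4, 4))
  onset <- 5                                      # frames 41:70
  arr[41:70, 2, 2] <- 10 + ctr
  arr[41:70, 3, 3] <- 4 - 2 * ctr
  m <- eventPixelCorrelation(mkMovie(arr), ctr, onset, sp)
  expect_equal(m[2, 2], 1)
  expect_equal(m[3, 3], -1)
  expect_true(is.na(m[1, 1]))                     # constant pixel flagged
  expect_error(eventPixelCorrelation(mkMovie(arr), ctr[1:10], onset, sp),
               "window")
  # matches the brute-force Pearson oracle on random pixels
  set.seed(41)
  arr2 <- array(runif(100 * 4 * 4), c(100, 4, 4))
  m2 <- eventPixelCorrelation(mkMovie(arr2), ctr, onset, sp)
  for (i in 1:4) for (j in 1:4)
    expect_equal(m2[i, j], bruteForcePearson(arr2[41:70, i, j], ctr),
                 tolerance = 1e-10)
})

test_that("event maps average with NA flag propagation", {
  m1 <- matrix(c(0.5, NA, 0.2, NA), 2)
  m2 <- matrix(c(0.7, NA, -0.2, 0.4), 2)
  avg <- averageEventMaps(list(m1, m2))
  v <- mapValues(avg)
  expect_equal(v[1, 1], 0.6)
  expect_equal(v[1, 2], 0)          # +r and -r cancel
  expect_equal(v[2, 2], 0.4)        # defined in one event only
  expect_true(is.na(v[2, 1]))       # undefined everywhere stays undefined
  expect_equal(avg@nEvents, 2L)
  same <- averageEventMaps(list(m2, m2))
  expect_equal(mapValues(same), m2)
})

test_that("maps are invariant to affine intensity rescaling", {
  set.seed(42)
  arr <- array(runif(60 * 3 * 3), c(60, 3, 3))
  sp <- stimulusWindowSpec(preS = 1, postS = 2)
  ctr <- rnorm(30)
  m1 <- eventPixelCorrelation(mkMovie(arr), ctr, 3, sp)
  m2 <- eventPixelCorrelation(mkMovie(2.5 * arr + 7), ctr, 3, sp)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("cross-larva combination is an event-count weighted mean", {
  mk <- function(v, n) new("CorrelationMap", values = matrix(v, 2, 2),
                           clusterId = 1L, larvaId = "x",
                           nEvents = as.integer(n))
  a <- 0.8; b <- 0.2
  comb <- combineAcrossLarvae(list(mk(a, 10), mk(b, 30)))
  expect_equal(mapValues(comb)[1, 1], (10 * a + 30 * b) / 40)
  expect_equal(comb@nEvents, 40L)
  one <- combineAcrossLarvae(list(mk(0.5, 7)))
  expect_equal(mapValues(one), matrix(0.5, 2, 2))
  eq <- combineAcrossLarvae(list(mk(0.3, 5), mk(0.3, 50)), weights = c(9, 1))
  expect_equal(mapValues(eq), matrix(0.3, 2, 2))
  expect_error(combineAcrossLarvae(list(mk(0.3, 5)), weights = -1), "weights")
})

test_that("in-footprint pixels light up for the matching cluster map", {
  ex <- smallExperiment(seed = 12L, noise = zeroNoise())
  dur <- trialDuration(ex$schedule)
  sp <- stimulusWindowSpec()
  ev <- selectEvents(ex$schedule, sp, dur)
  raw <- extractRoiTraces(ex$cleanGreen, ex$scene@footprints)
  ids <- which(ex$scene@archetypes == "stim_on")
  avg <- t(vapply(ids, function(i) triggeredAverage(
    extractWindows(dff(raw[i, ], 5.81), ev, sp, 5.81)),
    numeric(round(15 * 5.81))))
  ctr <- colMeans(avg)
  map <- clusterCorrelationMap(ex$cleanGreen, ctr, ev, sp)
  inFp <- Reduce("|", lapply(ex$scene@footprints[ids], function(f) f > 0))
  otherFp <- Reduce("|", lapply(ex$scene@footprints[-ids], function(f) f > 0))
  v <- mapValues(map)
  expect_gt(mean(v[inFp], na.rm = TRUE), mean(v[otherFp], na.rm = TRUE))
  expect_gte(min(v[inFp], na.rm = TRUE), 0.99)
  # noise-free background pixels have zero variance: flagged undefined
  # (the 2 px filter smears footprints, so test far-from-ROI pixels)
  farBg <- !spatialMeanFilter(new("Movie",
    frames = array(inFp | otherFp, c(1, dim(v))), frameRateHz = 1,
    channel = "green"), 2L)@frames[1, , ] > 0
  expect_true(all(is.na(v[farBg])))
})
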