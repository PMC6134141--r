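test_that("generation is bit-reproducible under a fixed seed", {
  a <- smallExperiment(seed = 3L)
  b <- smallExperiment(seed = 3L)
  expect_identical(a$tail@angles, b$tail@angles)
  expect_identical(frames(a$green), frames(b$green))
  expect_identical(frames(a$red), frames(b$red))
  expect_identical(a$dffTruth, b$dffTruth)
  c0 <- smallExperiment(seed = 4L)
  expect_false(identical(frames(a$green), frames(c0$green)))
})

test_that("zero bout rates give a flat noise trace with no bouts", {
  sch <- makeSchedule(60, 10, 5)
  gen <- generateTailTrace(sch, params = boutParams(
    rateMotionHz = 0, rateStaticHz = 0, onsetBoostHz = 0), seed = 1L)
  expect_equal(nrow(gen$bouts), 0L)
  expect_lt(max(abs(gen$trace@angles)), 5)
})

test_that("a planted bout carries the expected oscillation count", {
  sch <- makeSchedule(30, 10, 5)
  gen <- generateTailTrace(sch, params = boutParams(noiseSdDeg = 0),
                           seed = 2L)
  skipIf <- nrow(gen$bouts) == 0
  expect_false(skipIf)
  b1 <- gen$bouts[1L, ]
  sel <- gen$trace@times >= b1$start_s & gen$trace@times < b1$end_s
  x <- gen$trace@angles[sel]
  # ~20 Hz beat over the bout duration: zero crossings = 2 * cycles
  zc <- sum(diff(sign(x[x != 0])) != 0)
  expectCycles <- 20 * (b1$end_s - b1$start_s)
  expect_equal(zc / 2, expectCycles, tolerance = 0.15)
})

test_that("bouts are initiated preferentially during stimulus motion", {
  sch <- makeSchedule(315, 10, 5)
  nM <- 0; nS <- 0
  for (s in 1:10) {
    gen <- generateTailTrace(sch, seed = s)
    mot <- inMotion(sch, gen$bouts$start_s)
    nM <- nM + sum(mot); nS <- nS + sum(!mot)
  }
  # per-second rate contrast (210 s motion vs 105 s static per trial)
  expect_gt((nM / 210) / (nS / 105), 2)
})

test_that("with zero noise all fluorescence variance sits inside footprints", {
  ex <- smallExperiment(seed = 6L, noise = zeroNoise())
  f <- frames(ex$green)
  inFp <- Reduce("|", lapply(ex$scene@footprints, function(fp) fp > 0))
  v <- apply(f, c(2L, 3L), stats::var)
  expect_equal(max(v[!inFp]), 0)
  expect_gt(max(v[inFp]), 0)
})

test_that("a lone swim-locked transient matches direct convolution", {
  sch <- makeSchedule(60, 10, 5)
  scene <- makeScene(frameShape = c(32L, 32L),
                     nPerArchetype = c(swim_locked = 1L), bleedFactor = 0,
                     seed = 2L)
  bouts <- data.frame(start_s = 20, end_s = 20.3)
  mv <- generateMovie(scene, sch, bouts, noise = zeroNoise(), seed = 1L)
  k <- sampleKernel(calciumKernel(), 5.81)
  drive <- numeric(floor(60 * 5.81))
  drive[floor(20 * 5.81) + 1L] <- 1
  expect_equal(as.vector(mv$dffTruth[1L, ]),
               1.2 * bruteForceConv(drive, k), tolerance = 1e-12)
  # pixel trace at the footprint peak reproduces the transient shape
  fp <- scene@footprints[[1L]]
  pk <- which(fp == max(fp), arr.ind = TRUE)[1L, ]
  px <- frames(mv$cleanGreen)[, pk[1L], pk[2L]]
  expect_equal(bruteForcePearson(px, mv$dffTruth[1L, ]), 1, tolerance = 1e-9)
})

test_that("a stim-suppressed ROI is minimal exactly during motion", {
  sch <- makeSchedule(90, 10, 5)
  scene <- makeScene(frameShape = c(32L, 32L),
                     nPerArchetype = c(stim_suppressed = 1L),
                     bleedFactor = 0, seed = 3L)
  mv <- generateMovie(scene, sch, data.frame(start_s = numeric(0),
                                             end_s = numeric(0)),
                      noise = zeroNoise(), seed = 1L)
  # skip the initial kernel-settling ramp before comparing regimes
  settled <- mv$frameTimes > 15
  tr <- mv$dffTruth[1L, settled]
  mot <- inMotion(sch, mv$frameTimes[settled])
  expect_lt(mean(tr[mot]), mean(tr[!mot]))
  # global minimum falls inside a motion interval (the causal kernel has
  # zero instantaneous response, so allow a one-frame lag)
  tMin <- mv$frameTimes[settled][which.min(tr)]
  expect_true(any(inMotion(sch, c(tMin, tMin - 1 / 5.81))))
})

test_that("empty scenes render a constant-baseline movie", {
  sch <- makeSchedule(15, 10, 5)
  scene <- makeScene(frameShape = c(16L, 16L),
                     nPerArchetype = c(swim_locked = 0L), bleedFactor = 0,
                     seed = 1L)
  mv <- generateMovie(scene, sch, data.frame(start_s = numeric(0),
                                             end_s = numeric(0)),
                      noise = zeroNoise(), seed = 1L)
  f <- frames(mv$cleanGreen)
  expect_equal(max(f) - min(f), 0)
})

test_that("scene validity enforces unit-sum footprints and archetypes", {
  expect_error(makeScene(nPerArchetype = c(banana = 3L)), "archetype")
  sc <- makeScene(frameShape = c(32L, 32L),
                  nPerArchetype = c(stim_on = 2L), seed = 1L)
  expect_true(validObject(sc))
  expect_equal(vapply(sc@footprints, sum, numeric(1)), c(1, 1))
  expect_error(generateMovie(sc, makeSchedule(15, 10, 5),
                             data.frame(start_s = 20, end_s = 20.2),
                             seed = 1L),
               "within the trial")
})
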