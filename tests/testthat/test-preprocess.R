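makeMovie <- function(arr, fps = 5.81, channel = "green")
  new("Movie", frames = arr, frameRateHz = fps, channel = channel)

test_that("a planted bleed-through slope is recovered exactly", {
  set.seed(1)
  red <- array(rexp(10 * 8 * 8, 1 / 50), c(10, 8, 8))
  green <- makeMovie(0.3 * red)
  expect_equal(estimateBleedthrough(green, makeMovie(red, channel = "red")),
               0.3, tolerance = 1e-10)
})

test_that("an all-zero red channel fails estimation", {
  z <- array(0, c(5, 4, 4))
  g <- makeMovie(array(runif(80), c(5, 4, 4)))
  expect_error(estimateBleedthrough(g, makeMovie(z, channel = "red")),
               "estimation failed")
})

test_that("the simulated bleed factor is recovered within tolerance", {
  exZ <- smallExperiment(seed = 9L, noise = zeroNoise())
  expect_equal(estimateBleedthrough(exZ$green, exZ$red), 0.15,
               tolerance = 1e-6)
  ex <- smallExperiment(seed = 9L)
  expect_lt(abs(estimateBleedthrough(ex$green, ex$red) - 0.15), 0.02)
})

test_that("bleed-through correction subtracts, clips and is idempotent", {
  set.seed(2)
  red <- array(rexp(10 * 8 * 8, 1 / 50), c(10, 8, 8))
  redM <- makeMovie(red, channel = "red")
  green <- makeMovie(0.3 * red)
  expect_identical(frames(correctBleedthrough(green, redM, 0)),
                   frames(green))
  corr <- correctBleedthrough(green, redM, 0.3)
  expect_equal(max(abs(frames(corr))), 0)
  expect_true(all(frames(correctBleedthrough(green, redM, 1)) >= 0))
  # re-estimating on corrected data finds ~no residual bleed
  base <- array(100, c(10, 8, 8))
  obs <- makeMovie(base + 0.25 * red)
  corr2 <- correctBleedthrough(obs, redM, 0.25)
  expect_lt(estimateBleedthrough(corr2, redM), 1e-8)
  expect_error(correctBleedthrough(green,
    makeMovie(array(0, c(10, 4, 4)), channel = "red"), 0.1), "shape")
})

test_that("dF/F matches fixed-baseline arithmetic and is gain-invariant", {
  expect_equal(dff(rep(7, 100), 5.81), rep(0, 100))
  raw <- rep(100, 200); raw[100] <- 150
  expect_equal(max(dff(raw, 5.81, method = "fixed", f0 = 100)), 0.5)
  set.seed(3)
  raw2 <- 100 + cumsum(rnorm(300))
  raw2 <- raw2 - min(raw2) + 50
  expect_equal(dff(raw2 * 2, 5.81), dff(raw2, 5.81), tolerance = 1e-12)
  expect_error(dff(c(0, 0, 0), 5.81), "degenerate")
})

test_that("quiet-mean baseline uses only samples outside events", {
  raw <- c(rep(100, 50), rep(150, 50))
  quiet <- c(rep(TRUE, 50), rep(FALSE, 50))
  d <- dff(raw, 5.81, method = "quiet_mean", quietMask = quiet)
  expect_equal(d[60], 0.5)
  expect_error(dff(raw, 5.81, method = "quiet_mean",
                   quietMask = rep(FALSE, 100)), "quiet")
})

test_that("the 2x2 spatial mean filter matches hand computation", {
  fr <- array(0, c(1, 5, 5))
  m <- makeMovie(fr + 3)
  expect_equal(frames(spatialMeanFilter(m, 2L)), frames(m))
  imp <- array(0, c(1, 5, 5))
  imp[1, 3, 3] <- 1
  out <- frames(spatialMeanFilter(makeMovie(imp), 2L))[1, , ]
  # top-left anchored 2x2 kernel: pixels (2,2),(2,3),(3,2),(3,3) = 1/4
  expect_equal(out[2:3, 2:3], matrix(0.25, 2, 2))
  expect_equal(sum(out), 1)
})

test_that("spatial filtering is purely per-frame (commutes with permutation)", {
  set.seed(4)
  arr <- array(runif(6 * 7 * 5), c(6, 7, 5))
  p <- sample(6)
  f1 <- frames(spatialMeanFilter(makeMovie(arr), 2L))[p, , ]
  f2 <- frames(spatialMeanFilter(makeMovie(arr[p, , ]), 2L))
  expect_equal(f1, f2)
})

test_that("ROI trace extraction is a footprint-weighted mean", {
  arr <- array(5, c(4, 6, 6))
  fp <- matrix(0, 6, 6); fp[2:3, 2:3] <- 1
  tr <- extractRoiTraces(makeMovie(arr), list(fp))
  expect_equal(as.vector(tr), rep(5, 4))
  expect_error(extractRoiTraces(makeMovie(arr), list(matrix(0, 6, 6))),
               "empty")
  # zero-noise planted scene: extracted trace correlates 1 with truth
  ex <- smallExperiment(seed = 7L, noise = zeroNoise())
  raw <- extractRoiTraces(ex$cleanGreen, ex$scene@footprints)
  active <- which(ex$scene@archetypes != "silent")
  for (i in active[1:4])
    expect_equal(bruteForcePearson(raw[i, ], ex$dffTruth[i, ]), 1,
                 tolerance = 1e-9)
  # disjoint footprints keep traces independent across ROIs
  fp2 <- matrix(0, 6, 6); fp2[5:6, 5:6] <- 1
  arr2 <- arr; arr2[, 2:3, 2:3] <- 99
  tr2 <- extractRoiTraces(makeMovie(arr2), list(fp, fp2))
  expect_equal(as.vector(tr2[2L, ]), rep(5, 4))
})
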