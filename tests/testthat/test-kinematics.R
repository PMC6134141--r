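test_that("bend angle reproduces hand-computed geometry", {
  ax <- c(1, 0)
  expect_equal(bendAngle(tailPoints(0), ax), 0)
  # tip offset perpendicular at equal axial distance: atan2(1, 1) = 45
  pts <- tailPoints(0)
  pts[9L, ] <- c(8, 8)
  expect_equal(bendAngle(pts, ax), 45)
  # mirror image flips the sign, same magnitude
  ptsM <- pts
  ptsM[, 2L] <- -ptsM[, 2L]
  expect_equal(bendAngle(ptsM, ax), -45)
  expect_error(bendAngle(matrix(1, 9L, 2L), ax), "coincide")
})

test_that("bend angle is equivariant under rigid rotation", {
  set.seed(11)
  for (i in 1:20) {
    pts <- tailPoints(runif(1, -170, 170))
    pts[2:8, 2L] <- rnorm(7, 0, 0.3)
    ax <- c(1, 0)
    a0 <- bendAngle(pts, ax)
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    expect_equal(bendAngle(pts %*% t(R), as.vector(R %*% ax)), a0,
                 tolerance = 1e-10)
  }
})

test_that("a 20 Hz sinusoid over 1 s yields exactly 40 extrema", {
  fs <- 250
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  tr <- tailTrace(30 * sin(2 * pi * 20 * tt), rateHz = fs)
  pk <- detectDeflections(tr, minAmplitudeDeg = 5)
  expect_equal(nrow(pk), 40L)
  expect_equal(sum(pk$angle_deg > 0), 20L)
  # alternating signs throughout
  expect_true(all(diff(sign(pk$angle_deg)) != 0))
})

test_that("deflection detection respects the amplitude threshold", {
  fs <- 250
  tt <- seq(0, 1, by = 1 / fs)
  low <- tailTrace(3 * sin(2 * pi * 20 * tt), rateHz = fs)
  expect_equal(nrow(detectDeflections(low, minAmplitudeDeg = 5)), 0L)
  flat <- tailTrace(rep(0, 100), rateHz = fs)
  expect_equal(nrow(detectDeflections(flat)), 0L)
})

test_that("peaks group into bouts by the intra-bout gap rule", {
  expect_equal(nrow(extractBouts(data.frame(time_s = numeric(0),
                                            angle_deg = numeric(0)))), 0L)
  pk <- data.frame(time_s = c(1.00, 1.05, 1.10, 2.00, 2.04),
                   angle_deg = c(20, -18, 15, 25, -22))
  b <- extractBouts(pk, maxIntraboutGapS = 0.1, padS = 0.02)
  expect_equal(nrow(b), 2L)
  expect_equal(b$n_peaks, c(3L, 2L))
  expect_equal(b$start_s, c(0.98, 1.98))
  expect_equal(b$end_s, c(1.12, 2.06))
  # disjoint and sorted with non-negative interbout durations
  expect_true(all(b$end_s[-nrow(b)] <= b$start_s[-1L]))
})

test_that("exclusion flags mark struggles and tracking failures", {
  fs <- 250
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  ang <- rep(0, length(tt))
  ang[tt >= 1 & tt < 1.2] <- 170 * sin(2 * pi * 20 * (tt[tt >= 1 & tt < 1.2]))
  ang[tt >= 2 & tt < 2.2] <- 30 * sin(2 * pi * 20 * (tt[tt >= 2 & tt < 2.2]))
  tr <- tailTrace(ang, rateHz = fs)
  b <- findBouts(tr)
  expect_equal(nrow(b), 2L)
  expect_equal(b$reason, c("struggle", "none"))
  # a bout sitting on missing frames is a tracking failure
  ang2 <- ang
  ang2[tt >= 2.05 & tt < 2.15] <- NA
  b2 <- flagExclusions(extractBouts(detectDeflections(
    tailTrace(ang, rateHz = fs))), tailTrace(ang2, rateHz = fs),
    nanFraction = 0.05)
  expect_equal(b2$reason[2L], "tracking_failure")
})

test_that("planted bouts are recovered from synthetic traces", {
  sch <- makeSchedule(315, 10, 5)
  gen <- generateTailTrace(sch, seed = 5L)
  b <- findBouts(gen$trace)
  b <- b[!b$excluded, ]
  m <- matchBouts(gen$bouts$start_s, b$start_s, tol = 0.02)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("tracked points round-trip into a bend-angle trace", {
  n <- 50L
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- tailPoints(ifelse(i > 25, 30, 0))
    data.frame(t_s = (i - 1) / 250, t(p[, 1L]), t(p[, 2L]))
  }))
  names(pts) <- c("t_s", paste0("x", 0:8), paste0("y", 0:8))
  tr <- tailTraceFromPoints(pts, bodyAxis = c(1, 0))
  expect_s4_class(tr, "TailTrace")
  expect_equal(tr@rateHz, 250)
  expect_equal(tr@angles[1:25], rep(0, 25), tolerance = 1e-8)
  expect_equal(tr@angles[26:50], rep(30, 25), tolerance = 1e-8)
})
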