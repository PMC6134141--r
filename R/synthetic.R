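#' Calcium indicator kernel
#'
#' @param riseTau rise time constant in seconds.
#' @param decayTau decay time constant in seconds.
#' @return a [CalciumKernel].
#' @export
calciumKernel <- function(riseTau = 0.05, decayTau = 1.0) {
  new("CalciumKernel", riseTau = riseTau, decayTau = decayTau)
}

#' Sample a calcium kernel on a frame grid
#'
#' Evaluates `exp(-t/decayTau) - exp(-t/riseTau)` at `t = 0, dt, 2*dt,
#' ...` out to `lengthS` (default five decay constants) and normalises
#' to unit peak.
#'
#' @param kernel a [CalciumKernel].
#' @param rateHz sampling rate in Hz.
#' @param lengthS kernel support in seconds.
#' @return numeric vector, peak value 1.
#' @export
sampleKernel <- function(kernel, rateHz, lengthS = 5 * kernel@decayTau) {
  stopifnot(is(kernel, "CalciumKernel"), rateHz > 0)
  t <- seq(0, lengthS, by = 1 / rateHz)
  k <- exp(-t / kernel@decayTau) - exp(-t / kernel@riseTau)
  k / max(k)
}

# causal convolution of a drive with a sampled kernel, truncated to the
# drive's length
.convCausal <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  nz <- which(x != 0)
  for (i in nz) {
    j <- i:min(n, i + length(k) - 1L)
    out[j] <- out[j] + x[i] * k[seq_along(j)]
  }
  out
}

#' Default bout-statistics parameters for the generator
#'
#' Bout statistics are model inputs chosen to emulate restrained larval
#' optomotor swimming: bouts are initiated far more often during grating
#' motion than during static presentation, with an extra burst of
#' initiations shortly after motion onset (the optomotor response
#' latency), ~20 Hz tail-beat frequency and ~0.3 s bout duration.
#'
#' @param rateMotionHz sustained bout initiation rate during motion.
#' @param rateStaticHz bout initiation rate during static periods.
#' @param onsetBoostHz extra initiation rate at motion onset.
#' @param onsetBoostTauS decay constant of the onset boost (s).
#' @param durMeanS,durSdS bout duration mean / sd (s, truncated > 0.1).
#' @param beatHz tail-beat frequency within a bout.
#' @param amplitudeDeg peak bend-angle amplitude (degrees).
#' @param refractoryS minimum quiescence between bouts (s).
#' @param noiseSdDeg sd of the inter-bout baseline angle noise.
#' @return named list of parameters.
#' @export
boutParams <- function(rateMotionHz = 0.08, rateStaticHz = 0.05,
                       onsetBoostHz = 2.6, onsetBoostTauS = 0.5,
                       durMeanS = 0.3, durSdS = 0.06, beatHz = 20,
                       amplitudeDeg = 30, refractoryS = 1.5,
                       noiseSdDeg = 0.5) {
  if (rateMotionHz < rateStaticHz)
    .stopf("bout rate during motion must be >= the static rate")
  if (any(c(rateMotionHz, rateStaticHz, onsetBoostHz) < 0))
    .stopf("bout rates must be >= 0")
  list(rateMotionHz = rateMotionHz, rateStaticHz = rateStaticHz,
       onsetBoostHz = onsetBoostHz, onsetBoostTauS = onsetBoostTauS,
       durMeanS = durMeanS, durSdS = durSdS, beatHz = beatHz,
       amplitudeDeg = amplitudeDeg, refractoryS = refractoryS,
       noiseSdDeg = noiseSdDeg)
}

#' Generate a synthetic tail trace with planted bouts
#'
#' Bout onsets follow an inhomogeneous Poisson process (thinned on a
#' fine grid) whose rate is `rateStaticHz` during static periods and
#' `rateMotionHz + onsetBoostHz * exp(-latency/onsetBoostTauS)` during
#' motion, with a refractory period between bouts. Each bout is an
#' amplitude-enveloped sinusoid at the tail-beat frequency (root-Hann
#' envelope: fast attack, smooth decay); the inter-bout baseline is
#' white Gaussian angle noise.
#'
#' @param schedule a [StimulusSchedule].
#' @param rateHz behaviour sampling rate (Hz).
#' @param params list from [boutParams()].
#' @param seed integer seed; fixed seed gives a bit-identical trace.
#' @return list with `trace` (a [TailTrace]) and `bouts` (data.frame
#'   `start_s`, `end_s` of the planted bouts).
#' @export
generateTailTrace <- function(schedule, rateHz = 250, params = boutParams(),
                              seed = 1L) {
  stopifnot(is(schedule, "StimulusSchedule"))
  if (rateHz <= 0) .stopf("rateHz must be positive")
  dur <- trialDuration(schedule)
  iv <- motionIntervals(schedule)
  .withSeed(seed, {
    # bout onset times by thinning on a 5 ms grid
    dt <- 0.005
    grid <- seq(0, dur, by = dt)
    rate <- rep(params$rateStaticHz, length(grid))
    for (i in seq_len(nrow(iv))) {
      inIv <- grid >= iv[i, 1L] & grid < iv[i, 2L]
      lat <- grid[inIv] - iv[i, 1L]
      rate[inIv] <- params$rateMotionHz +
        params$onsetBoostHz * exp(-lat / params$onsetBoostTauS)
    }
    hit <- runif(length(grid)) < rate * dt
    cand <- grid[hit]
    starts <- numeric(0); ends <- numeric(0)
    lastEnd <- -Inf
    for (tc in cand) {
      if (tc < lastEnd + params$refractoryS) next
      d <- max(0.1, rnorm(1, params$durMeanS, params$durSdS))
      if (tc + d >= dur) next
      starts <- c(starts, tc); ends <- c(ends, tc + d)
      lastEnd <- tc + d
    }
    n <- round(dur * rateHz)
    tt <- (seq_len(n) - 1) / rateHz
    ang <- rnorm(n, 0, params$noiseSdDeg)
    for (i in seq_along(starts)) {
      sel <- which(tt >= starts[i] & tt < ends[i])
      if (!length(sel)) next
      s <- (tt[sel] - starts[i]) / (ends[i] - starts[i])
      env <- sqrt(sin(pi * s))    # fast attack, smooth decay
      ang[sel] <- ang[sel] + params$amplitudeDeg * env *
        sin(2 * pi * params$beatHz * (tt[sel] - starts[i]))
    }
    list(trace = new("TailTrace", times = tt, angles = ang, rateHz = rateHz,
                     provenance = "direct"),
         bouts = data.frame(start_s = starts, end_s = ends))
  })
}

# one truncated 2-D Gaussian footprint (unit sum) at centre (r0, c0)
.gaussFootprint <- function(frameShape, r0, c0, sigma) {
  fp <- matrix(0, frameShape[1L], frameShape[2L])
  rad <- 2 * sigma
  rr <- max(1L, floor(r0 - rad)):min(frameShape[1L], ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(frameShape[2L], ceiling(c0 + rad))
  for (r in rr) for (cl in cc) {
    d2 <- (r - r0)^2 + (cl - c0)^2
    if (d2 <= rad^2) fp[r, cl] <- exp(-d2 / (2 * sigma^2))
  }
  fp / sum(fp)
}

# non-overlapping blob centres: jittered grid sites, shuffled. Grid
# spacing is chosen so that truncated footprints (radius 2*sigma) can
# never touch even at maximal jitter.
.placeCentres <- function(frameShape, n, sigma, jitter = 1) {
  sep <- ceiling(4 * sigma + 2 * jitter) + 1L
  margin <- ceiling(2 * sigma) + 1L
  rs <- seq(margin, frameShape[1L] - margin, by = sep)
  cs <- seq(margin, frameShape[2L] - margin, by = sep)
  sites <- expand.grid(r = rs, c = cs)
  if (nrow(sites) < n)
    .stopf("frame %dx%d cannot hold %d non-overlapping ROIs of sigma %.1f",
           frameShape[1L], frameShape[2L], n, sigma)
  sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  sites$r <- sites$r + runif(n, -jitter, jitter)
  sites$c <- sites$c + runif(n, -jitter, jitter)
  sites
}

#' Build a synthetic imaging scene
#'
#' Places non-overlapping truncated-Gaussian ROI footprints on the frame
#' (jittered-grid placement, which guarantees capacity at the default
#' desk-scale geometry) and assigns each ROI an activity archetype.
#'
#' @param frameShape (rows, cols) in pixels; the default 128 x 64 keeps
#'   simulations desk-scale (a 512 x 249 preset mirrors full acquisition
#'   geometry).
#' @param nPerArchetype named integer vector of ROI counts per archetype.
#' @param sigmaPx footprint Gaussian sd in pixels (truncated at 2 sd).
#' @param bleedFactor red-to-green bleed-through factor.
#' @param seed integer seed.
#' @return a [SyntheticScene].
#' @export
makeScene <- function(frameShape = c(128L, 64L),
                      nPerArchetype = c(swim_locked = 20L, stim_on = 20L,
                                        mixed = 20L, stim_suppressed = 20L),
                      sigmaPx = 1.4, bleedFactor = 0.15, seed = 1L) {
  frameShape <- as.integer(frameShape)
  bad <- setdiff(names(nPerArchetype), .ARCHETYPES)
  if (length(bad)) .stopf("unknown archetype(s): %s", paste(bad, collapse = ", "))
  n <- sum(nPerArchetype)
  .withSeed(seed, {
    ctr <- .placeCentres(frameShape, n, sigmaPx)
    fps <- lapply(seq_len(n), function(i)
      .gaussFootprint(frameShape, ctr$r[i], ctr$c[i], sigmaPx))
    arch <- rep(names(nPerArchetype), times = nPerArchetype)
    new("SyntheticScene", frameShape = frameShape, footprints = fps,
        archetypes = arch, bleedFactor = bleedFactor,
        seed = as.integer(seed))
  })
}

#' Noise model parameters for the movie generator
#'
#' Poisson shot noise on photon-scaled intensities plus additive
#' Gaussian read noise. `photonsPerUnit = Inf` disables shot noise;
#' `readSd = 0` disables read noise.
#'
#' @param photonsPerUnit photons per intensity unit (shot-noise scale).
#' @param readSd read-noise standard deviation (intensity units).
#' @return named list.
#' @export
noiseParams <- function(photonsPerUnit = 2, readSd = 2) {
  if (photonsPerUnit <= 0 || readSd < 0) .stopf("invalid noise parameters")
  list(photonsPerUnit = photonsPerUnit, readSd = readSd)
}

#' Zero-noise parameter set
#' @return list disabling both noise sources.
#' @export
zeroNoise <- function() list(photonsPerUnit = Inf, readSd = 0)

# archetype drive signals on the imaging frame grid.
# frameMid: frame midpoint times; boutStarts: planted/observed onsets.
# mixed ROIs are sensorimotor onset cells: they respond to the first
# bout of each motion period (independently per ROI with probability
# mixedBoutProb) on top of a weak visual drive, so each mixed ROI gets
# an idiosyncratic impulse train; uses the caller's RNG stream.
.archetypeDrives <- function(archetypes, schedule, boutStarts, frameMid,
                             frameRateHz, mixedSwimW, mixedStimW,
                             mixedBoutProb = 0.85) {
  nT <- length(frameMid)
  impulseFor <- function(starts) {
    imp <- numeric(nT)
    # the impulse lands in the frame containing the bout onset; the
    # epsilon keeps frame-boundary onsets deterministic under floating
    # point
    idx <- pmin(nT, pmax(1L, floor(starts * frameRateHz + 1e-9) + 1L))
    for (i in idx) imp[i] <- imp[i] + 1
    imp
  }
  impulse <- impulseFor(boutStarts)
  boxcar <- as.numeric(inMotion(schedule, frameMid))
  # first bout initiated within each motion interval
  iv <- motionIntervals(schedule)
  onsetBouts <- numeric(0)
  for (i in seq_len(nrow(iv))) {
    inIv <- boutStarts[boutStarts >= iv[i, 1L] & boutStarts < iv[i, 2L]]
    if (length(inIv)) onsetBouts <- c(onsetBouts, min(inIv))
  }
  lapply(archetypes, function(a) switch(a,
    swim_locked = impulse,
    stim_on = boxcar,
    mixed = {
      sel <- runif(length(onsetBouts)) < mixedBoutProb
      mixedSwimW * impulseFor(onsetBouts[sel]) + mixedStimW * boxcar
    },
    stim_suppressed = pmax(1 - boxcar, 0),
    silent = numeric(nT)))
}

#' Render a two-channel synthetic movie
#'
#' Each ROI's archetype drive (impulse train at bout onsets for
#' `swim_locked`; a boxcar over motion intervals for `stim_on`; a
#' weighted sum of both for `mixed`, whose impulse train covers the
#' initial bout of each motion period - sensorimotor onset cells -
#' rather than every bout; tonic baseline minus the boxcar, floored at
#' zero, for `stim_suppressed`) is convolved with the calcium kernel,
#' scaled onto a fluorescence baseline and projected through its
#' footprint. Sustained responses are normalised to unit peak after
#' convolution so `dffGain` sets a comparable peak dF/F across
#' archetypes. The red channel carries static anatomy: a diffuse
#' baseline with a smooth gradient plus bright red-only blobs disjoint
#' from all green footprints (these red-dominated, green-quiet
#' structures are what makes the bleed-through factor identifiable from
#' a red-vs-green pixel scatter). When `scene@bleedFactor > 0` the
#' observed green channel is `clean green + bleedFactor * red`. Noise is
#' Poisson shot noise plus Gaussian read noise per [noiseParams()].
#'
#' @param scene a [SyntheticScene].
#' @param schedule the [StimulusSchedule] the trial used.
#' @param bouts planted bout table (`start_s`, `end_s`).
#' @param kernel a [CalciumKernel].
#' @param frameRateHz imaging frame rate (Hz).
#' @param noise list from [noiseParams()] or [zeroNoise()].
#' @param seed integer seed (noise and red anatomy).
#' @param baselineF per-ROI fluorescence baseline (intensity units).
#' @param dffGain peak-normalised activity-to-dF/F gain.
#' @param backgroundF background intensity outside all footprints.
#' @param mixedSwimW,mixedStimW drive weights of the `mixed` archetype.
#' @param mixedBoutProb probability that a mixed ROI responds to any
#'   given bout (each mixed ROI draws its own bout subset).
#' @return list with `green`, `red` ([Movie]s, green includes
#'   bleed-through), `cleanGreen` (noise-free, bleed-free [Movie]),
#'   `dffTruth` (ROIs x frames matrix of noiseless dF/F), `drives`
#'   (list of drive vectors) and `frameTimes` (frame midpoints, s).
#' @export
generateMovie <- function(scene, schedule, bouts, kernel = calciumKernel(),
                          frameRateHz = 5.81, noise = noiseParams(),
                          seed = 1L, baselineF = 100, dffGain = 1.2,
                          backgroundF = 20, mixedSwimW = 1.3,
                          mixedStimW = 0.15, mixedBoutProb = 0.85) {
  stopifnot(is(scene, "SyntheticScene"), is(schedule, "StimulusSchedule"))
  if (nrow(bouts) > 0 && (any(bouts$start_s < 0) ||
                          any(bouts$end_s > trialDuration(schedule))))
    .stopf("bouts must lie within the trial")
  nT <- floor(trialDuration(schedule) * frameRateHz)
  frameMid <- (seq_len(nT) - 0.5) / frameRateHz
  k <- sampleKernel(kernel, frameRateHz)
  drives <- .withSeed(.subSeed(seed, 11L),
    .archetypeDrives(scene@archetypes, schedule,
                     bouts$start_s, frameMid, frameRateHz,
                     mixedSwimW, mixedStimW, mixedBoutProb))
  nR <- length(scene@footprints)
  # sustained responses (boxcar, tonic-suppressed) are normalised to
  # unit peak after convolution so dffGain sets a comparable peak dF/F
  # for every archetype (a lone bout transient already peaks at 1)
  boxcar <- as.numeric(inMotion(schedule, frameMid))
  normConv <- function(x) {
    y <- .convCausal(x, k)
    m <- max(y)
    if (m > 0) y / m else y
  }
  basisStim <- normConv(boxcar)
  basisSup <- normConv(pmax(1 - boxcar, 0))
  act <- vapply(seq_len(nR), function(r) {
    switch(scene@archetypes[r],
      swim_locked = .convCausal(drives[[r]], k),
      stim_on = basisStim,
      stim_suppressed = basisSup,
      silent = numeric(nT),
      mixed = {
        # split the drive back into its components so the boxcar part
        # is rendered on the same normalised scale as stim_on
        .convCausal(drives[[r]] - mixedStimW * boxcar, k) +
          mixedStimW * basisStim
      })
  }, numeric(nT))
  if (nR == 0L) act <- matrix(0, nT, 0L)
  dffTruth <- t(act) * dffGain                            # nR x nT
  shape <- scene@frameShape
  nP <- prod(shape)
  # footprints as a pixels x ROIs matrix, peak-normalised for rendering
  fpMat <- matrix(0, nP, nR)
  for (r in seq_len(nR)) {
    fp <- scene@footprints[[r]]
    fpMat[, r] <- as.vector(fp) / max(fp)
  }
  Froi <- baselineF * (1 + t(dffTruth))                   # nT x nR
  pix <- matrix(backgroundF, nT, nP)
  if (nR > 0L) pix <- pix + Froi %*% t(fpMat)
  .withSeed(.subSeed(seed, 7L), {
    # red anatomy: diffuse baseline with a smooth gradient, plus bright
    # red-only blobs placed away from every green footprint. Keeping the
    # red structures green-quiet is what makes the bleed-through factor
    # identifiable from red-dominated pixels.
    grad <- matrix(rep(seq(0, 15, length.out = shape[2L]),
                       each = shape[1L]), shape[1L], shape[2L])
    redImg <- 10 + grad
    occupied <- matrix(FALSE, shape[1L], shape[2L])
    for (fp in scene@footprints) occupied <- occupied | (fp > 0)
    nBlob <- 12L
    tries <- 0L
    placed <- 0L
    while (placed < nBlob && tries < 1000L) {
      tries <- tries + 1L
      r0 <- runif(1, 5, shape[1L] - 4)
      c0 <- runif(1, 5, shape[2L] - 4)
      blob <- .gaussFootprint(shape, r0, c0, 1.6)
      if (any(occupied[blob > 0])) next
      redImg <- redImg + 200 * blob / max(blob)
      occupied <- occupied | (blob > 0)
      placed <- placed + 1L
    }
    redPix <- matrix(rep(as.vector(redImg), each = nT), nT, nP)
    greenObs <- pix + scene@bleedFactor * redPix
    addNoise <- function(m) {
      if (is.finite(noise$photonsPerUnit))
        m <- matrix(rpois(length(m), m * noise$photonsPerUnit) /
                      noise$photonsPerUnit, nrow(m), ncol(m))
      if (noise$readSd > 0)
        m <- m + matrix(rnorm(length(m), 0, noise$readSd), nrow(m), ncol(m))
      pmax(m, 0)
    }
    greenObs <- addNoise(greenObs)
    redPix <- addNoise(redPix)
    toMovie <- function(m, ch) new("Movie",
      frames = array(m, c(nT, shape[1L], shape[2L])),
      frameRateHz = frameRateHz, channel = ch)
    list(green = toMovie(greenObs, "green"),
         red = toMovie(redPix, "red"),
         cleanGreen = toMovie(pix, "green"),
         dffTruth = dffTruth,
         drives = drives,
         frameTimes = frameMid)
  })
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: builds the schedule, tail trace and scene, and
#' renders the two-channel movie, returning everything including ground
#' truth. This is the canonical entry point for generating test data.
#'
#' @param seed integer master seed (sub-seeds are derived per stage).
#' @param trialDuration,motionS,staticS schedule parameters (s).
#' @param frameShape movie geometry (rows, cols).
#' @param nPerArchetype ROI counts per archetype (see [makeScene()]).
#' @param bout list from [boutParams()].
#' @param kernel a [CalciumKernel].
#' @param frameRateHz imaging frame rate (Hz).
#' @param behaviourRateHz tail-camera rate (Hz).
#' @param noise list from [noiseParams()] / [zeroNoise()].
#' @param bleedFactor red-to-green bleed-through factor.
#' @param ... further arguments to [generateMovie()].
#' @return list with `schedule`, `tail` (TailTrace), `plantedBouts`,
#'   `scene`, and all [generateMovie()] outputs.
#' @export
simulateExperiment <- function(seed = 1L, trialDuration = 315, motionS = 10,
                               staticS = 5, frameShape = c(128L, 64L),
                               nPerArchetype = c(swim_locked = 20L,
                                                 stim_on = 20L, mixed = 20L,
                                                 stim_suppressed = 20L),
                               bout = boutParams(),
                               kernel = calciumKernel(), frameRateHz = 5.81,
                               behaviourRateHz = 250,
                               noise = noiseParams(), bleedFactor = 0.15,
                               ...) {
  schedule <- makeSchedule(trialDuration, motionS, staticS)
  tl <- generateTailTrace(schedule, behaviourRateHz, bout,
                          seed = .subSeed(seed, 1L))
  scene <- makeScene(frameShape, nPerArchetype, bleedFactor = bleedFactor,
                     seed = .subSeed(seed, 2L))
  mv <- generateMovie(scene, schedule, tl$bouts, kernel, frameRateHz,
                      noise, seed = .subSeed(seed, 3L), ...)
  c(list(schedule = schedule, tail = tl$trace, plantedBouts = tl$bouts,
         scene = scene), mv)
}
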