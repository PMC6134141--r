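#' Estimate the red-to-green bleed-through factor
#'
#' Leakage of the red fluorophore's emission into the green channel is
#' modelled as `green = clean + factor * red`. The factor is the slope
#' of a robust (Theil-Sen) fit of time-averaged green pixel values
#' against red pixel values, restricted to red-dominated pixels (above
#' the red channel's `redQuantile` quantile), where the green signal is
#' background plus leakage. The pairwise-median slope is insensitive to
#' the unknown intercept and to a minority of green-active outliers.
#'
#' @param green,red co-registered [Movie]s of identical shape.
#' @param redQuantile quantile defining red-dominated pixels.
#' @param maxPoints cap on pixels entering the pairwise fit (quantile-
#'   spaced along red intensity, so the subsample is deterministic).
#' @return estimated factor (>= 0).
#' @export
estimateBleedthrough <- function(green, red, redQuantile = 0.9,
                                 maxPoints = 400L) {
  stopifnot(is(green, "Movie"), is(red, "Movie"))
  if (!all(dim(frames(green)) == dim(frames(red))))
    .stopf("green and red movies must have identical shape")
  gAvg <- apply(frames(green), c(2L, 3L), mean)
  rAvg <- apply(frames(red), c(2L, 3L), mean)
  thr <- quantile(rAvg, redQuantile)
  sel <- which(rAvg >= thr & rAvg > 0)
  r <- as.vector(rAvg)[sel]
  g <- as.vector(gAvg)[sel]
  if (length(sel) < 2L || diff(range(r)) == 0)
    .stopf("bleed-through estimation failed: no red-dominated pixel spread")
  o <- order(r)
  r <- r[o]; g <- g[o]
  if (length(r) > maxPoints) {
    pick <- unique(round(seq(1L, length(r), length.out = maxPoints)))
    r <- r[pick]; g <- g[pick]
  }
  dr <- outer(r, r, "-")
  dg <- outer(g, g, "-")
  keep <- upper.tri(dr) & dr != 0
  slope <- median(dg[keep] / dr[keep])
  max(0, slope)
}

#' Subtract scaled red channel from the green channel
#'
#' `out = max(green - factor * red, 0)` per pixel per frame
#' (fluorescence is non-negative, so the difference is clipped at 0).
#'
#' @param green,red [Movie]s of identical shape.
#' @param factor bleed-through factor (>= 0).
#' @return corrected green [Movie].
#' @export
correctBleedthrough <- function(green, red, factor) {
  stopifnot(is(green, "Movie"), is(red, "Movie"))
  if (!all(dim(frames(green)) == dim(frames(red))))
    .stopf("green and red movies must have identical shape")
  if (factor < 0) .stopf("bleed-through factor must be >= 0")
  new("Movie", frames = pmax(frames(green) - factor * frames(red), 0),
      frameRateHz = frameRate(green), channel = "green")
}

#' Fractional fluorescence change (dF/F)
#'
#' Computes `(F - F0) / F0` for one raw fluorescence trace. The default
#' baseline `F0` is a running 10th percentile over a sliding window
#' (robust to activity-dense trials); alternatively `F0` is the mean of
#' samples outside all supplied event windows, or a fixed value.
#'
#' @param raw numeric raw fluorescence trace.
#' @param frameRateHz sampling rate (needed for the sliding window).
#' @param method `"sliding_percentile"`, `"quiet_mean"`, or `"fixed"`.
#' @param windowS sliding window length in seconds.
#' @param percentile baseline percentile within the window.
#' @param strideS spacing of baseline evaluation points in seconds,
#'   linearly interpolated between them; 0 (default) evaluates the
#'   window percentile at every frame. A stride of ~1 s is a cheap
#'   approximation when the baseline only drifts slowly.
#' @param quietMask logical vector marking samples outside all stimulus
#'   and bout windows (required for `"quiet_mean"`).
#' @param f0 fixed baseline (required for `"fixed"`).
#' @return numeric dF/F trace.
#' @export
dff <- function(raw, frameRateHz, method = c("sliding_percentile",
                                             "quiet_mean", "fixed"),
                windowS = 30, percentile = 0.1, strideS = 0,
                quietMask = NULL, f0 = NULL) {
  method <- match.arg(method)
  raw <- as.numeric(raw)
  f0v <- switch(method,
    sliding_percentile = {
      n <- length(raw)
      w <- max(3L, round(windowS * frameRateHz))
      half <- w %/% 2L
      stride <- max(1L, round(strideS * frameRateHz))
      centres <- unique(c(seq(1L, n, by = stride), n))
      q <- vapply(centres, function(i)
        quantile(raw[max(1L, i - half):min(n, i + half)], percentile,
                 names = FALSE), numeric(1))
      if (length(centres) == 1L) rep(q, n)
      else approx(centres, q, xout = seq_len(n))$y
    },
    quiet_mean = {
      if (is.null(quietMask) || length(quietMask) != length(raw))
        .stopf("quiet_mean baseline requires a quietMask of trace length")
      if (!any(quietMask)) .stopf("quietMask marks no quiet samples")
      rep(mean(raw[quietMask]), length(raw))
    },
    fixed = {
      if (is.null(f0)) .stopf("fixed baseline requires f0")
      rep(f0, length(raw))
    })
  f0v <- as.numeric(f0v)
  if (any(f0v <= 0))
    .stopf("degenerate baseline: F0 <= 0 (raw fluorescence must be positive)")
  (raw - f0v) / f0v
}

#' Spatial mean filter of every frame
#'
#' Applies an `sizePx` x `sizePx` uniform mean kernel to each frame
#' independently (anchored at the top-left pixel: the output at (i, j)
#' averages the block `i..i+sizePx-1`, `j..j+sizePx-1`). Edges are
#' handled by nearest-pixel replication, so a constant frame is
#' unchanged.
#'
#' @param movie a [Movie].
#' @param sizePx kernel edge length in pixels (>= 1).
#' @return filtered [Movie].
#' @export
spatialMeanFilter <- function(movie, sizePx = 2L) {
  stopifnot(is(movie, "Movie"))
  sizePx <- as.integer(sizePx)
  if (sizePx < 1L) .stopf("sizePx must be >= 1")
  if (sizePx == 1L) return(movie)
  f <- frames(movie)
  d <- dim(f)
  nr <- d[2L]; nc <- d[3L]
  ri <- pmin(outer(seq_len(nr), 0:(sizePx - 1L), "+"), nr)   # replicate edge
  ci <- pmin(outer(seq_len(nc), 0:(sizePx - 1L), "+"), nc)
  out <- array(0, d)
  for (t in seq_len(d[1L])) {
    fr <- matrix(f[t, , ], nr, nc)
    acc <- matrix(0, nr, nc)
    for (a in seq_len(sizePx)) for (b in seq_len(sizePx))
      acc <- acc + fr[ri[, a], ci[, b]]
    out[t, , ] <- acc / (sizePx * sizePx)
  }
  new("Movie", frames = out, frameRateHz = frameRate(movie),
      channel = movie@channel)
}

#' Extract raw ROI traces through spatial footprints
#'
#' For each ROI, the trace is the footprint-weighted mean of pixel
#' intensities per frame. This is deliberately simple plumbing: the
#' pipeline accepts footprints and traces from any source extractor,
#' and the synthetic generator supplies ground-truth footprints.
#'
#' @param movie a [Movie].
#' @param footprints list of non-negative weight matrices matching the
#'   frame shape.
#' @return ROIs x frames numeric matrix of raw traces.
#' @export
extractRoiTraces <- function(movie, footprints) {
  stopifnot(is(movie, "Movie"))
  f <- frames(movie)
  d <- dim(f)
  nP <- d[2L] * d[3L]
  W <- matrix(0, nP, length(footprints))
  for (i in seq_along(footprints)) {
    fp <- footprints[[i]]
    if (!all(dim(fp) == d[2:3]))
      .stopf("footprint %d does not match the frame shape", i)
    s <- sum(fp)
    if (s <= 0) .stopf("footprint %d is empty", i)
    W[, i] <- as.vector(fp) / s
  }
  pix <- matrix(f, d[1L], nP)    # frames x pixels
  t(pix %*% W)                   # ROIs x frames
}
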