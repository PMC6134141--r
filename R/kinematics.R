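#' Construct a tail bend-angle trace
#'
#' @param angles bend angles in degrees (`NA` marks tracking failures).
#' @param rateHz sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @param provenance `"direct"` or `"tracked_points"`.
#' @return a [TailTrace].
#' @export
tailTrace <- function(angles, rateHz = 250, t0 = 0, provenance = "direct") {
  new("TailTrace", times = t0 + (seq_along(angles) - 1) / rateHz,
      angles = as.numeric(angles), rateHz = rateHz, provenance = provenance)
}

#' Signed tail-bend angle of one tracked frame
#'
#' The bend angle is defined between the caudal end of the swim bladder
#' (first tracked point) and the tip of the tail (last point): the
#' signed angle, in degrees, between the resting body axis and the
#' bladder-to-tip vector. Positive angles are leftward deflections
#' viewed from below (counter-clockwise in image coordinates).
#'
#' @param points 9 x 2 matrix of tracked (x, y) pixel coordinates from
#'   swim bladder to tail tip (8 tail segments).
#' @param bodyAxis length-2 vector, the resting head-to-tail direction.
#' @return signed angle in degrees, in `(-180, 180]`; `NA` if any
#'   coordinate is missing.
#' @export
bendAngle <- function(points, bodyAxis) {
  points <- as.matrix(points)
  if (nrow(points) != 9L || ncol(points) != 2L)
    .stopf("points must be a 9 x 2 matrix (swim bladder to tail tip)")
  if (anyNA(points)) return(NA_real_)
  v <- points[9L, ] - points[1L, ]
  if (sum(v^2) == 0)
    .stopf("swim bladder and tail tip coincide: bend angle undefined")
  if (length(bodyAxis) != 2L || sum(bodyAxis^2) == 0)
    .stopf("bodyAxis must be a non-zero 2-D vector")
  # signed angle from bodyAxis to v (ccw positive)
  ang <- unname(atan2(bodyAxis[1L] * v[2L] - bodyAxis[2L] * v[1L],
                      bodyAxis[1L] * v[1L] + bodyAxis[2L] * v[2L])) *
    180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bend-angle trace from tracked tail points
#'
#' Converts a per-frame table of 9 tracked points into a [TailTrace].
#' When `bodyAxis` is not supplied it is estimated as the direction from
#' the median swim-bladder position to the median tail-tip position over
#' all tracked frames (the resting axis, since deflections average out).
#' Runs of more than `maxInterpFrames` consecutive missing frames are
#' kept as `NA`; shorter gaps are linearly interpolated.
#'
#' @param pts data.frame with columns `t_s`, `x0..x8`, `y0..y8`
#'   (point 0 = swim bladder, point 8 = tail tip).
#' @param bodyAxis optional length-2 resting axis vector.
#' @param maxInterpFrames longest missing run to interpolate across.
#' @return a [TailTrace] with provenance `"tracked_points"`.
#' @export
tailTraceFromPoints <- function(pts, bodyAxis = NULL, maxInterpFrames = 3L) {
  need <- c("t_s", paste0("x", 0:8), paste0("y", 0:8))
  if (!all(need %in% names(pts)))
    .stopf("points table must have columns t_s, x0..x8, y0..y8")
  xs <- as.matrix(pts[, paste0("x", 0:8)])
  ys <- as.matrix(pts[, paste0("y", 0:8)])
  if (is.null(bodyAxis)) {
    p0 <- c(median(xs[, 1L], na.rm = TRUE), median(ys[, 1L], na.rm = TRUE))
    p8 <- c(median(xs[, 9L], na.rm = TRUE), median(ys[, 9L], na.rm = TRUE))
    bodyAxis <- p8 - p0
    if (sum(bodyAxis^2) == 0)
      .stopf("cannot estimate body axis: median bladder and tip coincide")
  }
  n <- nrow(pts)
  ang <- vapply(seq_len(n), function(i) {
    p <- cbind(xs[i, ], ys[i, ])
    if (anyNA(p)) return(NA_real_)
    bendAngle(p, bodyAxis)
  }, numeric(1))
  # interpolate only short tracking gaps
  if (anyNA(ang) && any(!is.na(ang))) {
    filled <- zoo::na.approx(ang, na.rm = FALSE, maxgap = maxInterpFrames)
    ang <- as.numeric(filled)
  }
  dt <- median(diff(pts$t_s))
  new("TailTrace", times = pts$t_s, angles = ang, rateHz = 1 / dt,
      provenance = "tracked_points")
}

#' Detect alternating tail-deflection extrema
#'
#' Finds local maxima and minima of the bend-angle trace whose absolute
#' angle reaches `minAmplitudeDeg`, enforcing alternation: of two
#' same-sign extrema closer than `minInterpeakS`, the smaller (in
#' absolute angle) is dropped. These deflection peaks are the raw
#' material for bout segmentation.
#'
#' @param trace a [TailTrace] (uniformly sampled).
#' @param minAmplitudeDeg amplitude threshold in degrees.
#' @param minInterpeakS minimum separation of same-sign peaks (s).
#' @return data.frame with columns `time_s`, `angle_deg`.
#' @export
detectDeflections <- function(trace, minAmplitudeDeg = 5,
                              minInterpeakS = 0.01) {
  stopifnot(is(trace, "TailTrace"))
  x <- trace@angles
  tt <- trace@times
  empty <- data.frame(time_s = numeric(0), angle_deg = numeric(0))
  if (length(x) < 3L) return(empty)
  ok <- !is.na(x)
  # local extrema on finite runs: sign of slope changes
  d <- diff(x)
  s <- sign(d)
  # carry the previous non-zero slope through flat runs
  for (i in seq_along(s))
    if (!is.na(s[i]) && s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(!is.na(s[-length(s)]) & !is.na(s[-1L]) &
                 s[-length(s)] != s[-1L]) + 1L
  idx <- idx[ok[idx] & abs(x[idx]) >= minAmplitudeDeg]
  if (length(idx) == 0L) return(empty)
  # drop the smaller of same-sign neighbours that crowd minInterpeakS
  keep <- rep(TRUE, length(idx))
  repeat {
    ids <- idx[keep]
    if (length(ids) < 2L) break
    gaps <- diff(tt[ids])
    sg <- sign(x[ids])
    bad <- which(gaps < minInterpeakS & sg[-length(sg)] == sg[-1L])
    if (length(bad) == 0L) break
    b <- bad[1L]
    drop_i <- if (abs(x[ids[b]]) < abs(x[ids[b + 1L]])) b else b + 1L
    keep[which(keep)[drop_i]] <- FALSE
  }
  idx <- idx[keep]
  data.frame(time_s = tt[idx], angle_deg = x[idx])
}

#' Group deflection peaks into swim bouts
#'
#' Consecutive peaks separated by at most `maxIntraboutGapS` belong to
#' the same bout; bout boundaries are the first/last peak time padded by
#' `padS` and clipped to the trace extent. Bouts are half-open
#' `[start_s, end_s)`, disjoint and time-sorted; if padding would make
#' neighbours overlap the boundary is clipped at the midpoint.
#'
#' @param peaks data.frame from [detectDeflections()].
#' @param maxIntraboutGapS largest within-bout inter-peak gap (s).
#' @param padS padding added before the first / after the last peak (s).
#' @param traceRange length-2 vector clipping bout boundaries (s).
#' @return data.frame with one row per bout: `start_s`, `end_s`,
#'   `n_peaks`, `max_abs_angle_deg`, `excluded` (logical), `reason`, and
#'   a list-column `peaks` holding each bout's peak table.
#' @export
extractBouts <- function(peaks, maxIntraboutGapS = 0.1, padS = 0.02,
                         traceRange = c(-Inf, Inf)) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_peaks = integer(0), max_abs_angle_deg = numeric(0),
                      excluded = logical(0), reason = character(0))
  empty$peaks <- list()
  if (nrow(peaks) == 0L) return(empty)
  o <- order(peaks$time_s)
  peaks <- peaks[o, , drop = FALSE]
  grp <- cumsum(c(1, diff(peaks$time_s) > maxIntraboutGapS))
  sp <- split(peaks, grp)
  start <- vapply(sp, function(p) min(p$time_s), numeric(1)) - padS
  end <- vapply(sp, function(p) max(p$time_s), numeric(1)) + padS
  start <- pmax(start, traceRange[1L])
  end <- pmin(end, traceRange[2L])
  if (length(start) > 1L) {           # keep bouts disjoint if pads collide
    for (i in seq_len(length(start) - 1L)) {
      if (end[i] > start[i + 1L]) {
        mid <- (end[i] + start[i + 1L]) / 2
        end[i] <- mid; start[i + 1L] <- mid
      }
    }
  }
  out <- data.frame(
    start_s = start, end_s = end,
    n_peaks = vapply(sp, nrow, integer(1)),
    max_abs_angle_deg = vapply(sp, function(p) max(abs(p$angle_deg)),
                               numeric(1)),
    excluded = FALSE, reason = "none", row.names = NULL)
  out$peaks <- unname(sp)
  out
}

#' Flag bouts for exclusion
#'
#' Marks bouts overlapping tracking gaps (fraction of `NA` angles within
#' the bout above `nanFraction`) as `tracking_failure`, and bouts whose
#' largest deflection exceeds `struggleAmplitudeDeg` as `struggle`
#' (escape/struggle movements are not analysed as swim bouts). Flagged
#' bouts are retained in the table but must be excluded from event
#' selection, which [selectEvents()] does automatically.
#'
#' @param bouts bout table from [extractBouts()].
#' @param trace the [TailTrace] the bouts were extracted from.
#' @param struggleAmplitudeDeg amplitude ceiling for normal swims (deg).
#' @param nanFraction tolerated missing-sample fraction within a bout.
#' @return the bout table with `excluded` / `reason` filled in.
#' @export
flagExclusions <- function(bouts, trace, struggleAmplitudeDeg = 100,
                           nanFraction = 0.05) {
  stopifnot(is(trace, "TailTrace"))
  if (nrow(bouts) == 0L) return(bouts)
  for (i in seq_len(nrow(bouts))) {
    sel <- trace@times >= bouts$start_s[i] & trace@times < bouts$end_s[i]
    fracNA <- if (any(sel)) mean(is.na(trace@angles[sel])) else 0
    if (fracNA > nanFraction) {
      bouts$excluded[i] <- TRUE
      bouts$reason[i] <- "tracking_failure"
    } else if (bouts$max_abs_angle_deg[i] > struggleAmplitudeDeg) {
      bouts$excluded[i] <- TRUE
      bouts$reason[i] <- "struggle"
    }
  }
  bouts
}

#' Full bout extraction from a bend-angle trace
#'
#' Convenience wrapper chaining [detectDeflections()], [extractBouts()]
#' and [flagExclusions()] with a single parameter list.
#'
#' @param trace a [TailTrace].
#' @param params named list overriding any of `minAmplitudeDeg`,
#'   `minInterpeakS`, `maxIntraboutGapS`, `padS`, `struggleAmplitudeDeg`,
#'   `nanFraction`.
#' @return bout table (see [extractBouts()]).
#' @export
findBouts <- function(trace, params = list()) {
  p <- modifyList(list(minAmplitudeDeg = 5, minInterpeakS = 0.01,
                       maxIntraboutGapS = 0.1, padS = 0.02,
                       struggleAmplitudeDeg = 100, nanFraction = 0.05),
                  params)
  pk <- detectDeflections(trace, p$minAmplitudeDeg, p$minInterpeakS)
  b <- extractBouts(pk, p$maxIntraboutGapS, p$padS,
                    traceRange = range(trace@times))
  flagExclusions(b, trace, p$struggleAmplitudeDeg, p$nanFraction)
}

#' Write a bout table to CSV
#'
#' @param bouts bout table.
#' @param path output file.
#' @export
writeBoutTable <- function(bouts, path) {
  cols <- c("start_s", "end_s", "n_peaks", "max_abs_angle_deg",
            "excluded", "reason")
  write.csv(bouts[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
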