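#' Per-event pixel-wise correlation with a cluster centroid
#'
#' For one event, correlates every pixel's intensity time series within
#' the event window against the cluster centroid. The movie should be
#' spatially mean-filtered first (see [spatialMeanFilter()]); raw
#' filtered intensities are used rather than dF/F because Pearson
#' correlation is invariant to the per-window affine dF/F transform.
#' Pixels with zero variance in the window are undefined and returned
#' as `NA`.
#'
#' @param movie a (filtered) [Movie].
#' @param centroid cluster centroid waveform; its length must equal the
#'   window's frame count.
#' @param eventOnset event onset time in seconds.
#' @param spec the [EventWindowSpec] the centroid was built with.
#' @return rows x cols matrix of correlations (`NA` where undefined).
#' @export
eventPixelCorrelation <- function(movie, centroid, eventOnset, spec) {
  stopifnot(is(movie, "Movie"), is(spec, "EventWindowSpec"))
  fps <- frameRate(movie)
  nPre <- round(spec@preS * fps)
  nPost <- round(spec@postS * fps)
  len <- nPre + nPost
  if (length(centroid) != len)
    .stopf("centroid length %d does not match the %d-frame window",
           length(centroid), len)
  i0 <- round(eventOnset * fps) + 1L
  idx <- (i0 - nPre):(i0 + nPost - 1L)
  f <- frames(movie)
  if (idx[1L] < 1L || idx[len] > dim(f)[1L])
    .stopf("event at %.2f s has a window outside the movie", eventOnset)
  d <- dim(f)
  W <- matrix(f[idx, , ], len, d[2L] * d[3L])
  r <- .colPearson(W, centroid)
  matrix(r, d[2L], d[3L])
}

#' Average per-event correlation images into a final map
#'
#' Per-pixel mean over events, ignoring undefined (`NA`) values; a
#' pixel is undefined in the final map only if it was undefined in
#' every event.
#'
#' @param maps list of rows x cols correlation matrices (common shape).
#' @param clusterId,larvaId identifiers stored on the result.
#' @return a [CorrelationMap].
#' @export
averageEventMaps <- function(maps, clusterId = 1L, larvaId = "larva1") {
  if (length(maps) < 1L) .stopf("at least one event map required")
  d <- dim(maps[[1L]])
  for (m in maps) if (!all(dim(m) == d))
    .stopf("event maps must share a common shape")
  acc <- matrix(0, d[1L], d[2L])
  cnt <- matrix(0L, d[1L], d[2L])
  for (m in maps) {
    ok <- !is.na(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  new("CorrelationMap", values = out, clusterId = as.integer(clusterId),
      larvaId = larvaId, nEvents = length(maps))
}

#' Build the final correlation map of one cluster
#'
#' Convenience wrapper: filters the movie, computes the per-event pixel
#' correlation image for every event, and averages them.
#'
#' @param movie a [Movie] (unfiltered; filtering applied here).
#' @param centroid cluster centroid waveform.
#' @param events admissible event onsets (s) from [selectEvents()].
#' @param spec the matching [EventWindowSpec].
#' @param filterPx spatial mean filter size (default 2).
#' @param clusterId,larvaId identifiers stored on the result.
#' @return a [CorrelationMap].
#' @export
clusterCorrelationMap <- function(movie, centroid, events, spec,
                                  filterPx = 2L, clusterId = 1L,
                                  larvaId = "larva1") {
  if (length(events) < 1L) .stopf("at least one event required")
  filt <- spatialMeanFilter(movie, filterPx)
  maps <- lapply(events, function(ev)
    eventPixelCorrelation(filt, centroid, ev, spec))
  averageEventMaps(maps, clusterId = clusterId, larvaId = larvaId)
}

#' Combine pre-registered maps across larvae
#'
#' Per-pixel weighted mean of correlation maps already registered to a
#' common space. Default weights are proportional to each larva's event
#' count, so larvae contributing more events weigh more. Undefined
#' pixels are ignored per larva; a pixel undefined in every larva stays
#' undefined.
#'
#' @param maps list of [CorrelationMap]s of common shape.
#' @param weights optional numeric weights (default `nEvents`).
#' @return a [CorrelationMap] with `larvaId = "combined"` and `nEvents`
#'   equal to the total event count.
#' @export
combineAcrossLarvae <- function(maps, weights = NULL) {
  if (length(maps) < 1L) .stopf("at least one map required")
  d <- dim(mapValues(maps[[1L]]))
  for (m in maps) if (!all(dim(mapValues(m)) == d))
    .stopf("maps must share a common shape (register them first)")
  if (is.null(weights))
    weights <- vapply(maps, function(m) as.numeric(m@nEvents), numeric(1))
  if (length(weights) != length(maps) || any(weights < 0) ||
      sum(weights) <= 0)
    .stopf("weights must be non-negative with positive sum")
  acc <- matrix(0, d[1L], d[2L])
  wsum <- matrix(0, d[1L], d[2L])
  for (i in seq_along(maps)) {
    v <- mapValues(maps[[i]])
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + weights[i] * v[ok]
    wsum[ok] <- wsum[ok] + weights[i]
  }
  out <- acc / wsum
  out[wsum == 0] <- NA_real_
  new("CorrelationMap", values = out,
      clusterId = maps[[1L]]@clusterId, larvaId = "combined",
      nEvents = as.integer(sum(vapply(maps, function(m) m@nEvents,
                                      integer(1)))))
}
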