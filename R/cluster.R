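#' Correlation-threshold clustering of triggered averages
#'
#' Groups event-triggered average waveforms into activity archetypes by
#' iterative centroid growing: (1) each waveform is z-scored (Pearson
#' correlation is scale-invariant, so this only fixes the centroid's
#' display scale); (2) a new cluster is seeded with the most-correlated
#' remaining waveform pair above `threshold` (ties broken by lowest
#' index); (3) membership is re-evaluated in sweeps - every remaining
#' waveform whose correlation with the current centroid is at least
#' `threshold` joins, the centroid is recomputed, and sweeps repeat to a
#' fixed point; (4) members are removed from the pool and the procedure
#' repeats from (2); (5) clusters smaller than `minSize` are discarded
#' and their waveforms labelled unassigned. Clusters are returned sorted
#' by size (largest first). All-constant waveforms cannot be z-scored
#' and are always unassigned.
#'
#' `minSize = 50` is the full-scale default for recordings with
#' hundreds of functional ROIs; scale it down for smaller inputs.
#'
#' @param waveforms waveforms x samples matrix (one triggered average
#'   per row).
#' @param threshold correlation threshold (default 0.75).
#' @param minSize minimum members per surviving cluster (default 50).
#' @param eventKind label stored on each cluster.
#' @param maxSweeps safety cap on membership sweeps per cluster.
#' @return list with `clusters` (list of [ActivityCluster]) and
#'   `assignment` (integer vector, `NA` = unassigned).
#' @export
clusterTraces <- function(waveforms, threshold = 0.75, minSize = 50L,
                          eventKind = "", maxSweeps = 100L) {
  waveforms <- as.matrix(waveforms)
  n <- nrow(waveforms)
  if (n < 1L) .stopf("at least one waveform required")
  if (threshold < -1 || threshold > 1)
    .stopf("threshold must lie in [-1, 1]")
  z <- matrix(NA_real_, n, ncol(waveforms))
  usable <- logical(n)
  for (i in seq_len(n)) {
    zi <- .zscore(waveforms[i, ])
    if (!is.null(zi)) { z[i, ] <- zi; usable[i] <- TRUE }
  }
  assignment <- rep(NA_integer_, n)
  pool <- which(usable)
  rawClusters <- list()
  if (length(pool) == 1L && minSize <= 1L)
    rawClusters <- list(pool)                 # lone usable waveform
  while (length(pool) >= 2L) {
    cm <- cor(t(z[pool, , drop = FALSE]))
    diag(cm) <- -Inf
    best <- which(cm == max(cm), arr.ind = TRUE)
    if (max(cm) < threshold) break
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]  # lowest idx
    seedPair <- sort(pool[best[1L, ]])
    memb <- seedPair
    for (s in seq_len(maxSweeps)) {
      ctr <- colMeans(z[memb, , drop = FALSE])
      if (sd(ctr) <= .Machine$double.eps) break
      rs <- .colPearson(t(z[pool, , drop = FALSE]), ctr)
      # the seed pair stays even if a sweep pulls the centroid away
      newMemb <- sort(unique(c(seedPair,
                               pool[!is.na(rs) & rs >= threshold])))
      if (identical(newMemb, memb)) break
      memb <- newMemb
    }
    rawClusters[[length(rawClusters) + 1L]] <- memb
    pool <- setdiff(pool, memb)
  }
  keep <- Filter(function(m) length(m) >= minSize, rawClusters)
  keep <- keep[order(vapply(keep, length, integer(1)), decreasing = TRUE)]
  clusters <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    memb <- keep[[k]]
    assignment[memb] <- k
    zm <- z[memb, , drop = FALSE]
    ctr <- colMeans(zm)
    sem <- if (length(memb) > 1L)
      apply(zm, 2L, sd) / sqrt(length(memb)) else rep(0, ncol(zm))
    clusters[[k]] <- new("ActivityCluster", clusterId = k,
                         eventKind = eventKind, members = as.integer(memb),
                         centroid = ctr, sem = sem)
  }
  list(clusters = clusters, assignment = assignment)
}

#' Centroid and SEM of a set of member waveforms
#'
#' @param waveforms members x samples matrix.
#' @return list with `centroid` (element-wise mean) and `sem`
#'   (per-sample standard error of the mean; 0 for a single member).
#' @export
waveformCentroid <- function(waveforms) {
  waveforms <- as.matrix(waveforms)
  if (nrow(waveforms) < 1L) .stopf("at least one member required")
  ctr <- colMeans(waveforms)
  sem <- if (nrow(waveforms) > 1L)
    apply(waveforms, 2L, sd) / sqrt(nrow(waveforms))
  else rep(0, ncol(waveforms))
  list(centroid = ctr, sem = sem)
}
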