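#' @rdname StimulusSchedule-class
#' @param object,x an object.
#' @export
setGeneric("motionIntervals", function(x) standardGeneric("motionIntervals"))

#' @rdname StimulusSchedule-class
#' @export
setGeneric("trialDuration", function(x) standardGeneric("trialDuration"))

#' @rdname Movie-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname Movie-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname TriggeredSet-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname TriggeredSet-class
#' @export
setGeneric("triggeredAverage", function(x) standardGeneric("triggeredAverage"))

#' @rdname TriggeredSet-class
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname ActivityCluster-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname ActivityCluster-class
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))

#' @rdname ActivityCluster-class
#' @export
setGeneric("centroidSem", function(x) standardGeneric("centroidSem"))

#' @rdname CorrelationMap-class
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Select admissible event onsets
#'
#' Given either a bout table (swim events) or a [StimulusSchedule]
#' (stimulus events) and a window specification, return the onsets whose
#' full window fits inside the trial and, for swim events, that start
#' more than `minGapS` after the previous bout's end. Excluded bouts
#' (tracking failures, struggles) must be removed by the caller or are
#' dropped here when the table carries an `excluded` column.
#'
#' @param x a bout `data.frame` (see [extractBouts()]) or a
#'   [StimulusSchedule].
#' @param spec an [EventWindowSpec].
#' @param trialDuration trial length in seconds (taken from the schedule
#'   when `x` is a [StimulusSchedule]).
#' @return numeric vector of admissible event onset times (seconds).
#' @export
setGeneric("selectEvents",
  function(x, spec, trialDuration) standardGeneric("selectEvents"))

setMethod("motionIntervals", "StimulusSchedule", function(x) x@intervals)
setMethod("trialDuration", "StimulusSchedule", function(x) x@trialDuration)
setMethod("frames", "Movie", function(x) x@frames)
setMethod("frameRate", "Movie", function(x) x@frameRateHz)
setMethod("segments", "TriggeredSet", function(x) x@segments)
setMethod("triggeredAverage", "TriggeredSet", function(x) x@average)
setMethod("nEvents", "TriggeredSet", function(x) nrow(x@segments))
setMethod("members", "ActivityCluster", function(x) x@members)
setMethod("centroid", "ActivityCluster", function(x) x@centroid)
setMethod("centroidSem", "ActivityCluster", function(x) x@sem)
setMethod("mapValues", "CorrelationMap", function(x) x@values)

setMethod("show", "StimulusSchedule", function(object) {
  cat(sprintf("StimulusSchedule: %.0f s trial, %d motion interval(s)\n",
              object@trialDuration, nrow(object@intervals)))
  if (nrow(object@intervals) > 0L) {
    d <- object@intervals[, 2L] - object@intervals[, 1L]
    cat(sprintf("  first onset %.1f s, motion %.1f s, duty %.2f\n",
                object@intervals[1L, 1L], mean(d),
                sum(d) / object@trialDuration))
  }
})

setMethod("show", "TailTrace", function(object) {
  cat(sprintf("TailTrace: %d samples at %.0f Hz (%.1f s), %s\n",
              length(object@angles), object@rateHz,
              length(object@angles) / object@rateHz, object@provenance))
})

setMethod("show", "Movie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Movie [%s]: %d frames of %dx%d px at %.2f Hz\n",
              object@channel, d[1L], d[2L], d[3L], object@frameRateHz))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %dx%d px, %d ROIs, bleed %.2f\n",
              object@frameShape[1L], object@frameShape[2L],
              length(object@footprints), object@bleedFactor))
  print(table(factor(object@archetypes, levels = .ARCHETYPES)))
})

setMethod("show", "TriggeredSet", function(object) {
  cat(sprintf("TriggeredSet: %d events x %d samples (%.2f to %.2f s)\n",
              nrow(object@segments), ncol(object@segments),
              min(object@timeAxis), max(object@timeAxis)))
})

setMethod("show", "ActivityCluster", function(object) {
  cat(sprintf("ActivityCluster %d [%s]: %d members, centroid length %d\n",
              object@clusterId, object@eventKind, length(object@members),
              length(object@centroid)))
})

setMethod("show", "CorrelationMap", function(object) {
  cat(sprintf(
    "CorrelationMap cluster %d, larva %s: %dx%d px, %d events, %d undefined px\n",
    object@clusterId, object@larvaId, nrow(object@values),
    ncol(object@values), object@nEvents, sum(is.na(object@values))))
})
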