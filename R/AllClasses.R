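#' @import methods
#' @importFrom stats cor quantile median rnorm rpois rexp runif sd approx
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

#' Optomotor stimulus schedule
#'
#' Describes one open-loop trial as an ordered set of half-open motion
#' intervals `[tOn, tOff)` inside `[0, trialDuration)`. The canonical
#' protocol tiles 10 s of whole-field grating motion with 5 s static
#' presentation, starting with a static period.
#'
#' @slot trialDuration trial length in seconds.
#' @slot intervals two-column matrix (`tOn`, `tOff`) of motion periods,
#'   sorted and non-overlapping, in seconds.
#' @seealso [makeSchedule()]
#' @export
setClass("StimulusSchedule",
  representation(trialDuration = "numeric", intervals = "matrix"))

setValidity("StimulusSchedule", function(object) {
  iv <- object@intervals
  msg <- character()
  if (length(object@trialDuration) != 1L || !is.finite(object@trialDuration) ||
      object@trialDuration <= 0)
    msg <- c(msg, "trialDuration must be a single positive number")
  if (ncol(iv) != 2L)
    msg <- c(msg, "intervals must have two columns (tOn, tOff)")
  if (nrow(iv) > 0L) {
    if (any(iv[, 1L] >= iv[, 2L]))
      msg <- c(msg, "each interval must satisfy tOn < tOff")
    if (any(iv < 0) || any(iv[, 2L] > object@trialDuration))
      msg <- c(msg, "intervals must lie within [0, trialDuration]")
    if (nrow(iv) > 1L && any(diff(iv[, 1L]) <= 0))
      msg <- c(msg, "intervals must be sorted by onset")
    if (nrow(iv) > 1L && any(iv[-nrow(iv), 2L] > iv[-1L, 1L]))
      msg <- c(msg, "intervals must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Tail bend-angle trace
#'
#' A uniformly sampled, signed bend-angle time series (degrees) between
#' the caudal end of the swim bladder and the tip of the tail, recorded
#' from below at the behaviour frame rate (typically 250 Hz). Positive
#' angles denote leftward deflection viewed from below; missing tracking
#' frames are carried as `NA`.
#'
#' @slot times sample times in seconds, strictly increasing.
#' @slot angles bend angles in degrees (may contain `NA`).
#' @slot rateHz sampling rate in Hz.
#' @slot provenance `"tracked_points"` or `"direct"`.
#' @export
setClass("TailTrace",
  representation(times = "numeric", angles = "numeric", rateHz = "numeric",
                 provenance = "character"))

setValidity("TailTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@angles))
    msg <- c(msg, "times and angles must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Calcium indicator impulse response
#'
#' Double-exponential kernel `exp(-t/decayTau) - exp(-t/riseTau)`,
#' normalised to unit peak. Defaults approximate GCaMP5-class dynamics
#' (fast rise, ~1 s decay); the indicator kinetics are a tunable model
#' input, not a measured constant.
#'
#' @slot riseTau rise time constant in seconds (> 0).
#' @slot decayTau decay time constant in seconds (> riseTau).
#' @seealso [calciumKernel()]
#' @export
setClass("CalciumKernel",
  representation(riseTau = "numeric", decayTau = "numeric"))

setValidity("CalciumKernel", function(object) {
  msg <- character()
  if (object@riseTau <= 0 || object@decayTau <= 0)
    msg <- c(msg, "time constants must be positive")
  if (object@decayTau <= object@riseTau)
    msg <- c(msg, "decayTau must exceed riseTau")
  if (length(msg)) msg else TRUE
})

#' Single-channel fluorescence movie
#'
#' A single-plane movie as a 3-D array indexed (frame, row, col), with
#' non-negative intensities and a fixed frame rate.
#'
#' @slot frames numeric array (time, rows, cols).
#' @slot frameRateHz imaging frame rate in Hz (canonically 5.81).
#' @slot channel `"green"` (GCaMP) or `"red"` (anatomy).
#' @export
setClass("Movie",
  representation(frames = "array", frameRateHz = "numeric",
                 channel = "character"))

setValidity("Movie", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-D array (time, rows, cols)")
  if (any(object@frames < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@frameRateHz) != 1L || object@frameRateHz <= 0)
    msg <- c(msg, "frameRateHz must be a single positive number")
  if (!object@channel %in% c("green", "red"))
    msg <- c(msg, "channel must be 'green' or 'red'")
  if (length(msg)) msg else TRUE
})

#' Synthetic imaging scene
#'
#' Ground-truth geometry for a simulated single-plane recording: ROI
#' footprints (non-negative, unit-sum pixel weight images) with one
#' activity archetype each, plus the red-to-green bleed-through factor
#' used when rendering the green channel.
#'
#' Archetypes: `swim_locked` (transient at each bout onset), `stim_on`
#' (sustained during stimulus motion), `mixed` (both drives),
#' `stim_suppressed` (tonic activity shut off during motion), `silent`.
#'
#' @slot frameShape integer (rows, cols).
#' @slot footprints list of weight matrices, one per ROI.
#' @slot archetypes character vector, one label per ROI.
#' @slot bleedFactor red-to-green leakage factor (>= 0).
#' @slot seed integer seed the scene was built from.
#' @seealso [makeScene()], [generateMovie()]
#' @export
setClass("SyntheticScene",
  representation(frameShape = "integer", footprints = "list",
                 archetypes = "character", bleedFactor = "numeric",
                 seed = "integer"))

.ARCHETYPES <- c("swim_locked", "stim_on", "mixed", "stim_suppressed", "silent")

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (length(object@frameShape) != 2L || any(object@frameShape < 1L))
    msg <- c(msg, "frameShape must be two positive integers")
  if (length(object@footprints) != length(object@archetypes))
    msg <- c(msg, "one archetype per footprint required")
  if (!all(object@archetypes %in% .ARCHETYPES))
    msg <- c(msg, sprintf("archetypes must be in {%s}",
                          paste(.ARCHETYPES, collapse = ", ")))
  for (fp in object@footprints) {
    if (!all(dim(fp) == object@frameShape)) {
      msg <- c(msg, "each footprint must match frameShape"); break
    }
    if (any(fp < 0) || abs(sum(fp) - 1) > 1e-8) {
      msg <- c(msg, "footprints must be non-negative and unit-sum"); break
    }
  }
  if (object@bleedFactor < 0)
    msg <- c(msg, "bleedFactor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Event window specification
#'
#' Defines the trace window taken around each event onset. Defaults
#' follow the standard protocol: swim bouts use 2 s before to 5 s after
#' bout start, admitting only bouts starting more than 0.5 s after the
#' end of the previous bout; stimulus presentations use 5 s before
#' motion onset plus the full 10 s of motion.
#'
#' @slot eventKind `"swim"` or `"stimulus"`.
#' @slot preS seconds before onset.
#' @slot postS seconds after onset.
#' @slot minGapS minimum quiescence (s) between the previous bout's end
#'   and the bout start (swim only; ignored for stimulus).
#' @seealso [swimWindowSpec()], [stimulusWindowSpec()]
#' @export
setClass("EventWindowSpec",
  representation(eventKind = "character", preS = "numeric", postS = "numeric",
                 minGapS = "numeric"))

setValidity("EventWindowSpec", function(object) {
  msg <- character()
  if (!object@eventKind %in% c("swim", "stimulus"))
    msg <- c(msg, "eventKind must be 'swim' or 'stimulus'")
  if (object@preS < 0 || object@postS < 0)
    msg <- c(msg, "preS and postS must be >= 0")
  if (object@preS + object@postS <= 0)
    msg <- c(msg, "window must have positive length")
  if (length(msg)) msg else TRUE
})

#' Event-triggered segment set
#'
#' Trace segments aligned on repeated event onsets (one row per event,
#' all the same length) plus their element-wise mean, the triggered
#' average.
#'
#' @slot segments events x samples matrix.
#' @slot eventTimes event onsets in seconds.
#' @slot timeAxis seconds relative to onset for each column.
#' @slot average the element-wise mean segment.
#' @export
setClass("TriggeredSet",
  representation(segments = "matrix", eventTimes = "numeric",
                 timeAxis = "numeric", average = "numeric"))

setValidity("TriggeredSet", function(object) {
  msg <- character()
  if (nrow(object@segments) < 1L)
    msg <- c(msg, "at least one event segment required")
  if (nrow(object@segments) != length(object@eventTimes))
    msg <- c(msg, "one event time per segment required")
  if (ncol(object@segments) != length(object@average) ||
      ncol(object@segments) != length(object@timeAxis))
    msg <- c(msg, "average and timeAxis must match segment length")
  if (length(msg)) msg else TRUE
})

#' Activity-archetype cluster
#'
#' One cluster of event-triggered average waveforms: its members, the
#' centroid (mean waveform of the z-scored members) and the per-sample
#' standard error of the mean.
#'
#' @slot clusterId integer label (1 = largest cluster).
#' @slot eventKind `"swim"`, `"stimulus"` or `""` when unknown.
#' @slot members integer indices of member waveforms.
#' @slot centroid mean member waveform.
#' @slot sem per-sample standard error of the centroid.
#' @export
setClass("ActivityCluster",
  representation(clusterId = "integer", eventKind = "character",
                 members = "integer", centroid = "numeric", sem = "numeric"))

setValidity("ActivityCluster", function(object) {
  msg <- character()
  if (length(object@members) < 1L)
    msg <- c(msg, "a cluster must have at least one member")
  if (length(object@sem) != length(object@centroid))
    msg <- c(msg, "sem must match centroid length")
  if (length(msg)) msg else TRUE
})

#' Event-averaged pixel correlation map
#'
#' Per-pixel mean Pearson correlation between the movie's pixel time
#' series (within event windows) and a cluster centroid, averaged over
#' events. Pixels with zero variance in every event window are
#' undefined and stored as `NA`.
#'
#' @slot values rows x cols matrix of mean correlations in `[-1, 1]`,
#'   `NA` where undefined.
#' @slot clusterId cluster the map belongs to.
#' @slot larvaId identifier of the recording/larva.
#' @slot nEvents number of events averaged.
#' @export
setClass("CorrelationMap",
  representation(values = "matrix", clusterId = "integer",
                 larvaId = "character", nEvents = "integer"))

setValidity("CorrelationMap", function(object) {
  v <- object@values
  msg <- character()
  if (any(abs(v) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "defined correlations must lie in [-1, 1]")
  if (object@nEvents < 1L)
    msg <- c(msg, "nEvents must be >= 1")
  if (length(msg)) msg else TRUE
})
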