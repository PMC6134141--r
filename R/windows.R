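#' Swim-bout window specification
#'
#' Default window: 2 s before to 5 s after bout start, admitting only
#' bouts starting more than 0.5 s after the previous bout's end (the
#' gap is measured bout-end to next bout-start).
#'
#' @param preS,postS window extent around bout start (s).
#' @param minGapS minimum quiescence before the bout (s).
#' @return an [EventWindowSpec].
#' @export
swimWindowSpec <- function(preS = 2, postS = 5, minGapS = 0.5) {
  new("EventWindowSpec", eventKind = "swim", preS = preS, postS = postS,
      minGapS = minGapS)
}

#' Stimulus-presentation window specification
#'
#' Default window: 5 s before motion onset plus the full 10 s of
#' stimulus motion (the window ends at motion offset; post-motion static
#' seconds are not included).
#'
#' @param preS,postS window extent around motion onset (s).
#' @return an [EventWindowSpec].
#' @export
stimulusWindowSpec <- function(preS = 5, postS = 10) {
  new("EventWindowSpec", eventKind = "stimulus", preS = preS, postS = postS,
      minGapS = 0)
}

#' @describeIn selectEvents swim events from a bout table: bouts not
#'   flagged excluded, starting more than `minGapS` after the previous
#'   bout's end (the first bout has no predecessor and passes), with the
#'   full window inside `[0, trialDuration]`.
#' @export
setMethod("selectEvents", signature(x = "data.frame"),
  function(x, spec, trialDuration) {
    stopifnot(is(spec, "EventWindowSpec"))
    if (spec@eventKind != "swim")
      .stopf("bout tables provide swim events; use a swim window spec")
    if (nrow(x) == 0L) return(numeric(0))
    x <- x[order(x$start_s), , drop = FALSE]
    if ("excluded" %in% names(x)) {
      keep <- !x$excluded
    } else keep <- rep(TRUE, nrow(x))
    # gap to the previous retained bout's end (excluded bouts still
    # occupy time, so gaps are measured against all bouts)
    prevEnd <- c(-Inf, x$end_s[-nrow(x)])
    gapOk <- (x$start_s - prevEnd) > spec@minGapS
    fits <- x$start_s - spec@preS >= 0 &
      x$start_s + spec@postS <= trialDuration
    x$start_s[keep & gapOk & fits]
  })

#' @describeIn selectEvents stimulus events from a schedule: motion
#'   onsets whose full window fits inside the trial.
#' @export
setMethod("selectEvents", signature(x = "StimulusSchedule"),
  function(x, spec, trialDuration) {
    stopifnot(is(spec, "EventWindowSpec"))
    if (spec@eventKind != "stimulus")
      .stopf("schedules provide stimulus events; use a stimulus window spec")
    dur <- if (missing(trialDuration)) x@trialDuration else trialDuration
    on <- motionIntervals(x)[, 1L]
    on[on - spec@preS >= 0 & on + spec@postS <= dur]
  })

#' Extract event-triggered windows from a trace
#'
#' For each event onset, takes the trace samples in
#' `[onset - preS, onset + postS)` on the imaging clock (the onset is
#' snapped to the nearest frame; behaviour-clock events therefore carry
#' sub-frame jitter of at most half a frame period) and stacks them into
#' a [TriggeredSet] together with their element-wise mean, the
#' triggered average. Events whose window would leave the trace are
#' rejected by [selectEvents()]; encountering one here is an error.
#'
#' @param trace numeric trace on the imaging clock.
#' @param events event onset times in seconds.
#' @param spec an [EventWindowSpec].
#' @param frameRateHz imaging frame rate (Hz).
#' @param t0 time of the first trace sample (s).
#' @return a [TriggeredSet].
#' @export
extractWindows <- function(trace, events, spec, frameRateHz, t0 = 0) {
  stopifnot(is(spec, "EventWindowSpec"))
  if (length(events) == 0L)
    .stopf("no admissible events: the trace cannot be windowed")
  nPre <- round(spec@preS * frameRateHz)
  nPost <- round(spec@postS * frameRateHz)
  len <- nPre + nPost
  if (len < 1L) .stopf("window has zero length at this frame rate")
  seg <- matrix(NA_real_, length(events), len)
  for (i in seq_along(events)) {
    i0 <- round((events[i] - t0) * frameRateHz) + 1L   # frame at onset
    idx <- (i0 - nPre):(i0 + nPost - 1L)
    if (idx[1L] < 1L || idx[len] > length(trace))
      .stopf("event at %.2f s has a window outside the trace", events[i])
    seg[i, ] <- trace[idx]
  }
  new("TriggeredSet", segments = seg, eventTimes = as.numeric(events),
      timeAxis = ((-nPre):(nPost - 1L)) / frameRateHz,
      average = colMeans(seg))
}
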