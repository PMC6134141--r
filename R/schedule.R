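#' Build the tiled optomotor stimulus schedule
#'
#' Tiles a trial of `trialDuration` seconds with alternating static and
#' motion periods, starting with a static period, so the first motion
#' onset falls at `staticS` seconds. A trailing partial motion period is
#' truncated at the trial end; a cycle whose motion would start at or
#' after the trial end is dropped. The canonical protocol is a 315 s
#' trial of 10 s caudal-to-rostral grating motion alternating with 5 s
#' static presentation, which yields 21 motion presentations.
#'
#' @param trialDuration trial length in seconds (> 0).
#' @param motionS duration of each motion period in seconds (> 0).
#' @param staticS duration of each static period in seconds (> 0).
#' @return a [StimulusSchedule].
#' @examples
#' makeSchedule(315, 10, 5)   # 21 motion intervals
#' makeSchedule(15, 10, 5)    # a single [5, 15) interval
#' @export
makeSchedule <- function(trialDuration = 315, motionS = 10, staticS = 5) {
  if (!is.numeric(trialDuration) || length(trialDuration) != 1L ||
      !is.finite(trialDuration) || trialDuration <= 0)
    .stopf("trialDuration must be a single positive number")
  if (!is.numeric(motionS) || length(motionS) != 1L || motionS <= 0)
    .stopf("motionS must be a single positive number")
  if (!is.numeric(staticS) || length(staticS) != 1L || staticS <= 0)
    .stopf("staticS must be a single positive number")
  cycle <- motionS + staticS
  onsets <- if (staticS < trialDuration)
    seq(staticS, trialDuration, by = cycle) else numeric(0)
  onsets <- onsets[onsets < trialDuration]
  iv <- cbind(tOn = onsets, tOff = pmin(onsets + motionS, trialDuration))
  if (length(onsets) == 0L)
    iv <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("tOn", "tOff")))
  new("StimulusSchedule", trialDuration = trialDuration, intervals = iv)
}

#' Is each time point inside a motion interval?
#'
#' @param schedule a [StimulusSchedule].
#' @param times numeric vector of times in seconds.
#' @return logical vector, `TRUE` where `times` falls in a half-open
#'   motion interval `[tOn, tOff)`.
#' @export
inMotion <- function(schedule, times) {
  stopifnot(is(schedule, "StimulusSchedule"))
  iv <- motionIntervals(schedule)
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(iv)))
    out <- out | (times >= iv[i, 1L] & times < iv[i, 2L])
  out
}

#' Total motion and static time of a schedule
#'
#' @param schedule a [StimulusSchedule].
#' @return named numeric vector with `motion` and `static` durations (s).
#' @export
scheduleDurations <- function(schedule) {
  stopifnot(is(schedule, "StimulusSchedule"))
  iv <- motionIntervals(schedule)
  motion <- if (nrow(iv)) sum(iv[, 2L] - iv[, 1L]) else 0
  c(motion = motion, static = trialDuration(schedule) - motion)
}
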