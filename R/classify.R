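#' Mean event-wise correlation with the triggered average
#'
#' The consistency score of a trace with respect to an event class: the
#' mean over events of the Pearson correlation between each individual
#' event segment and the set's triggered average. A segment (or an
#' average) with zero variance has an undefined correlation; such events
#' contribute 0 and are counted, with a message. With fewer than two
#' events the score is degenerate (each segment trivially matches the
#' average) and `NA` is returned.
#'
#' @param set a [TriggeredSet].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return mean correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
meanEventCorrelation <- function(set, method = c("pearson", "spearman")) {
  stopifnot(is(set, "TriggeredSet"))
  method <- match.arg(method)
  seg <- segments(set)
  if (nrow(seg) < 2L) return(NA_real_)
  avg <- triggeredAverage(set)
  if (method == "spearman") {
    avg <- rank(avg)
    seg <- t(apply(seg, 1L, rank))
  }
  rs <- .colPearson(t(seg), avg)
  nDeg <- sum(is.na(rs))
  if (nDeg > 0L) {
    message(sprintf("%d zero-variance event segment(s) scored as 0", nDeg))
    rs[is.na(rs)] <- 0
  }
  mean(rs)
}

#' Classify one trace from its two consistency scores
#'
#' A trace is `swim_driven` when its mean event-wise correlation with
#' the swim-triggered average exceeds `threshold` but the stimulus score
#' does not; `stimulus_driven` in the opposite case; `ambiguous` when
#' both exceed the threshold (such traces are excluded from clustering);
#' otherwise `unclassified`. Comparisons are strict, so scores exactly
#' at the threshold do not qualify. Undefined (`NA`) scores never
#' qualify.
#'
#' @param rSwim,rStim mean event-wise correlations in `[-1, 1]` or `NA`.
#' @param threshold classification threshold (default 0.6).
#' @return one of `"swim_driven"`, `"stimulus_driven"`, `"ambiguous"`,
#'   `"unclassified"`; vectorised over inputs.
#' @export
classifyTrace <- function(rSwim, rStim, threshold = 0.6) {
  if (length(rSwim) != length(rStim))
    .stopf("rSwim and rStim must have equal length")
  swimHi <- !is.na(rSwim) & rSwim > threshold
  stimHi <- !is.na(rStim) & rStim > threshold
  out <- rep("unclassified", length(rSwim))
  out[swimHi & !stimHi] <- "swim_driven"
  out[stimHi & !swimHi] <- "stimulus_driven"
  out[swimHi & stimHi] <- "ambiguous"
  out
}

#' Score and classify every ROI trace
#'
#' For each row of `traces`, builds the swim- and stimulus-triggered
#' sets, computes both mean event-wise correlations, and applies the
#' classification rule. ROIs with fewer than two admissible events of a
#' kind get an `NA` score for that kind.
#'
#' @param traces ROIs x frames matrix (typically dF/F).
#' @param bouts bout table ([findBouts()]); excluded bouts are dropped.
#' @param schedule the trial's [StimulusSchedule].
#' @param frameRateHz imaging frame rate (Hz).
#' @param threshold classification threshold.
#' @param swimSpec,stimSpec window specifications.
#' @return data.frame with `roi_id`, `r_swim`, `r_stim`, `category`.
#' @export
classifyRois <- function(traces, bouts, schedule, frameRateHz,
                         threshold = 0.6, swimSpec = swimWindowSpec(),
                         stimSpec = stimulusWindowSpec()) {
  dur <- trialDuration(schedule)
  swimEv <- selectEvents(bouts, swimSpec, dur)
  stimEv <- selectEvents(schedule, stimSpec, dur)
  n <- nrow(traces)
  score <- function(tr, ev, spec) {
    if (length(ev) < 2L) return(NA_real_)
    suppressMessages(
      meanEventCorrelation(extractWindows(tr, ev, spec, frameRateHz)))
  }
  rSwim <- vapply(seq_len(n), function(i)
    score(traces[i, ], swimEv, swimSpec), numeric(1))
  rStim <- vapply(seq_len(n), function(i)
    score(traces[i, ], stimEv, stimSpec), numeric(1))
  data.frame(roi_id = seq_len(n), r_swim = rSwim, r_stim = rStim,
             category = classifyTrace(rSwim, rStim, threshold))
}
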