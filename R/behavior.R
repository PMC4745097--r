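# Trace-conditioning trial structure and eyelid-based trial scoring.

#' Behavior parameters
#'
#' @param baselineWindow seconds of pre-tone trace used for the baseline
#'   statistics (default 3 s).
#' @param responseWindow seconds after tone onset scored for a conditioned
#'   response; must not extend past the air puff (default 0.6 s, i.e. the
#'   tone-to-puff interval).
#' @param thresholdK the response threshold is
#'   \code{baseline mean + thresholdK * baseline SD}. The exact multiplier
#'   is the one genuinely tunable constant of the scoring rule; 4 is the
#'   package default and should be reviewed against each rig's noise.
#' @return A validated parameter list of class \code{BehaviorParams}.
#' @export
behaviorParams <- function(baselineWindow = 3, responseWindow = 0.6,
                           thresholdK = 4) {
  stopIfNot(baselineWindow > 0 && responseWindow > 0,
            "windows must be positive")
  stopIfNot(thresholdK >= 0, "'thresholdK' must be nonnegative")
  structure(list(baselineWindow = baselineWindow,
                 responseWindow = responseWindow, thresholdK = thresholdK),
            class = "BehaviorParams")
}

#' Generate a randomized trial schedule
#'
#' Tone onsets separated by inter-trial intervals drawn uniformly from
#' \code{itiRange}. Each trial is a 350 ms tone (CS), a 250 ms stimulus-free
#' trace interval, then a 100 ms air puff (US): the puff starts 600 ms after
#' tone onset.
#'
#' @param n number of trials.
#' @param itiRange inter-trial interval range in seconds.
#' @param seed optional seed (local to this call).
#' @param startOffset time of the first tone, seconds.
#' @param toneDuration,traceInterval,puffDuration stimulus timing, seconds.
#' @return data.frame: trial, toneOnset, toneDuration, traceInterval,
#'   puffOnset, puffDuration, outcome ("unscored").
#' @examples
#' generateTrialSchedule(3, seed = 1)
#' @export
generateTrialSchedule <- function(n = 40, itiRange = c(31, 36), seed = NULL,
                                  startOffset = 6, toneDuration = 0.35,
                                  traceInterval = 0.25, puffDuration = 0.1) {
  stopIfNot(isCount(n) && n >= 1, "'n' must be a positive count")
  itis <- withSeed(seed, stats::runif(n - 1, itiRange[1], itiRange[2]))
  tones <- startOffset + c(0, cumsum(itis))
  data.frame(trial = seq_len(n), toneOnset = tones,
             toneDuration = toneDuration, traceInterval = traceInterval,
             puffOnset = tones + toneDuration + traceInterval,
             puffDuration = puffDuration, outcome = "unscored",
             stringsAsFactors = FALSE)
}

# sample indices of a half-open absolute-time window [a, b), 1-based,
# sample i covering time (i - 1) / rate
windowIndices <- function(a, b, rate, n, t0 = 0) {
  i0 <- ceiling((a - t0) * rate - 1e-9) + 1
  i1 <- ceiling((b - t0) * rate - 1e-9)
  if (i0 > i1) return(integer(0))
  out <- i0:i1
  out[out >= 1 & out <= n]
}

#' Score one trial from the eyelid trace
#'
#' Baseline mean and SD are taken over the \code{baselineWindow} seconds
#' before tone onset; the trial is correct iff any sample in the half-open
#' \code{[tone, tone + responseWindow)} interval exceeds
#' \code{mean + thresholdK * SD}. With a perfectly flat baseline (SD = 0)
#' the rule degenerates to "any sample above the baseline mean".
#'
#' @param eyelid reflection trace sampled at \code{frameRate}.
#' @param trial one row of a trial schedule (needs \code{toneOnset}).
#' @param params a \code{\link{behaviorParams}} list.
#' @param frameRate Hz.
#' @return "correct" or "incorrect".
#' @export
classifyTrial <- function(eyelid, trial, params = behaviorParams(),
                          frameRate = 20) {
  n <- length(eyelid)
  bi <- windowIndices(trial$toneOnset - params$baselineWindow,
                      trial$toneOnset, frameRate, n)
  ri <- windowIndices(trial$toneOnset,
                      trial$toneOnset + params$responseWindow, frameRate, n)
  stopIfNot(length(bi) > 1 && length(ri) >= 1,
            "baseline/response windows not covered by the eyelid trace")
  mu <- mean(eyelid[bi])
  sg <- stats::sd(eyelid[bi])
  thr <- mu + params$thresholdK * sg
  if (any(eyelid[ri] > thr)) "correct" else "incorrect"
}

#' Score every trial of a schedule
#'
#' @param eyelid reflection trace.
#' @param schedule trial table.
#' @param params a \code{\link{behaviorParams}} list.
#' @param frameRate Hz.
#' @return the schedule with the \code{outcome} column filled.
#' @export
classifyTrials <- function(eyelid, schedule, params = behaviorParams(),
                           frameRate = 20) {
  schedule$outcome <- vapply(seq_len(nrow(schedule)), function(i)
    classifyTrial(eyelid, schedule[i, ], params, frameRate), character(1))
  schedule
}

#' Behavioral performance percentage
#'
#' \code{100 * correct / (correct + incorrect)}, rounded to one decimal
#' (33 of 40 gives 82.5).
#'
#' @param schedule trial table with scored outcomes.
#' @return percentage.
#' @export
performancePercent <- function(schedule) {
  nc <- sum(schedule$outcome == "correct")
  ni <- sum(schedule$outcome == "incorrect")
  stopIfNot(nc + ni > 0, "no scored trials")
  round(100 * nc / (nc + ni), 1)
}
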