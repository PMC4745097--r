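# Trial alignment, task-modulation classification, latency-to-peak,
# population summaries.

#' Analysis parameters for task-modulation statistics
#'
#' @param baselineWindow seconds relative to tone onset, half-open
#'   (default [-2, 0)).
#' @param taskWindow seconds relative to tone onset (default [0, 2)).
#' @param alpha per-ROI significance level for the paired t-test (no
#'   multiple-testing correction by default, matching a per-ROI 0.05
#'   criterion).
#' @param latencyWindow seconds after tone onset searched for the response
#'   peak (default [0, 8]).
#' @param percentDecimals decimals for population percentages.
#' @param adjust "none" or "BH" (Benjamini-Hochberg) for the population
#'   classification.
#' @return A validated parameter list of class \code{AnalysisParams}.
#' @export
analysisParams <- function(baselineWindow = c(-2, 0), taskWindow = c(0, 2),
                           alpha = 0.05, latencyWindow = c(0, 8),
                           percentDecimals = 2, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopIfNot(baselineWindow[1] < baselineWindow[2] &&
            taskWindow[1] < taskWindow[2], "windows must be increasing")
  stopIfNot(baselineWindow[2] <= taskWindow[1],
            "baseline and task windows must not overlap")
  stopIfNot(alpha > 0 && alpha < 1, "'alpha' must be in (0, 1)")
  structure(list(baselineWindow = baselineWindow, taskWindow = taskWindow,
                 alpha = alpha, latencyWindow = latencyWindow,
                 percentDecimals = percentDecimals, adjust = adjust),
            class = "AnalysisParams")
}

#' Align a trace to tone onsets
#'
#' Cuts one row per trial from the trace, with columns at the frame rate
#' relative to tone onset over the half-open window \code{[w0, w1)}. The
#' tone-onset column is the first sample at or after the onset. Trials whose
#' window does not fit inside the recording are excluded with a warning.
#'
#' @param trace numeric trace (e.g. one dF/F row).
#' @param schedule trial table.
#' @param window \code{c(w0, w1)} seconds relative to tone onset.
#' @param frameRate Hz.
#' @param t0 time of the first sample, seconds.
#' @return trials x samples matrix with attributes \code{times} (column
#'   times relative to tone onset) and \code{trials} (schedule row kept).
#' @export
alignTrials <- function(trace, schedule, window = c(-2, 8), frameRate = 20,
                        t0 = 0) {
  offsets <- seq(round(window[1] * frameRate),
                 round(window[2] * frameRate) - 1)
  n <- length(trace)
  rows <- list(); kept <- integer(0)
  for (i in seq_len(nrow(schedule))) {
    iOn <- ceiling((schedule$toneOnset[i] - t0) * frameRate - 1e-9) + 1
    idx <- iOn + offsets
    if (idx[1] < 1 || idx[length(idx)] > n) next
    kept <- c(kept, i)
    rows[[length(rows) + 1L]] <- trace[idx]
  }
  if (length(kept) < nrow(schedule))
    warning(nrow(schedule) - length(kept),
            " trial(s) excluded: window extends past the recording")
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(0, 0, length(offsets))
  attr(out, "times") <- offsets / frameRate
  attr(out, "trials") <- kept
  out
}

#' Area under a trial-aligned trace segment
#'
#' Rectangle rule: sum of the samples whose times fall in the half-open
#' window, times the sample interval.
#'
#' @param row one aligned row (or any numeric vector).
#' @param window \code{c(a, b)} seconds, half-open, in the same time base
#'   as \code{times}.
#' @param frameRate Hz.
#' @param times sample times; defaults to the \code{times} attribute of
#'   \code{row}.
#' @return the area (value x seconds).
#' @export
windowAuc <- function(row, window, frameRate = 20, times = attr(row, "times")) {
  stopIfNot(!is.null(times), "sample times required")
  sel <- times >= window[1] - 1e-9 & times < window[2] - 1e-9
  sum(row[sel]) / frameRate
}

#' Classify the task modulation of one ROI
#'
#' Paired two-sided t-test of task-window versus baseline-window area under
#' the trace over correct trials (df = n - 1). The ROI is task-relevant if
#' p < alpha; the sign of the mean paired difference assigns the label:
#' larger task-window area is "positive" modulation, smaller is "negative".
#' If the paired differences have zero variance but a nonzero mean the
#' difference is exact and p is reported as 0 with \code{exactDifference =
#' TRUE}; all-zero differences give "none".
#'
#' @param aligned trials x samples matrix from \code{\link{alignTrials}}.
#' @param correctTrials indices (rows of \code{aligned}) of correct trials.
#' @param params an \code{\link{analysisParams}} list.
#' @param frameRate Hz.
#' @return list: label, pValue, tStat, meanDiff, baselineAuc, taskAuc,
#'   nTrials, exactDifference.
#' @export
classifyModulation <- function(aligned, correctTrials,
                               params = analysisParams(), frameRate = 20) {
  stopIfNot(length(correctTrials) >= 2, "at least 2 correct trials required")
  times <- attr(aligned, "times")
  bSel <- times >= params$baselineWindow[1] - 1e-9 &
          times < params$baselineWindow[2] - 1e-9
  tSel <- times >= params$taskWindow[1] - 1e-9 &
          times < params$taskWindow[2] - 1e-9
  baseAuc <- rowSums(aligned[correctTrials, bSel, drop = FALSE]) / frameRate
  taskAuc <- rowSums(aligned[correctTrials, tSel, drop = FALSE]) / frameRate
  d <- taskAuc - baseAuc
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  exact <- FALSE
  if (s == 0) {
    if (m == 0)
      return(list(label = "none", pValue = 1, tStat = 0, meanDiff = 0,
                  baselineAuc = baseAuc, taskAuc = taskAuc, nTrials = n,
                  exactDifference = FALSE))
    exact <- TRUE
    tStat <- sign(m) * Inf
    p <- 0
  } else {
    tStat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tStat), df = n - 1)
  }
  label <- if (p < params$alpha) {
    if (m > 0) "positive" else "negative"
  } else "none"
  list(label = label, pValue = p, tStat = tStat, meanDiff = m,
       baselineAuc = baseAuc, taskAuc = taskAuc, nTrials = n,
       exactDifference = exact)
}

#' Latency to peak of the trial-averaged response
#'
#' Averages the aligned trace over correct trials and returns the time of
#' the first maximum inside the latency window (ties resolved to the
#' earliest sample).
#'
#' @inheritParams classifyModulation
#' @return list: latency (s, a multiple of the sample interval), peakValue.
#' @export
latencyToPeak <- function(aligned, correctTrials, params = analysisParams(),
                          frameRate = 20) {
  times <- attr(aligned, "times")
  sel <- which(times >= params$latencyWindow[1] - 1e-9 &
               times <= params$latencyWindow[2] + 1e-9)
  stopIfNot(length(sel) > 0, "latency window outside the aligned range")
  avg <- colMeans(aligned[correctTrials, , drop = FALSE])
  k <- sel[which.max(avg[sel])]
  list(latency = times[k], peakValue = avg[k])
}

#' Task-modulation analysis of every ROI
#'
#' Aligns each dF/F trace to tone onset, classifies its modulation over
#' correct trials, and computes its latency to peak.
#'
#' @param traces a normalized \linkS4class{TraceMatrix} (dff filled).
#' @param schedule scored trial table.
#' @param params an \code{\link{analysisParams}} list.
#' @param useDff analyze dF/F traces (default) or raw.
#' @return data.frame: roi, label, pValue, tStat, meanDiff, latency,
#'   peakValue. p-values are BH-adjusted before labeling when
#'   \code{params$adjust == "BH"}.
#' @export
analyzeTaskModulation <- function(traces, schedule,
                                  params = analysisParams(),
                                  useDff = TRUE) {
  mat <- if (useDff) traces@dff else traces@raw
  stopIfNot(nrow(mat) > 0, "no traces (did you run normalizeTraces?)")
  window <- c(params$baselineWindow[1],
              max(params$taskWindow[2], params$latencyWindow[2]))
  R <- nrow(mat)
  res <- vector("list", R)
  for (r in seq_len(R)) {
    al <- suppressWarnings(
      alignTrials(mat[r, ], schedule, window, traces@frameRate,
                  t0 = traces@times[1]))
    correct <- which(schedule$outcome[attr(al, "trials")] == "correct")
    cm <- classifyModulation(al, correct, params, traces@frameRate)
    lt <- latencyToPeak(al, correct, params, traces@frameRate)
    res[[r]] <- data.frame(roi = r, label = cm$label, pValue = cm$pValue,
                           tStat = cm$tStat, meanDiff = cm$meanDiff,
                           latency = lt$latency, peakValue = lt$peakValue)
  }
  out <- do.call(rbind, res)
  if (params$adjust == "BH") {
    padj <- stats::p.adjust(out$pValue, "BH")
    out$pAdjusted <- padj
    out$label <- ifelse(padj < params$alpha,
                        ifelse(out$meanDiff > 0, "positive", "negative"),
                        "none")
  }
  out
}

#' Population summary of modulation labels
#'
#' Counts and percentages of positively / negatively / non-modulated ROIs.
#' Percentages are rounded half away from zero to \code{percentDecimals}
#' (81 of 422 gives 19.19).
#'
#' @param labels character vector of per-ROI labels.
#' @param params an \code{\link{analysisParams}} list.
#' @return data.frame: label, count, percent.
#' @export
summarizePopulation <- function(labels, params = analysisParams()) {
  stopIfNot(length(labels) > 0, "no ROIs to summarize")
  lv <- c("positive", "negative", "none")
  counts <- vapply(lv, function(l) sum(labels == l), 1L)
  data.frame(label = lv, count = as.integer(counts),
             percent = roundHalfUp(100 * counts / length(labels),
                                   params$percentDecimals),
             row.names = NULL)
}
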