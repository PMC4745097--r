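# Per-ROI fluorescence traces, dF/F normalization, SNR, photobleaching.

#' Extract raw fluorescence traces
#'
#' \code{raw[r, t]} is the mean intensity over ROI r's mask pixels in frame
#' t, computed from the native-depth motion-corrected movie (the 8-bit
#' reduced copy is for storage/visualization only). Implemented as a sparse
#' mask-matrix product over frame chunks.
#'
#' @param video motion-corrected \linkS4class{VideoSequence}.
#' @param rois a \linkS4class{RoiSet} with nonempty masks inside the frame.
#' @param chunkFrames frames per chunk.
#' @return A \linkS4class{TraceMatrix} with raw traces only.
#' @export
extractTraces <- function(video, rois, chunkFrames = 250L) {
  R <- length(rois)
  stopIfNot(R >= 1L, "no ROIs")
  stopIfNot(all(lengths(rois@masks) > 0L), "empty ROI mask")
  d <- frameDim(video)
  stopIfNot(identical(as.integer(d), rois@dim),
            "ROI frame dimensions do not match the movie")
  npix <- prod(d)
  Tn <- nFrames(video)
  M <- Matrix::sparseMatrix(
    i = unlist(rois@masks),
    j = rep(seq_len(R), lengths(rois@masks)),
    x = rep(1 / lengths(rois@masks), lengths(rois@masks)),
    dims = c(npix, R))
  raw <- matrix(0, R, Tn)
  for (start in seq(1L, Tn, by = chunkFrames)) {
    idx <- start:min(Tn, start + chunkFrames - 1L)
    X <- matrix(as.double(video@frames[, , idx]), npix, length(idx))
    raw[, idx] <- as.matrix(Matrix::crossprod(M, X))
    rm(X)
    trimMemory()
  }
  new("TraceMatrix", raw = raw, dff = matrix(0, 0, 0), fAvg = numeric(0),
      times = frameTimes(video), frameRate = video@frameRate)
}

#' Normalize one trace to dF/F percent
#'
#' \code{d = (f - f_avg) / f_avg} with \code{f_avg} the whole-trace mean,
#' then rescaled by a single positive factor so that the trace maximum
#' equals 100 (percent); negative excursions are scaled by the same factor.
#' A constant trace maps to all zeros.
#'
#' @param raw numeric trace with nonzero mean.
#' @return normalized trace; attribute \code{fAvg} carries the mean.
#' @examples
#' normalizeTrace(c(90, 110))   # -100, +100
#' @export
normalizeTrace <- function(raw) {
  fAvg <- mean(raw)
  if (fAvg == 0) stop("zero-mean trace cannot be dF/F normalized")
  d <- (raw - fAvg) / fAvg
  m <- max(d)
  # dividing by the maximum first makes the peak exactly 100 in floating
  # point (m / m == 1)
  out <- if (m > 0) (d / m) * 100 else rep(0, length(raw))
  attr(out, "fAvg") <- fAvg
  out
}

#' Normalize all traces of a TraceMatrix
#'
#' @param traces a \linkS4class{TraceMatrix}.
#' @return the same object with \code{dff} and \code{fAvg} filled.
#' @export
normalizeTraces <- function(traces) {
  R <- nrow(traces@raw)
  dff <- matrix(0, R, ncol(traces@raw))
  fAvg <- numeric(R)
  for (r in seq_len(R)) {
    d <- normalizeTrace(traces@raw[r, ])
    fAvg[r] <- attr(d, "fAvg")
    dff[r, ] <- d
  }
  new("TraceMatrix", raw = traces@raw, dff = dff, fAvg = fAvg,
      times = traces@times, frameRate = traces@frameRate)
}

#' Signal-to-noise ratio per ROI
#'
#' The noise level is the mean, over all pixels not registered to any ROI,
#' of each pixel's temporal standard deviation; each ROI's SNR is its
#' maximum raw trace intensity divided by that shared noise value.
#'
#' @param video the motion-corrected \linkS4class{VideoSequence}.
#' @param rois a \linkS4class{RoiSet}.
#' @param traces the \linkS4class{TraceMatrix} extracted from \code{video}.
#' @param stats optional precomputed \linkS4class{FrameStats} (saves a
#'   pass over the movie).
#' @return list with \code{snr} (per ROI), \code{noiseSigma}, and
#'   \code{meanSnr}/\code{semSnr}.
#' @export
computeSnr <- function(video, rois, traces, stats = NULL) {
  if (is.null(stats)) stats <- computePixelStats(video)
  inRoi <- logical(prod(frameDim(video)))
  for (m in rois@masks) inRoi[m] <- TRUE
  if (all(inRoi)) stop("no non-ROI pixels to estimate noise from")
  noiseSigma <- mean(stats@sd[!inRoi])
  if (noiseSigma == 0) stop("zero noise estimate (degenerate input)")
  snr <- apply(traces@raw, 1, max) / noiseSigma
  list(snr = snr, noiseSigma = noiseSigma, meanSnr = mean(snr),
       semSnr = stats::sd(snr) / sqrt(length(snr)))
}

#' Whole-field photobleaching percentage
#'
#' \code{100 * (mean(first frame) - mean(last frame)) / mean(first frame)},
#' optionally averaging k frames at each end to damp per-frame noise.
#' Increasing intensity yields a negative percentage (reported as-is).
#'
#' @param video a \linkS4class{VideoSequence} with T >= 2.
#' @param k frames averaged at each end.
#' @return percentage of signal lost between the first and last frame.
#' @export
photobleachingPercent <- function(video, k = 1L) {
  Tn <- nFrames(video)
  stopIfNot(Tn >= 2L, "at least 2 frames required")
  k <- min(k, floor(Tn / 2))
  first <- mean(video@frames[, , seq_len(k), drop = FALSE])
  last <- mean(video@frames[, , (Tn - k + 1L):Tn, drop = FALSE])
  if (first == 0) stop("zero-intensity first frame")
  100 * (first - last) / first
}
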