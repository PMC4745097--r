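#' VideoSequence: a grayscale movie with acquisition metadata
#'
#' The central container every pipeline stage transforms: a stack of
#' equally-sized grayscale frames with a frame rate (Hz) and a pixel pitch
#' (micrometres per pixel). Frames are stored as an \code{H x W x T} array
#' (rows x columns x time); intensities are photon counts (16-bit range) or
#' normalized floats depending on origin.
#'
#' @slot frames numeric or integer array, dim \code{c(H, W, T)}.
#' @slot frameRate sampling rate in Hz.
#' @slot pixelPitch micrometres per pixel (isotropic).
#' @slot t0 acquisition time of the first frame, seconds.
#' @export
setClass("VideoSequence",
  representation(frames = "array", frameRate = "numeric",
                 pixelPitch = "numeric", t0 = "numeric"),
  prototype(frameRate = 20, pixelPitch = 1.312, t0 = 0))

setValidity("VideoSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("'frames' must be an H x W x T array")
  if (d[3] < 1L) return("movie must contain at least one frame")
  if (!isScalar(object@frameRate) || object@frameRate <= 0)
    return("'frameRate' must be a positive scalar (Hz)")
  if (!isScalar(object@pixelPitch) || object@pixelPitch <= 0)
    return("'pixelPitch' must be a positive scalar (um/px)")
  if (!isScalar(object@t0)) return("'t0' must be a finite scalar (s)")
  TRUE
})

#' Construct a VideoSequence
#'
#' @param frames \code{H x W x T} array, or a matrix (interpreted as a single
#'   frame).
#' @param frameRate frames per second.
#' @param pixelPitch micrometres per pixel.
#' @param t0 time of the first frame in seconds.
#' @return A \linkS4class{VideoSequence}.
#' @examples
#' v <- VideoSequence(array(0L, c(4, 4, 3)))
#' nFrames(v)
#' @export
VideoSequence <- function(frames, frameRate = 20, pixelPitch = 1.312, t0 = 0) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("VideoSequence", frames = frames, frameRate = frameRate,
      pixelPitch = pixelPitch, t0 = t0)
}

#' FrameStats: per-pixel temporal statistics of a movie
#'
#' Exact per-pixel minimum, maximum, mean and population standard deviation
#' over time, each stored as an \code{H x W} map.
#'
#' @slot min,max,mean,sd \code{H x W} numeric matrices.
#' @slot nFrames number of frames the statistics were computed over.
#' @export
setClass("FrameStats",
  representation(min = "matrix", max = "matrix", mean = "matrix",
                 sd = "matrix", nFrames = "integer"))

setValidity("FrameStats", function(object) {
  d <- dim(object@min)
  for (s in c("max", "mean", "sd"))
    if (!identical(dim(slot(object, s)), d))
      return("statistic maps must share dimensions")
  if (any(object@sd < 0)) return("'sd' must be nonnegative")
  if (any(object@min > object@mean + 1e-9) ||
      any(object@mean > object@max + 1e-9))
    return("per-pixel min <= mean <= max violated")
  TRUE
})

#' RoiSet: multi-frame regions of interest
#'
#' A collection of putative neurons ("multi-frame ROIs"): each has a pixel
#' mask, a centroid (mean of the contributing single-frame centroids), a
#' half-open bounding box, and the list of frames it was detected in.
#'
#' @slot masks list of sorted integer vectors of linear pixel indices
#'   (column-major within an \code{H x W} frame).
#' @slot centroids n x 2 matrix (row, col), 1-based pixel coordinates.
#' @slot bboxes n x 4 matrix (r0, r1, c0, c1), half-open
#'   \code{[r0, r1) x [c0, c1)}.
#' @slot frameIndices list of sorted integer frame indices per ROI.
#' @slot nAppearances integer vector, number of contributing frames.
#' @slot dim frame dimensions \code{c(H, W)}.
#' @slot pixelPitch micrometres per pixel.
#' @export
setClass("RoiSet",
  representation(masks = "list", centroids = "matrix", bboxes = "matrix",
                 frameIndices = "list", nAppearances = "integer",
                 dim = "integer", pixelPitch = "numeric"))

setValidity("RoiSet", function(object) {
  n <- length(object@masks)
  if (nrow(object@centroids) != n || nrow(object@bboxes) != n ||
      length(object@frameIndices) != n || length(object@nAppearances) != n)
    return("slot lengths disagree")
  if (length(object@dim) != 2L) return("'dim' must be c(H, W)")
  if (n && any(lengths(object@masks) == 0L)) return("empty ROI mask")
  if (n && any(object@nAppearances != lengths(object@frameIndices)))
    return("nAppearances must equal the number of contributing frames")
  TRUE
})

#' TraceMatrix: per-ROI fluorescence over time
#'
#' Raw traces are mean fluorescence over each ROI mask per frame. The dF/F
#' ("dff") traces are \code{(f - f_avg)/f_avg} rescaled so that the maximum of
#' each non-constant trace equals 100 (percent).
#'
#' @slot raw R x T matrix of raw traces (counts).
#' @slot dff R x T matrix of normalized traces (percent), empty until
#'   \code{\link{normalizeTraces}} is applied.
#' @slot fAvg per-ROI mean of the raw trace.
#' @slot times sample times in seconds.
#' @slot frameRate Hz.
#' @export
setClass("TraceMatrix",
  representation(raw = "matrix", dff = "matrix", fAvg = "numeric",
                 times = "numeric", frameRate = "numeric"))

setValidity("TraceMatrix", function(object) {
  if (length(object@times) != ncol(object@raw))
    return("'times' must have one entry per frame")
  if (nrow(object@dff) && !identical(dim(object@dff), dim(object@raw)))
    return("'dff' must match 'raw' in shape")
  TRUE
})

#' SimParams: synthetic-movie generator parameters
#'
#' The study conditions of the simulator: geometry and sampling of the movie,
#' soma size and brightness, calcium-transient kinetics and rates, rigid
#' motion, illumination non-uniformity, photobleaching, sensor noise, and the
#' trace-conditioning trial schedule. Defaults emulate a desk-scale wide-field
#' recording of hippocampal CA1 at 20 Hz and 1.312 um/px with GCaMP6f-like
#' kinetics; see the package vignette for the rationale behind each value.
#'
#' @slot frameHeight,frameWidth frame size in pixels.
#' @slot nFrames number of frames.
#' @slot frameRate Hz.
#' @slot pixelPitch micrometres per pixel.
#' @slot nCells number of planted somata.
#' @slot somaRadius soma radius in pixels (15 um diameter at 1.312 um/px
#'   gives ~5.7 px).
#' @slot background tissue background level in counts.
#' @slot cellF0 resting somatic fluorescence above background, counts.
#' @slot transientAmplitude peak transient amplitude, counts.
#' @slot tauRise,tauDecay transient kinetics, seconds.
#' @slot backgroundRate spontaneous transient rate, events/s/cell.
#' @slot illumAmplitude fractional amplitude of the static multiplicative
#'   illumination field.
#' @slot respFreq,respAmplitude respiratory motion: frequency (Hz) and
#'   amplitude (px).
#' @slot jumpRate,jumpAmplitude rare large biphasic jumps: rate (events/s)
#'   and amplitude (px).
#' @slot bleachEndFraction fraction of initial intensity remaining at the
#'   last frame (exponential bleaching), in (0, 1].
#' @slot readNoiseSigma additive read noise SD, counts; shot noise with
#'   variance equal to the signal is added on top.
#' @slot nTrials,itiRange,trialStartOffset trial schedule: number of tone-puff
#'   trials, inter-trial-interval range (s), and time of the first tone (s).
#'   Trials whose analysis windows do not fit in the movie are dropped.
#' @slot correctFraction fraction of trials planted as correct.
#' @slot fracPositive,fracNegative fraction of cells positively / negatively
#'   task-modulated.
#' @slot pOn probability a positive cell emits an extra transient in the
#'   0-0.6 s window after the tone of a correct trial.
#' @slot negRateMultiplier baseline-rate multiplier for negative cells
#'   (tonically active).
#' @slot suppressionFactor,suppressionDuration rate suppression of negative
#'   cells after the tone of a correct trial (factor, seconds).
#' @slot seed master seed; all randomness derives from it via per-component
#'   sub-streams.
#' @export
setClass("SimParams",
  representation(frameHeight = "numeric", frameWidth = "numeric",
    nFrames = "numeric", frameRate = "numeric", pixelPitch = "numeric",
    nCells = "numeric", somaRadius = "numeric", background = "numeric",
    cellF0 = "numeric", transientAmplitude = "numeric", tauRise = "numeric",
    tauDecay = "numeric", backgroundRate = "numeric",
    illumAmplitude = "numeric", respFreq = "numeric",
    respAmplitude = "numeric", jumpRate = "numeric", jumpAmplitude = "numeric",
    bleachEndFraction = "numeric", readNoiseSigma = "numeric",
    nTrials = "numeric", itiRange = "numeric", trialStartOffset = "numeric",
    correctFraction = "numeric", fracPositive = "numeric",
    fracNegative = "numeric", pOn = "numeric", negRateMultiplier = "numeric",
    suppressionFactor = "numeric", suppressionDuration = "numeric",
    seed = "numeric"))

setValidity("SimParams", function(object) {
  p <- object
  pos <- c("frameHeight", "frameWidth", "nFrames", "frameRate", "pixelPitch",
           "somaRadius", "tauRise", "tauDecay", "respFreq")
  for (s in pos) if (!isScalar(slot(p, s)) || slot(p, s) <= 0)
    return(paste0("'", s, "' must be positive"))
  nonneg <- c("nCells", "background", "cellF0", "transientAmplitude",
              "backgroundRate", "illumAmplitude", "respAmplitude", "jumpRate",
              "jumpAmplitude", "readNoiseSigma", "nTrials",
              "trialStartOffset", "pOn", "negRateMultiplier",
              "suppressionFactor", "suppressionDuration")
  for (s in nonneg) if (!isScalar(slot(p, s)) || slot(p, s) < 0)
    return(paste0("'", s, "' must be nonnegative"))
  if (p@bleachEndFraction <= 0 || p@bleachEndFraction > 1)
    return("'bleachEndFraction' must be in (0, 1]")
  if (length(p@itiRange) != 2L || any(p@itiRange <= 0) ||
      p@itiRange[1] > p@itiRange[2])
    return("'itiRange' must be an increasing positive pair (s)")
  if (p@correctFraction < 0 || p@correctFraction > 1)
    return("'correctFraction' must be in [0, 1]")
  if (p@fracPositive + p@fracNegative > 1)
    return("'fracPositive' + 'fracNegative' must not exceed 1")
  if (p@pOn > 1 || p@suppressionFactor > 1)
    return("'pOn' and 'suppressionFactor' must be <= 1")
  if (p@nCells * (2 * p@somaRadius)^2 >= p@frameHeight * p@frameWidth)
    return("cell placement infeasible: nCells * (2*somaRadius)^2 must be smaller than the frame area")
  TRUE
})

#' GroundTruth: the simulator's validation record
#'
#' Everything the simulator planted, so downstream stages can be scored
#' against known truth: cell centers and masks, per-cell transient times,
#' modulation labels, the per-frame rigid motion, and the trial schedule with
#' planted outcomes.
#'
#' @slot cellCenters n x 2 matrix (row, col) in pixels.
#' @slot cellMasks H x W integer label image (0 = background, k = cell k).
#' @slot eventTimes list of per-cell transient onset times (s).
#' @slot modulationLabel per-cell label in {"positive", "negative", "none"}.
#' @slot motionTrace nFrames x 2 matrix of (dx, dy) content displacement in
#'   pixels (dx = columns/right, dy = rows/down).
#' @slot schedule trial table (data.frame) with planted outcomes.
#' @slot params the \linkS4class{SimParams} used.
#' @export
setClass("GroundTruth",
  representation(cellCenters = "matrix", cellMasks = "matrix",
                 eventTimes = "list", modulationLabel = "character",
                 motionTrace = "matrix", schedule = "data.frame",
                 params = "SimParams"))

setValidity("GroundTruth", function(object) {
  n <- nrow(object@cellCenters)
  if (length(object@eventTimes) != n || length(object@modulationLabel) != n)
    return("per-cell slots disagree in length")
  if (!all(object@modulationLabel %in% c("positive", "negative", "none")))
    return("invalid modulation label")
  if (nrow(object@motionTrace) != object@params@nFrames)
    return("motionTrace must have one row per frame")
  TRUE
})

# ---- accessors & show methods -----------------------------------------------

#' @describeIn VideoSequence number of frames
#' @param object,x a VideoSequence
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname VideoSequence-class
#' @export
setMethod("nFrames", "VideoSequence", function(object) dim(object@frames)[3])

#' @export
setGeneric("frameDim", function(object) standardGeneric("frameDim"))

#' @describeIn VideoSequence frame dimensions \code{c(H, W)}
#' @export
setMethod("frameDim", "VideoSequence", function(object) dim(object@frames)[1:2])

#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @describeIn VideoSequence frame rate in Hz
#' @export
setMethod("frameRate", "VideoSequence", function(object) object@frameRate)

#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @describeIn VideoSequence pixel pitch in micrometres per pixel
#' @export
setMethod("pixelPitch", "VideoSequence", function(object) object@pixelPitch)

#' @rdname RoiSet-class
#' @export
setMethod("pixelPitch", "RoiSet", function(object) object@pixelPitch)

#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @describeIn VideoSequence sample times in seconds
#' @export
setMethod("frameTimes", "VideoSequence", function(object)
  object@t0 + (seq_len(nFrames(object)) - 1) / object@frameRate)

#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))

#' @describeIn VideoSequence extract frame \code{i} as a matrix
#' @param i frame index
#' @export
setMethod("getFrame", "VideoSequence", function(object, i)
  object@frames[, , i, drop = TRUE])

setMethod("show", "VideoSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoSequence: %d x %d px, %d frames @ %g Hz, %g um/px\n",
              d[1], d[2], d[3], object@frameRate, object@pixelPitch))
  cat(sprintf("  intensity range [%g, %g], storage %s\n",
              min(object@frames), max(object@frames),
              typeof(object@frames)))
})

setMethod("show", "FrameStats", function(object) {
  cat(sprintf("FrameStats over %d frames: %d x %d px\n", object@nFrames,
              nrow(object@mean), ncol(object@mean)))
  cat(sprintf("  mean intensity %.2f, mean per-pixel SD %.2f\n",
              mean(object@mean), mean(object@sd)))
})

#' @rdname RoiSet-class
#' @export
setMethod("length", "RoiSet", function(x) length(x@masks))

#' @export
setGeneric("roiCentroids", function(object, units = c("px", "um"))
  standardGeneric("roiCentroids"))

#' @describeIn RoiSet ROI centroids as an n x 2 matrix (row, col), in pixels
#'   or micrometres
#' @param units "px" or "um"
#' @export
setMethod("roiCentroids", "RoiSet", function(object, units = c("px", "um")) {
  units <- match.arg(units)
  cc <- object@centroids
  if (units == "um") cc <- cc * object@pixelPitch
  cc
})

#' @export
setGeneric("roiAreas", function(object) standardGeneric("roiAreas"))

#' @describeIn RoiSet mask areas in pixels
#' @export
setMethod("roiAreas", "RoiSet", function(object) lengths(object@masks))

#' @describeIn RoiSet subset to the ROIs in \code{i}
#' @param i,j,...,drop index vector (j, drop ignored)
#' @export
setMethod("[", "RoiSet", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(length(x))[i]
  new("RoiSet", masks = x@masks[i],
      centroids = x@centroids[i, , drop = FALSE],
      bboxes = x@bboxes[i, , drop = FALSE],
      frameIndices = x@frameIndices[i],
      nAppearances = x@nAppearances[i],
      dim = x@dim, pixelPitch = x@pixelPitch)
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet: %d multi-frame ROIs in a %d x %d px frame\n",
              length(object), object@dim[1], object@dim[2]))
  if (length(object))
    cat(sprintf("  area %d-%d px, appearances %d-%d frames\n",
                min(roiAreas(object)), max(roiAreas(object)),
                min(object@nAppearances), max(object@nAppearances)))
})

#' @describeIn RoiSet convert to a data.frame (id, centroid, bbox, area,
#'   appearances)
#' @param row.names,optional passed through (unused)
#' @export
setMethod("as.data.frame", "RoiSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(id = seq_len(length(x)),
               centroidR = x@centroids[, 1], centroidC = x@centroids[, 2],
               r0 = x@bboxes[, 1], r1 = x@bboxes[, 2],
               c0 = x@bboxes[, 3], c1 = x@bboxes[, 4],
               areaPx = as.integer(lengths(x@masks)),
               nAppearances = x@nAppearances)
  })

#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))

#' @describeIn RoiSet render the ROI masks as an H x W integer label image
#'   (0 = background, k = ROI k; later ROIs overwrite earlier on overlap)
#' @export
setMethod("labelImage", "RoiSet", function(object) {
  lab <- matrix(0L, object@dim[1], object@dim[2])
  for (k in seq_len(length(object))) lab[object@masks[[k]]] <- k
  lab
})

setMethod("show", "TraceMatrix", function(object) {
  cat(sprintf("TraceMatrix: %d ROIs x %d frames @ %g Hz (%s)\n",
              nrow(object@raw), ncol(object@raw), object@frameRate,
              if (nrow(object@dff)) "raw + dff" else "raw only"))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %g x %g px, %g frames @ %g Hz, %g cells (r = %g px)\n",
    object@frameHeight, object@frameWidth, object@nFrames, object@frameRate,
    object@nCells, object@somaRadius))
  cat(sprintf("  kinetics tau = %g/%g s, rate %g ev/s, noise sd %g, seed %g\n",
              object@tauRise, object@tauDecay, object@backgroundRate,
              object@readNoiseSigma, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells (%s), %d trials, %d frames\n",
              nrow(object@cellCenters),
              paste(table(factor(object@modulationLabel,
                                 c("positive", "negative", "none"))),
                    collapse = "/"),
              nrow(object@schedule), nrow(object@motionTrace)))
})
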