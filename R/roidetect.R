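# Reduce frames to binary activity maps and label single-frame ROIs.

#' Detection parameters
#'
#' @param z0 initial z-score threshold in SD units.
#' @param zBounds admissible threshold range \code{c(zMin, zMax)}.
#' @param zStep adjustment step in SD units.
#' @param activeFracBounds target range \code{c(lo, hi)} for the fraction of
#'   active pixels per frame; the threshold is raised while the fraction is
#'   above \code{hi} and lowered while below \code{lo}. Guards against
#'   spurious motion-induced borders flooding a frame with foreground.
#' @param openRadius,closeRadius disc radii (px) for morphological opening /
#'   closing.
#' @param connectivity pixel connectivity for component labeling (4 or 8).
#' @param areaBounds \code{c(minPx, maxPx)} admissible component area; the
#'   defaults bracket a ~15 um soma at 1.312 um/px (~103 px).
#' @return A validated parameter list of class \code{DetectionParams}.
#' @export
detectionParams <- function(z0 = 1.5, zBounds = c(1.0, 6.0), zStep = 0.25,
                            activeFracBounds = c(0.0005, 0.01),
                            openRadius = 1, closeRadius = 1,
                            connectivity = 8, areaBounds = c(30, 300)) {
  stopIfNot(zBounds[1] <= z0 && z0 <= zBounds[2],
            "'z0' must lie inside 'zBounds'")
  stopIfNot(activeFracBounds[1] < activeFracBounds[2],
            "'activeFracBounds' must be increasing")
  stopIfNot(areaBounds[1] < areaBounds[2], "'areaBounds' must be increasing")
  stopIfNot(connectivity %in% c(4, 8), "'connectivity' must be 4 or 8")
  structure(list(z0 = z0, zBounds = zBounds, zStep = zStep,
                 activeFracBounds = activeFracBounds,
                 openRadius = openRadius, closeRadius = closeRadius,
                 connectivity = as.integer(connectivity),
                 areaBounds = areaBounds),
            class = "DetectionParams")
}

#' Per-pixel z-score of a frame
#'
#' \code{z = (x - mean) / sd} using the per-pixel temporal statistics.
#' Pixels with zero temporal SD get z = 0 (they carry no activity signal);
#' their positions are attached as the \code{"flagged"} attribute.
#'
#' @param frame intensity matrix.
#' @param stats a \linkS4class{FrameStats} for the same movie.
#' @return z-score matrix with attribute \code{flagged} (linear indices of
#'   zero-SD pixels).
#' @export
zscoreFrame <- function(frame, stats) {
  stopIfNot(identical(dim(frame), dim(stats@mean)),
            "frame and stats dimensions disagree")
  sd0 <- stats@sd == 0
  s <- stats@sd
  s[sd0] <- 1
  z <- (frame - stats@mean) / s
  z[sd0] <- 0
  attr(z, "flagged") <- which(sd0)
  z
}

#' Adaptive activity threshold
#'
#' Starts at \code{z0} and raises the threshold by \code{zStep} while the
#' active fraction exceeds the upper target, then lowers it while the
#' fraction is below the lower target (never leaving \code{zBounds}, at most
#' 20 adjustment iterations). This prevents frames with global brightening
#' or motion-induced high-contrast borders from flooding the mask.
#'
#' @param zmap finite z-score matrix.
#' @param params a \code{\link{detectionParams}} list.
#' @return logical mask with attribute \code{threshold} (the final value).
#' @export
adaptiveThreshold <- function(zmap, params = detectionParams()) {
  stopIfNot(all(is.finite(zmap)), "zmap must be finite")
  lo <- params$activeFracBounds[1]; hi <- params$activeFracBounds[2]
  zMin <- params$zBounds[1]; zMax <- params$zBounds[2]
  z <- params$z0
  n <- length(zmap)
  frac <- function(th) sum(zmap > th) / n
  f <- frac(z)
  iter <- 0L
  while (f > hi && z < zMax && iter < 20L) {
    z <- min(z + params$zStep, zMax)
    f <- frac(z)
    iter <- iter + 1L
  }
  while (f < lo && z > zMin && iter < 20L) {
    z <- max(z - params$zStep, zMin)
    f <- frac(z)
    iter <- iter + 1L
  }
  mask <- zmap > z
  attr(mask, "threshold") <- z
  mask
}

#' Morphological cleanup of a binary mask
#'
#' Closing (disc, \code{closeRadius}) to bridge small gaps, then opening
#' (disc, \code{openRadius}) to remove speckle.
#'
#' @param mask logical matrix.
#' @param params a \code{\link{detectionParams}} list.
#' @return cleaned logical matrix.
#' @export
cleanBinary <- function(mask, params = detectionParams()) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (params$closeRadius > 0) {
    kc <- EBImage::makeBrush(2 * params$closeRadius + 1, shape = "disc")
    m <- EBImage::closing(m, kc)
  }
  if (params$openRadius > 0) {
    ko <- EBImage::makeBrush(2 * params$openRadius + 1, shape = "disc")
    m <- EBImage::opening(m, ko)
  }
  m > 0.5
}

#' Label connected components as single-frame ROIs
#'
#' Components under the configured connectivity whose area lies inside
#' \code{areaBounds} become single-frame ROIs: one row per component with
#' its unweighted centroid, half-open bounding box, intensity summary and
#' pixel list.
#'
#' @param mask cleaned logical matrix.
#' @param frame intensity matrix the mask was derived from.
#' @param params a \code{\link{detectionParams}} list.
#' @param frameIndex frame number stored with each ROI.
#' @return data.frame with columns frame, area, centroidR, centroidC, r0,
#'   r1, c0, c1, meanIntensity, maxIntensity and list-column \code{pixels}
#'   (linear indices).
#' @export
labelComponents <- function(mask, frame, params = detectionParams(),
                            frameIndex = 1L) {
  lab <- .ccLabel(mask, params$connectivity)
  n <- max(lab)
  if (n == 0L) return(emptySfroi())
  idx <- which(lab > 0L)
  comp <- lab[idx]
  areas <- tabulate(comp, nbins = n)
  keep <- which(areas >= params$areaBounds[1] & areas <= params$areaBounds[2])
  if (!length(keep)) return(emptySfroi())
  H <- nrow(mask)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  vals <- frame[idx]
  out <- lapply(keep, function(k) {
    sel <- comp == k
    px <- idx[sel]
    r <- rows[sel]; cc <- cols[sel]
    data.frame(frame = frameIndex, area = areas[k],
               centroidR = mean(r), centroidC = mean(cc),
               r0 = min(r), r1 = max(r) + 1L,
               c0 = min(cc), c1 = max(cc) + 1L,
               meanIntensity = mean(vals[sel]),
               maxIntensity = max(vals[sel]))
  })
  df <- do.call(rbind, out)
  df$pixels <- lapply(keep, function(k) sort(idx[comp == k]))
  df
}

emptySfroi <- function() {
  df <- data.frame(frame = integer(0), area = integer(0),
                   centroidR = numeric(0), centroidC = numeric(0),
                   r0 = integer(0), r1 = integer(0), c0 = integer(0),
                   c1 = integer(0), meanIntensity = numeric(0),
                   maxIntensity = numeric(0))
  df$pixels <- list()
  df
}

#' Detect single-frame ROIs across a movie
#'
#' Per frame: z-score against the session statistics, adaptive threshold,
#' morphological cleanup, component labeling. Cost scales linearly in frames
#' and pixels.
#'
#' @param video motion-corrected \linkS4class{VideoSequence}.
#' @param stats \linkS4class{FrameStats} of the same movie.
#' @param params a \code{\link{detectionParams}} list.
#' @param frames optional subset of frame indices to process.
#' @return data.frame of single-frame ROIs (see
#'   \code{\link{labelComponents}}) with attribute \code{dim} = frame
#'   dimensions; thresholds used per frame are in attribute
#'   \code{thresholds}.
#' @export
detectRois <- function(video, stats, params = detectionParams(),
                       frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(video))
  out <- vector("list", length(frames))
  th <- numeric(length(frames))
  for (j in seq_along(frames)) {
    f <- video@frames[, , frames[j], drop = TRUE]
    z <- zscoreFrame(f, stats)
    mask <- adaptiveThreshold(z, params)
    th[j] <- attr(mask, "threshold")
    if (!any(mask)) { out[[j]] <- emptySfroi(); next }
    cleaned <- cleanBinary(mask, params)
    out[[j]] <- labelComponents(cleaned, f, params, frames[j])
    if (j %% 500L == 0L) trimMemory()
  }
  trimMemory()
  df <- do.call(rbind, out)
  attr(df, "dim.frame") <- frameDim(video)
  attr(df, "thresholds") <- th
  df
}
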