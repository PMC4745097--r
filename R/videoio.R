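# Reading/writing movies and tabular artifacts; per-pixel statistics and the
# 8-bit dynamic-range reduction.

#' Read a multi-page TIFF movie
#'
#' Reads one or more multi-page grayscale TIFF files into a
#' \linkS4class{VideoSequence}, concatenating in file order then page order.
#' All pages must share dimensions and bit depth. Acquisition metadata (frame
#' rate, pixel pitch) is taken from the arguments, never from TIFF tags,
#' because acquisition-software tag dialects are unreliable.
#'
#' @param paths character vector of file paths, in acquisition order.
#' @param frameRate frames per second.
#' @param pixelPitch micrometres per pixel.
#' @param pages optional integer vector: read only these pages (1-based,
#'   counted across the concatenated sequence) for chunked processing of
#'   large sessions.
#' @return A \linkS4class{VideoSequence} with integer frames.
#' @export
readTiffSequence <- function(paths, frameRate = 20, pixelPitch = 1.312,
                             pages = NULL) {
  stopIfNot(length(paths) >= 1L, "at least one file required")
  for (p in paths) stopIfNot(file.exists(p), paste("file not found:", p))
  pageList <- list()
  for (p in paths) {
    pg <- tiff::readTIFF(p, all = TRUE, as.is = TRUE, info = TRUE)
    if (length(pg) == 0L) stop("empty TIFF: ", p)
    pageList <- c(pageList, pg)
  }
  if (length(pageList) == 0L) stop("no pages found in input")
  d <- dim(pageList[[1]])
  bits <- attr(pageList[[1]], "bits.per.sample")
  for (pg in pageList) {
    if (!identical(dim(pg), d))
      stop("mixed page dimensions across the sequence")
    if (!identical(attr(pg, "bits.per.sample"), bits))
      stop("mixed bit depths across the sequence")
  }
  if (!is.null(pages)) {
    stopIfNot(all(pages >= 1 & pages <= length(pageList)),
              "'pages' out of range")
    pageList <- pageList[pages]
  }
  frames <- array(0L, c(d[1], d[2], length(pageList)))
  for (i in seq_along(pageList)) frames[, , i] <- pageList[[i]]
  VideoSequence(frames, frameRate = frameRate, pixelPitch = pixelPitch)
}

#' Number of pages in a TIFF file
#' @param path file path.
#' @return integer page count.
#' @export
tiffFrameCount <- function(path) {
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.data.frame(info)) nrow(info) else 1L
}

#' Write a movie as a multi-page grayscale TIFF
#'
#' Frames are stored little-endian at the requested bit depth; integer
#' intensities in \code{[0, 2^bits - 1]} round-trip losslessly.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return \code{path}, invisibly.
#' @export
writeTiffSequence <- function(video, path, bits = 16L) {
  stopIfNot(bits %in% c(8L, 16L), "'bits' must be 8 or 16")
  maxv <- 2^bits - 1
  fr <- video@frames
  stopIfNot(min(fr) >= 0 && max(fr) <= maxv,
            "intensities out of range for the requested bit depth")
  pages <- lapply(seq_len(nFrames(video)), function(i)
    fr[, , i, drop = TRUE] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Per-pixel temporal statistics
#'
#' Exact per-pixel minimum, maximum, mean and population standard deviation
#' (1/T convention) over time, accumulated in chunks so that peak resident
#' data stays bounded.
#'
#' @param video a \linkS4class{VideoSequence} with at least 2 frames.
#' @param chunkFrames number of frames per accumulation chunk.
#' @return A \linkS4class{FrameStats}.
#' @export
computePixelStats <- function(video, chunkFrames = 256L) {
  Tn <- nFrames(video)
  stopIfNot(Tn >= 2L, "at least 2 frames required (std undefined for T = 1)")
  d <- frameDim(video)
  s1 <- matrix(0, d[1], d[2]); s2 <- matrix(0, d[1], d[2])
  mn <- matrix(Inf, d[1], d[2]); mx <- matrix(-Inf, d[1], d[2])
  for (start in seq(1L, Tn, by = chunkFrames)) {
    idx <- start:min(Tn, start + chunkFrames - 1L)
    for (i in idx) {
      f <- video@frames[, , i, drop = TRUE]
      s1 <- s1 + f
      s2 <- s2 + f * f
      mn <- pmin(mn, f)
      mx <- pmax(mx, f)
    }
  }
  trimMemory()
  mu <- s1 / Tn
  va <- pmax(s2 / Tn - mu * mu, 0)
  new("FrameStats", min = mn, max = mx, mean = mu, sd = sqrt(va),
      nFrames = as.integer(Tn))
}

# type-7 (linear interpolation) quantile of pooled integer-valued data from
# a value histogram; counts[v + 1] = number of pixels with value v
quantileFromCounts <- function(counts, probs) {
  n <- sum(counts)
  cum <- cumsum(counts)
  vals <- which(counts > 0) - 1         # distinct values present
  orderStat <- function(k) {            # k-th smallest value, 1-based
    (which(cum >= k)[1]) - 1
  }
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- orderStat(floor(h))
    hi <- orderStat(ceiling(h))
    lo + (h - floor(h)) * (hi - lo)
  }, numeric(1))
}

#' Reduce a movie to 8-bit dynamic range
#'
#' Pools all pixel values of the session, takes the global 1st and 99th
#' percentiles, and linearly maps \code{[p_lo, p_hi]} to \code{[0, 255]}
#' (clipping outside, rounding half up): the top 1% of intensities saturate
#' at 255 and the bottom 1% map to 0. Intended for storage and
#' visualization; trace extraction uses the native-depth movie.
#'
#' @param video a \linkS4class{VideoSequence} (integer counts).
#' @param stats optional \linkS4class{FrameStats} computed on the same movie
#'   (accepted for interface symmetry; percentiles are computed from the
#'   pooled distribution, not from the per-pixel maps).
#' @param probs the clipping percentiles.
#' @return An 8-bit \linkS4class{VideoSequence}.
#' @export
reduceBitDepth <- function(video, stats = NULL, probs = c(0.01, 0.99)) {
  fr <- video@frames
  if (is.integer(fr) && min(fr) >= 0) {
    counts <- tabulate(as.vector(fr) + 1L, nbins = 65536L)
    q <- quantileFromCounts(counts, probs)
  } else {
    q <- as.numeric(stats::quantile(as.vector(fr), probs, type = 7))
  }
  pLo <- q[1]; pHi <- q[2]
  d <- dim(fr)
  if (pHi <= pLo) {
    warning("constant movie: degenerate percentiles, output all zeros")
    out <- array(0L, d)
  } else {
    scaled <- floor((clampRange(fr, pLo, pHi) - pLo) / (pHi - pLo) * 255 + 0.5)
    out <- array(as.integer(scaled), d)
  }
  VideoSequence(out, frameRate = video@frameRate,
                pixelPitch = video@pixelPitch, t0 = video@t0)
}

#' Imaging field of view in millimetres
#'
#' @param px frame dimension in pixels (vectorized).
#' @param pixelPitch micrometres per pixel.
#' @return field size in mm, rounded to 3 decimals (1024 px at 1.312 um/px
#'   gives 1.343 mm).
#' @examples
#' fieldOfView(1024, 1.312)
#' @export
fieldOfView <- function(px, pixelPitch = 1.312) {
  round(px * pixelPitch / 1000, 3)
}

# ---- tabular artifact I/O ---------------------------------------------------

#' Write/read an events table (trial schedule) as CSV
#'
#' Columns: trial, toneOnset, toneDuration, traceInterval, puffOnset,
#' puffDuration, outcome.
#' @param schedule trial table data.frame.
#' @param path CSV path.
#' @return the path / the schedule.
#' @export
writeEvents <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write/read traces as CSV (long format: roi, frame, time_s, raw, dff)
#' @param traces a \linkS4class{TraceMatrix}.
#' @param path CSV path.
#' @return the path / a TraceMatrix.
#' @export
writeTraces <- function(traces, path) {
  R <- nrow(traces@raw); Tn <- ncol(traces@raw)
  hasDff <- nrow(traces@dff) > 0
  df <- data.frame(
    roi = rep(seq_len(R), each = Tn),
    frame = rep(seq_len(Tn), R),
    time_s = rep(traces@times, R),
    raw = as.vector(t(traces@raw)),
    dff = if (hasDff) as.vector(t(traces@dff)) else NA_real_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  df <- utils::read.csv(path)
  R <- max(df$roi); Tn <- max(df$frame)
  raw <- matrix(df$raw, Tn, R)
  times <- df$time_s[seq_len(Tn)]
  dt <- diff(times[1:2])
  dff <- if (all(is.na(df$dff))) matrix(0, 0, 0) else matrix(df$dff, Tn, R)
  new("TraceMatrix", raw = t(raw),
      dff = if (length(dff)) t(dff) else dff,
      fAvg = if (length(dff)) rowMeans(t(raw)) else numeric(0),
      times = times, frameRate = 1 / dt)
}

#' Write/read an ROI set as JSON (+ optional 16-bit label TIFF)
#'
#' JSON records id, centroid, bbox, area, contributing frames and the mask
#' pixel indices; the label image (0 = background, k = ROI id) can be
#' written alongside.
#' @param rois a \linkS4class{RoiSet}.
#' @param path JSON path.
#' @param labelTiff optional path for the label image TIFF.
#' @return the path / a RoiSet.
#' @export
writeRois <- function(rois, path, labelTiff = NULL) {
  obj <- list(
    dim = rois@dim, pixelPitch = rois@pixelPitch,
    rois = lapply(seq_len(length(rois)), function(k) list(
      id = k,
      centroid_px = as.numeric(rois@centroids[k, ]),
      bbox = as.numeric(rois@bboxes[k, ]),
      area_px = length(rois@masks[[k]]),
      frames = rois@frameIndices[[k]],
      mask = rois@masks[[k]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(labelTiff)) {
    lab <- labelImage(rois)
    stopIfNot(max(lab) <= 65535, "too many ROIs for a 16-bit label image")
    tiff::writeTIFF(lab / 65535, labelTiff, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname writeRois
#' @export
readRois <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- nrow(obj$rois)
  if (is.null(n)) n <- 0L
  asMat <- function(col, k) {
    if (n == 0L) return(matrix(0, 0, k))
    do.call(rbind, lapply(obj$rois[[col]], as.numeric))
  }
  new("RoiSet",
      masks = if (n) lapply(obj$rois$mask, as.integer) else list(),
      centroids = asMat("centroid_px", 2),
      bboxes = asMat("bbox", 4),
      frameIndices = if (n) lapply(obj$rois$frames, as.integer) else list(),
      nAppearances = if (n) vapply(obj$rois$frames, length, 1L) else integer(0),
      dim = as.integer(obj$dim), pixelPitch = as.numeric(obj$pixelPitch))
}

#' Write/read an eyelid-reflection trace as CSV (frame, time_s, reflection)
#' @param eyelid numeric reflection trace.
#' @param frameRate Hz.
#' @param path CSV path.
#' @return the path / a numeric vector with attribute \code{frameRate}.
#' @export
writeEyelid <- function(eyelid, frameRate, path) {
  df <- data.frame(frame = seq_along(eyelid),
                   time_s = (seq_along(eyelid) - 1) / frameRate,
                   reflection = eyelid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEyelid
#' @export
readEyelid <- function(path) {
  df <- utils::read.csv(path)
  out <- df$reflection
  attr(out, "frameRate") <- 1 / diff(df$time_s[1:2])
  out
}
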