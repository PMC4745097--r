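# Contrast enhancement and rigid motion correction.

#' Registration parameters
#'
#' @param filterSigma Gaussian low-pass sigma (px) for the homomorphic
#'   enhancement; must be well above the soma radius so that cells survive
#'   the implied high-pass (default 32 px, about 42 um at 1.312 um/px).
#' @param templateMode "moving_average" updates the template with a running
#'   mean of previously aligned frames; "two_pass_fixed" additionally blends
#'   in a fixed mean of randomly sampled, individually aligned frames.
#' @param templateWindow effective window (frames) of the running mean.
#' @param maxShift largest admissible shift (px); the correlation peak is
#'   searched only inside this range.
#' @param subpixel refine the integer peak by separable 3-point parabolic
#'   interpolation of the correlation surface.
#' @param eps relative spectrum floor for the phase normalization: bins
#'   with cross-power magnitude far below \code{eps * max} are damped
#'   instead of being inflated to unit magnitude. Near-empty bins carry no
#'   displacement information (on quantized noise-free movies they vote for
#'   zero shift), so a floor on the order of 1e-3 is required for reliable
#'   sub-pixel registration; pure phase correlation is recovered with
#'   vanishing \code{eps}.
#' @param normalization "phase" uses the unit-magnitude cross-power spectrum
#'   (phase correlation); "cross" uses the plain cross-correlation spectrum
#'   for comparison.
#' @param fixedSampleFrames frames sampled for the fixed template in
#'   "two_pass_fixed" mode.
#' @return A validated parameter list of class \code{RegistrationParams}.
#' @export
registrationParams <- function(filterSigma = 32,
                               templateMode = c("moving_average",
                                                "two_pass_fixed"),
                               templateWindow = 50, maxShift = 25,
                               subpixel = TRUE, eps = 1e-3,
                               normalization = c("phase", "cross"),
                               fixedSampleFrames = 50) {
  templateMode <- match.arg(templateMode)
  normalization <- match.arg(normalization)
  stopIfNot(isScalar(filterSigma) && filterSigma > 0,
            "'filterSigma' must be positive")
  stopIfNot(isCount(templateWindow) && templateWindow >= 1,
            "'templateWindow' must be a positive count")
  stopIfNot(isScalar(maxShift) && maxShift >= 1, "'maxShift' must be >= 1")
  stopIfNot(isScalar(eps) && eps > 0, "'eps' must be positive")
  structure(list(filterSigma = filterSigma, templateMode = templateMode,
                 templateWindow = as.integer(templateWindow),
                 maxShift = maxShift, subpixel = isTRUE(subpixel), eps = eps,
                 normalization = normalization,
                 fixedSampleFrames = as.integer(fixedSampleFrames)),
            class = "RegistrationParams")
}

#' Homomorphic contrast enhancement
#'
#' Removes multiplicative illumination non-uniformity by high-pass filtering
#' in the log domain: \code{y = exp(L - G(L) + mean(G(L))) - 1} with
#' \code{L = log(1 + x)} and \code{G} a Gaussian low-pass of width
#' \code{filterSigma}. The low-pass component is computed explicitly and
#' subtracted, which avoids ringing artifacts of direct high-pass kernels;
#' adding back the mean of the low-pass keeps overall brightness roughly
#' unchanged. Output is clipped at 0.
#'
#' @param frame nonnegative intensity matrix.
#' @param filterSigma Gaussian sigma in pixels.
#' @return enhanced frame, same dimensions.
#' @export
homomorphicEnhance <- function(frame, filterSigma = 32) {
  if (!all(is.finite(frame))) stop("non-finite values in frame")
  L <- log1p(frame)
  Lp <- gaussBlur(L, filterSigma)
  pmax(expm1(L - Lp + mean(Lp)), 0)
}

# wrap FFT bin indices (0..n-1) to signed shifts
wrapShift <- function(i, n) ifelse(i > n / 2, i - n, i)

# 3-point parabolic peak refinement; returns offset in [-0.5, 0.5]
parabolicOffset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || den >= 0) return(0)
  clampRange(0.5 * (ym - yp) / den, -0.5, 0.5)
}

#' Estimate the displacement between two frames by phase correlation
#'
#' Computes the normalized cross-power spectrum of the moving and template
#' frames, inverse-transforms it, and reads the displacement off the
#' correlation peak. The search is restricted to shifts of magnitude at most
#' \code{maxShift} per axis; exact ties are broken toward the smallest
#' shift. With \code{subpixel = TRUE} the integer peak is refined by
#' separable 3-point parabolic interpolation of the correlation surface.
#'
#' Returned shifts follow the content convention: \code{moving} looks like
#' \code{template} translated by \code{(dx, dy)} pixels
#' (dx = columns/right, dy = rows/down).
#'
#' @param moving,template equally-sized (enhanced) frames.
#' @param params a \code{\link{registrationParams}} list.
#' @return named vector \code{c(dx, dy, peakCorr)}.
#' @export
estimateDisplacement <- function(moving, template,
                                 params = registrationParams()) {
  stopIfNot(identical(dim(moving), dim(template)),
            "frames must share dimensions")
  H <- nrow(moving); W <- ncol(moving)
  # both real-valued forward transforms from one complex FFT:
  # F(moving + i*template); then F_m = (F(k)+conj(F(-k)))/2,
  # F_t = (F(k)-conj(F(-k)))/(2i)
  Fz <- stats::fft(moving + 1i * template)
  rev1 <- c(1L, H:2L); rev2 <- c(1L, W:2L)
  Fc <- Conj(Fz[rev1, rev2])
  Fm <- (Fz + Fc) / 2
  Ft <- (Fz - Fc) / (2i)
  R <- Fm * Conj(Ft)
  aR <- Mod(R)
  mR <- max(aR)
  if (mR == 0) stop("degenerate spectrum (all-zero frame?)")
  if (params$normalization == "phase") R <- R / (aR + params$eps * mR)
  r <- Re(stats::fft(R, inverse = TRUE)) / (H * W)

  ms <- min(params$maxShift, floor((min(H, W) - 1) / 2))
  rIdx <- unique(c(1:(ms + 1), (H - ms + 1):H))
  cIdx <- unique(c(1:(ms + 1), (W - ms + 1):W))
  sub <- r[rIdx, cIdx, drop = FALSE]
  peak <- max(sub)
  hits <- which(sub == peak, arr.ind = TRUE)
  sy <- wrapShift(rIdx[hits[, 1]] - 1L, H)
  sx <- wrapShift(cIdx[hits[, 2]] - 1L, W)
  best <- which.min(sx^2 + sy^2)
  dy <- sy[best]; dx <- sx[best]

  if (params$subpixel) {
    i0 <- ((dy %% H)) + 1L; j0 <- ((dx %% W)) + 1L
    im <- ((i0 - 2L) %% H) + 1L; ip <- (i0 %% H) + 1L
    jm <- ((j0 - 2L) %% W) + 1L; jp <- (j0 %% W) + 1L
    dy <- dy + parabolicOffset(r[im, j0], r[i0, j0], r[ip, j0])
    dx <- dx + parabolicOffset(r[i0, jm], r[i0, j0], r[i0, jp])
  }
  c(dx = dx, dy = dy, peakCorr = peak)
}

#' Translate frame content by a (possibly fractional) shift
#'
#' \code{out(r, c) = in(r - dy, c - dx)} with bilinear interpolation for
#' fractional shifts and replicated edge pixels. Integer shifts are exact
#' translations. To undo an estimated displacement \code{(dx, dy)}, apply
#' \code{applyShift(frame, -dx, -dy)}.
#'
#' @param frame intensity matrix.
#' @param dx,dy shift in pixels (columns/right, rows/down).
#' @return shifted frame.
#' @export
applyShift <- function(frame, dx, dy) {
  stopIfNot(is.finite(dx) && is.finite(dy), "shift must be finite")
  if (dx == 0 && dy == 0) return(frame)
  .bilinearShift(frame, dx, dy)
}

#' Update the registration template
#'
#' Running mean of previously aligned frames with effective window
#' \code{min(frameIndex + 1, templateWindow)} (frame indices are 0-based, so
#' the first frame is the template itself). In \code{two_pass_fixed} mode
#' the running mean is blended half-and-half with a fixed mean of randomly
#' sampled, pre-aligned frames supplied as \code{fixedMean}.
#'
#' @param template current template (enhanced, aligned space).
#' @param correctedFrame newly aligned (enhanced) frame.
#' @param frameIndex 0-based index of \code{correctedFrame}.
#' @param params a \code{\link{registrationParams}} list.
#' @param fixedMean fixed sampled-frame mean (only used in
#'   \code{two_pass_fixed} mode).
#' @return updated template.
#' @export
updateTemplate <- function(template, correctedFrame, frameIndex,
                           params = registrationParams(), fixedMean = NULL) {
  if (frameIndex == 0) return(correctedFrame)
  w <- min(frameIndex + 1, params$templateWindow)
  run <- template + (correctedFrame - template) / w
  if (params$templateMode == "two_pass_fixed" && !is.null(fixedMean))
    (run + fixedMean) / 2
  else run
}

# sequential-access frame source over an in-memory movie or multi-page TIFF
# part files; file access is chunk-cached so that peak resident input stays
# bounded at `chunk` frames
makeFrameSource <- function(x, chunk = 100L) {
  if (is(x, "VideoSequence")) {
    return(list(n = nFrames(x), dim = frameDim(x),
                get = function(i) x@frames[, , i, drop = TRUE]))
  }
  stopIfNot(is.character(x), "input must be a VideoSequence or file paths")
  counts <- vapply(x, tiffFrameCount, 1L)
  ends <- cumsum(counts)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  first <- tiff::readTIFF(x[1], as.is = TRUE)
  cache <- new.env(parent = emptyenv())
  cache$range <- c(0L, -1L)
  list(n = sum(counts), dim = dim(first), get = function(i) {
    if (i < cache$range[1] || i > cache$range[2]) {
      f <- which(i >= starts & i <= ends)[1]
      pg <- i - starts[f] + 1L
      hi <- min(pg + chunk - 1L, counts[f])
      pages <- tiff::readTIFF(x[f], all = pg:hi, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      cache$frames <- pages
      cache$range <- c(i, i + length(pages) - 1L)
    }
    cache$frames[[i - cache$range[1] + 1L]]
  })
}

#' Motion-correct a movie
#'
#' The sequential enhance-estimate-shift-update loop: every frame is
#' contrast-enhanced (so the static illumination pattern does not anchor the
#' registration), its displacement from the running template is estimated by
#' phase correlation, the native-depth frame is shifted back by the estimate,
#' and the template is updated with the aligned enhanced frame. The template
#' is seeded with the first frame. In \code{two_pass_fixed} mode a first
#' pass builds a fixed mean from randomly sampled, individually aligned
#' frames which is registered to the frame-1 template and blended into the
#' running template.
#'
#' @param video a \linkS4class{VideoSequence} (T >= 2), or a character
#'   vector of multi-page TIFF files (e.g. from
#'   \code{\link{renderMovieFiles}}), which are streamed in chunks so only
#'   the corrected movie is held in memory.
#' @param params a \code{\link{registrationParams}} list.
#' @param seed seed for the frame sampling of \code{two_pass_fixed} mode.
#' @param frameRate,pixelPitch metadata for file input (ignored when
#'   \code{video} is a VideoSequence).
#' @param chunkFrames frames per read chunk for file input.
#' @return list with \code{video} (corrected \linkS4class{VideoSequence},
#'   integer counts) and \code{displacement} (data.frame: frame, dx, dy,
#'   magnitudeUm, peakCorr). The mean +/- SD of \code{magnitudeUm} is the
#'   session motion metric, in um/frame.
#' @export
correctSequence <- function(video, params = registrationParams(), seed = 1,
                            frameRate = 20, pixelPitch = 1.312,
                            chunkFrames = 100L) {
  fromFiles <- is.character(video)
  if (!fromFiles) {
    frameRate <- video@frameRate
    pixelPitch <- video@pixelPitch
  }
  src <- makeFrameSource(video, chunkFrames)
  Tn <- src$n
  stopIfNot(Tn >= 2L, "at least 2 frames required")
  d <- src$dim
  isInt <- fromFiles || is.integer(video@frames)
  corrected <- array(if (isInt) 0L else 0, c(d[1], d[2], Tn))
  dx <- numeric(Tn); dy <- numeric(Tn); pk <- numeric(Tn)

  fixedMean <- NULL
  if (params$templateMode == "two_pass_fixed") {
    idx <- withSeed(seed, sort(sample.int(Tn,
      min(params$fixedSampleFrames, Tn))))
    ref <- homomorphicEnhance(src$get(idx[1]), params$filterSigma)
    acc <- ref
    for (i in idx[-1]) {
      e <- homomorphicEnhance(src$get(i), params$filterSigma)
      s <- estimateDisplacement(e, ref, params)
      acc <- acc + applyShift(e, -s[["dx"]], -s[["dy"]])
    }
    fixedMean <- acc / length(idx)
  }

  f1 <- src$get(1L)
  template <- homomorphicEnhance(f1, params$filterSigma)
  if (!is.null(fixedMean)) {
    # anchor the sampled mean to the frame-1 template so blending does not
    # bias the shift estimates
    s0 <- estimateDisplacement(fixedMean, template, params)
    fixedMean <- applyShift(fixedMean, -s0[["dx"]], -s0[["dy"]])
  }
  corrected[, , 1] <- f1
  pk[1] <- 1
  for (t in 2:Tn) {
    raw <- src$get(t)
    e <- homomorphicEnhance(raw, params$filterSigma)
    s <- estimateDisplacement(e, template, params)
    dx[t] <- s[["dx"]]; dy[t] <- s[["dy"]]; pk[t] <- s[["peakCorr"]]
    alignedRaw <- applyShift(raw, -dx[t], -dy[t])
    corrected[, , t] <- if (isInt) as.integer(round(alignedRaw))
                        else alignedRaw
    alignedEnh <- applyShift(e, -dx[t], -dy[t])
    template <- updateTemplate(template, alignedEnh, t - 1L, params,
                               fixedMean)
    if (t %% 250L == 0L) trimMemory()
  }
  trimMemory()
  disp <- data.frame(frame = seq_len(Tn), dx = dx, dy = dy,
                     magnitudeUm = sqrt(dx^2 + dy^2) * pixelPitch,
                     peakCorr = pk)
  list(video = VideoSequence(corrected, frameRate = frameRate,
                             pixelPitch = pixelPitch,
                             t0 = if (fromFiles) 0 else video@t0),
       displacement = disp)
}

#' Summarize a displacement trace
#'
#' @param displacement the data.frame returned by
#'   \code{\link{correctSequence}}.
#' @return list with \code{meanUm} and \code{sdUm} of the per-frame
#'   displacement magnitude.
#' @export
summarizeDisplacement <- function(displacement) {
  list(meanUm = mean(displacement$magnitudeUm),
       sdUm = stats::sd(displacement$magnitudeUm))
}
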