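#' Synthetic-movie generator parameters
#'
#' Builds a validated \linkS4class{SimParams} object. The defaults describe a
#' desk-scale wide-field recording of hippocampal CA1: 512 x 512 px at 20 Hz
#' and 1.312 um/px, 50 somata of ~15 um diameter, GCaMP6f-like transient
#' kinetics (fast rise, sub-second decay), static multiplicative illumination
#' non-uniformity, ~2.5 Hz sub-pixel respiratory motion with rare large
#' biphasic jumps, exponential photobleaching, and additive read noise plus
#' shot noise. Setting \code{readNoiseSigma = 0} disables all sensor noise
#' (shot noise included), giving a deterministic noise-free movie for exact
#' checks.
#'
#' Spontaneous transients are modelled as short bursts at
#' \code{backgroundRate} events/s per cell. Negatively task-modulated cells
#' are tonically active (rate multiplied by \code{negRateMultiplier}) and
#' their rate is suppressed by \code{suppressionFactor} for
#' \code{suppressionDuration} seconds after the tone of a correct trial;
#' positively modulated cells emit an extra transient with probability
#' \code{pOn} in the 0-0.6 s window after the tone of a correct trial.
#'
#' @param frameHeight,frameWidth,nFrames,frameRate,pixelPitch movie geometry
#'   and sampling.
#' @param nCells,somaRadius,background,cellF0,transientAmplitude scene
#'   brightness model (counts).
#' @param tauRise,tauDecay transient kinetics (s).
#' @param backgroundRate spontaneous transient rate (events/s/cell).
#' @param illumAmplitude,respFreq,respAmplitude,jumpRate,jumpAmplitude
#'   illumination and rigid-motion model.
#' @param bleachEndFraction fraction of initial intensity left at the last
#'   frame.
#' @param readNoiseSigma read noise SD in counts (0 = noise-free movie).
#' @param nTrials,itiRange,trialStartOffset,correctFraction trial schedule.
#' @param fracPositive,fracNegative,pOn,negRateMultiplier,suppressionFactor,
#'   suppressionDuration task-modulation model.
#' @param seed master seed for all randomness (per-component sub-streams).
#' @return A \linkS4class{SimParams}.
#' @examples
#' p <- simParams(frameHeight = 64, frameWidth = 64, nFrames = 100, nCells = 3)
#' p
#' @export
simParams <- function(frameHeight = 512, frameWidth = 512, nFrames = 2000,
                      frameRate = 20, pixelPitch = 1.312, nCells = 50,
                      somaRadius = 5.7, background = 1000, cellF0 = 150,
                      transientAmplitude = 600, tauRise = 0.045,
                      tauDecay = 0.40, backgroundRate = 0.1,
                      illumAmplitude = 0.2, respFreq = 2.5,
                      respAmplitude = 0.8, jumpRate = 0.02,
                      jumpAmplitude = 5, bleachEndFraction = 0.933,
                      readNoiseSigma = 10, nTrials = 40,
                      itiRange = c(31, 36), trialStartOffset = 6,
                      correctFraction = 0.825, fracPositive = 0.19,
                      fracNegative = 0.24, pOn = 0.9, negRateMultiplier = 3,
                      suppressionFactor = 0.1, suppressionDuration = 2,
                      seed = 1) {
  new("SimParams", frameHeight = frameHeight, frameWidth = frameWidth,
      nFrames = nFrames, frameRate = frameRate, pixelPitch = pixelPitch,
      nCells = nCells, somaRadius = somaRadius, background = background,
      cellF0 = cellF0, transientAmplitude = transientAmplitude,
      tauRise = tauRise, tauDecay = tauDecay,
      backgroundRate = backgroundRate, illumAmplitude = illumAmplitude,
      respFreq = respFreq, respAmplitude = respAmplitude,
      jumpRate = jumpRate, jumpAmplitude = jumpAmplitude,
      bleachEndFraction = bleachEndFraction, readNoiseSigma = readNoiseSigma,
      nTrials = nTrials, itiRange = itiRange,
      trialStartOffset = trialStartOffset, correctFraction = correctFraction,
      fracPositive = fracPositive, fracNegative = fracNegative, pOn = pOn,
      negRateMultiplier = negRateMultiplier,
      suppressionFactor = suppressionFactor,
      suppressionDuration = suppressionDuration, seed = seed)
}

#' Calcium transient impulse response
#'
#' \code{k(t) = (1 - exp(-t/tauRise)) * exp(-t/tauDecay)} for \code{t >= 0},
#' 0 otherwise. Note the peak value is below 1; amplitudes multiply this
#' kernel as-is.
#'
#' @param t time since event onset, seconds (vectorized).
#' @param tauRise,tauDecay kinetics in seconds.
#' @return kernel values, same length as \code{t}.
#' @examples
#' transientKernel(c(-0.1, 0, 0.1, 0.5), 0.045, 0.4)
#' @export
transientKernel <- function(t, tauRise = 0.045, tauDecay = 0.40) {
  ifelse(t >= 0, (1 - exp(-t / tauRise)) * exp(-t / tauDecay), 0)
}

# time after which the kernel is negligible (< 1e-3 of amplitude)
kernelSupport <- function(tauRise, tauDecay) tauRise + tauDecay * log(1e3)

#' Static multiplicative illumination field
#'
#' A radially symmetric vignetting field: brightest at the frame center,
#' falling quadratically so that the corner-to-center ratio equals
#' \code{1 - amplitude}.
#'
#' @param h,w frame dimensions in pixels.
#' @param amplitude fractional drop from center to corner.
#' @return An \code{h x w} matrix with value 1 at the center pixel.
#' @export
illuminationField <- function(h, w, amplitude) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  1 - amplitude * d2 / max(d2)
}

# radially flat-topped soma profile (supergaussian): ~1 inside the soma,
# falling steeply near radius R, ~0 beyond
somaProfile <- function(d, radius) 1 / (1 + (d / radius)^8)

# exponential bleaching curve from 1 (first frame) to endFraction (last)
bleachCurve <- function(nFrames, endFraction) {
  if (nFrames == 1L) return(1)
  endFraction^((seq_len(nFrames) - 1) / (nFrames - 1))
}

# homogeneous Poisson event times on [0, duration)
poissonTimes <- function(rate, duration) {
  n <- stats::rpois(1L, rate * duration)
  sort(stats::runif(n, 0, duration))
}

#' Plant the ground truth for a synthetic movie
#'
#' Draws everything the simulator will render: non-overlapping cell
#' positions (minimum center separation of one soma diameter), per-cell
#' transient times from a Poisson process (modulated around planted trial
#' outcomes for positively/negatively labelled cells), the rigid-motion
#' trace (respiratory sinusoid plus rare biphasic jumps), and the trial
#' schedule with planted outcomes. Deterministic given
#' \code{params@seed}; each component draws from its own sub-stream so
#' changing, say, the motion model does not perturb cell placement.
#'
#' @param params a \linkS4class{SimParams}.
#' @return A \linkS4class{GroundTruth}.
#' @examples
#' gt <- makeGroundTruth(simParams(frameHeight = 128, frameWidth = 128,
#'                                 nFrames = 200, nCells = 5))
#' gt
#' @export
makeGroundTruth <- function(params) {
  validObject(params)
  p <- params
  seeds <- subSeeds(p@seed, c("placement", "schedule", "labels", "events",
                              "motion", "noise", "eyelid", "traceNoise"))
  duration <- p@nFrames / p@frameRate
  H <- as.integer(p@frameHeight); W <- as.integer(p@frameWidth)
  nCells <- as.integer(p@nCells)

  # --- trial schedule with planted outcomes ---------------------------------
  schedule <- withSeed(seeds$schedule, {
    sch <- generateTrialSchedule(n = as.integer(p@nTrials),
                                 itiRange = p@itiRange,
                                 startOffset = p@trialStartOffset)
    # keep trials whose baseline and response windows fit in the movie
    sch <- sch[sch$toneOnset - 3 >= 0 & sch$toneOnset + 8 <= duration, ,
               drop = FALSE]
    if (nrow(sch)) {
      sch$trial <- seq_len(nrow(sch))
      nCorrect <- round(p@correctFraction * nrow(sch))
      outcome <- rep("incorrect", nrow(sch))
      outcome[sample.int(nrow(sch), nCorrect)] <- "correct"
      sch$outcome <- outcome
    }
    sch
  })
  correctTones <- schedule$toneOnset[schedule$outcome == "correct"]

  # --- modulation labels -----------------------------------------------------
  label <- withSeed(seeds$labels, {
    lab <- rep("none", nCells)
    nPos <- round(p@fracPositive * nCells)
    nNeg <- round(p@fracNegative * nCells)
    idx <- if (nCells) sample.int(nCells) else integer(0)
    lab[idx[seq_len(nPos)]] <- "positive"
    lab[idx[nPos + seq_len(nNeg)]] <- "negative"
    lab
  })

  # --- cell placement (dart throwing) ---------------------------------------
  centers <- withSeed(seeds$placement, {
    margin <- ceiling(p@somaRadius) + 1
    minSep2 <- (2 * p@somaRadius)^2
    out <- matrix(NA_real_, nCells, 2)
    placed <- 0L
    tries <- 0L
    maxTries <- 500L * max(nCells, 1L)
    while (placed < nCells && tries < maxTries) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, H - margin),
                stats::runif(1, margin, W - margin))
      if (placed == 0L ||
          min((out[seq_len(placed), 1] - cand[1])^2 +
              (out[seq_len(placed), 2] - cand[2])^2) >= minSep2) {
        placed <- placed + 1L
        out[placed, ] <- cand
      }
    }
    if (placed < nCells)
      stop("cell placement infeasible at this density: ",
           placed, " of ", nCells, " cells placed")
    out
  })
  colnames(centers) <- c("row", "col")

  # --- disjoint cell masks: pixels within somaRadius of the nearest center --
  masks <- matrix(0L, H, W)
  if (nCells) {
    r <- ceiling(p@somaRadius)
    for (k in seq_len(nCells)) {
      rows <- max(1, floor(centers[k, 1] - r)):min(H, ceiling(centers[k, 1] + r))
      cols <- max(1, floor(centers[k, 2] - r)):min(W, ceiling(centers[k, 2] + r))
      d2 <- outer((rows - centers[k, 1])^2, (cols - centers[k, 2])^2, `+`)
      sel <- d2 <= p@somaRadius^2
      block <- masks[rows, cols]
      block[sel & block == 0L] <- k
      masks[rows, cols] <- block
    }
  }

  # --- event times -----------------------------------------------------------
  eventTimes <- withSeed(seeds$events, {
    lapply(seq_len(nCells), function(k) {
      rate <- p@backgroundRate *
        if (label[k] == "negative") p@negRateMultiplier else 1
      ev <- poissonTimes(rate, duration)
      if (label[k] == "negative" && length(correctTones)) {
        # suppress the tonic rate for suppressionDuration after each correct
        # tone by thinning
        inWin <- vapply(ev, function(t)
          any(t >= correctTones & t < correctTones + p@suppressionDuration),
          logical(1))
        drop <- inWin & stats::runif(length(ev)) > p@suppressionFactor
        ev <- ev[!drop]
      }
      ev
    })
  })
  # positive-cell extra events from their own sub-stream
  eventTimes <- withSeed(seeds$events + 1, {
    lapply(seq_len(nCells), function(k) {
      ev <- eventTimes[[k]]
      if (label[k] == "positive" && length(correctTones)) {
        on <- stats::runif(length(correctTones)) < p@pOn
        ev <- sort(c(ev, correctTones[on] +
                       stats::runif(sum(on), 0.02, 0.58)))
      }
      ev
    })
  })

  # --- rigid motion ----------------------------------------------------------
  motion <- withSeed(seeds$motion, {
    tt <- (seq_len(p@nFrames) - 1) / p@frameRate
    dx <- p@respAmplitude * sin(2 * pi * p@respFreq * tt)
    dy <- p@respAmplitude * sin(2 * pi * p@respFreq * tt + pi / 2)
    jt <- poissonTimes(p@jumpRate, duration)
    for (t0 in jt) {
      f <- floor(t0 * p@frameRate) + 1
      if (f > p@nFrames) next
      ang <- stats::runif(1, 0, 2 * pi)
      amp <- p@jumpAmplitude * stats::runif(1, 0.5, 1)
      dx[f] <- dx[f] + amp * cos(ang)
      dy[f] <- dy[f] + amp * sin(ang)
      if (f + 1 <= p@nFrames) {        # biphasic overshoot on the next frame
        dx[f + 1] <- dx[f + 1] - 0.4 * amp * cos(ang)
        dy[f + 1] <- dy[f + 1] - 0.4 * amp * sin(ang)
      }
    }
    cbind(dx = dx, dy = dy)
  })

  new("GroundTruth", cellCenters = centers, cellMasks = masks,
      eventTimes = eventTimes, modulationLabel = label,
      motionTrace = motion, schedule = schedule, params = p)
}

# per-cell rendering patch: pixel indices (linear) and profile values within
# 2 radii of the center
cellPatch <- function(center, radius, H, W) {
  r <- ceiling(2 * radius)
  rows <- max(1, floor(center[1] - r)):min(H, ceiling(center[1] + r))
  cols <- max(1, floor(center[2] - r)):min(W, ceiling(center[2] + r))
  d <- sqrt(outer((rows - center[1])^2, (cols - center[2])^2, `+`))
  idx <- as.vector(outer(rows, (cols - 1) * H, `+`))
  prof <- somaProfile(as.vector(d), radius)
  keep <- prof > 1e-4
  list(idx = idx[keep], prof = prof[keep])
}

# shared frame renderer: calls consume(frameIndex, integerMatrix) for every
# frame in order, inside the noise sub-stream
renderCore <- function(gt, params, consume) {
  p <- params
  stopIfNot(nrow(gt@motionTrace) == p@nFrames,
            "ground truth is inconsistent with 'params'")
  H <- as.integer(p@frameHeight); W <- as.integer(p@frameWidth)
  Tn <- as.integer(p@nFrames)
  nCells <- nrow(gt@cellCenters)
  seeds <- subSeeds(p@seed, c("placement", "schedule", "labels", "events",
                              "motion", "noise", "eyelid", "traceNoise"))

  static <- matrix(p@background, H, W)
  patches <- vector("list", nCells)
  for (k in seq_len(nCells)) {
    patches[[k]] <- cellPatch(gt@cellCenters[k, ], p@somaRadius, H, W)
    static[patches[[k]]$idx] <- static[patches[[k]]$idx] +
      p@cellF0 * patches[[k]]$prof
  }

  # per-frame table of active (cell, kernel value) pairs
  support <- kernelSupport(p@tauRise, p@tauDecay)
  activeByFrame <- vector("list", Tn)
  tFrames <- (seq_len(Tn) - 1) / p@frameRate
  for (k in seq_len(nCells)) {
    for (te in gt@eventTimes[[k]]) {
      f0 <- max(1L, floor(te * p@frameRate) + 1L)
      f1 <- min(Tn, ceiling((te + support) * p@frameRate))
      if (f0 > f1) next
      kv <- transientKernel(tFrames[f0:f1] - te, p@tauRise, p@tauDecay)
      for (j in seq_along(kv)) {
        f <- f0 + j - 1L
        activeByFrame[[f]] <- c(activeByFrame[[f]], k, kv[j])
      }
    }
  }

  illum <- illuminationField(H, W, p@illumAmplitude)
  bleach <- bleachCurve(Tn, p@bleachEndFraction)
  noiseFree <- p@readNoiseSigma == 0

  withSeed(seeds$noise, {
    for (f in seq_len(Tn)) {
      content <- static
      act <- activeByFrame[[f]]
      if (!is.null(act)) {
        cells <- act[seq(1, length(act), 2)]
        kvals <- act[seq(2, length(act), 2)]
        for (j in seq_along(cells)) {
          pp <- patches[[cells[j]]]
          content[pp$idx] <- content[pp$idx] +
            p@transientAmplitude * kvals[j] * pp$prof
        }
      }
      if (any(gt@motionTrace[f, ] != 0))
        content <- .bilinearShift(content, gt@motionTrace[f, 1],
                                  gt@motionTrace[f, 2])
      signal <- illum * (bleach[f] * content)
      if (!noiseFree)
        signal <- signal + stats::rnorm(length(signal)) *
          sqrt(p@readNoiseSigma^2 + pmax(signal, 0))
      consume(f, matrix(as.integer(clampRange(round(signal), 0, 65535)),
                        H, W))
      if (f %% 250L == 0L) trimMemory()
    }
  })
  invisible(NULL)
}

#' Render the synthetic movie
#'
#' Renders each frame as
#' \code{quantize16(illum * bleach(t) * shift(content(t)) + noise)} where
#' \code{content(t)} is the static scene (tissue background plus resting
#' somata) with transient kernels added for every active event, shifted by
#' the planted rigid motion; the illumination field is static in the camera
#' frame (it does not move with the tissue). Noise is Gaussian with variance
#' \code{readNoiseSigma^2 + signal} (read + shot); with
#' \code{readNoiseSigma = 0} the movie is rendered noise-free. Output is
#' quantized to 16-bit integer counts.
#'
#' \code{renderMovie} returns the whole movie in memory;
#' \code{renderMovieFiles} writes it as a sequence of multi-page TIFF parts
#' (bit-identical pixels) so that sessions larger than memory can be
#' rendered and then processed with the streaming input of
#' \code{\link{correctSequence}}.
#'
#' @param gt a \linkS4class{GroundTruth} from \code{\link{makeGroundTruth}}.
#' @param params the same \linkS4class{SimParams} used to build \code{gt}.
#' @return A \linkS4class{VideoSequence} with integer frames
#'   (\code{renderMovie}), or the character vector of part files
#'   (\code{renderMovieFiles}).
#' @export
renderMovie <- function(gt, params) {
  p <- params
  frames <- array(0L, c(as.integer(p@frameHeight), as.integer(p@frameWidth),
                        as.integer(p@nFrames)))
  renderCore(gt, params, function(f, fr) frames[, , f] <<- fr)
  VideoSequence(frames, frameRate = p@frameRate, pixelPitch = p@pixelPitch)
}

#' @rdname renderMovie
#' @param dir directory for the TIFF parts (created if needed).
#' @param framesPerFile pages per TIFF part.
#' @export
renderMovieFiles <- function(gt, params, dir = tempfile("movie"),
                             framesPerFile = 250L) {
  p <- params
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Tn <- as.integer(p@nFrames)
  paths <- character(0)
  buf <- vector("list", min(framesPerFile, Tn))
  nbuf <- 0L
  flush <- function() {
    if (nbuf == 0L) return(invisible())
    path <- file.path(dir, sprintf("part%04d.tif", length(paths) + 1L))
    tiff::writeTIFF(lapply(buf[seq_len(nbuf)], function(m) m / 65535),
                    path, bits.per.sample = 16L)
    paths[length(paths) + 1L] <<- path
    nbuf <<- 0L
  }
  renderCore(gt, params, function(f, fr) {
    nbuf <<- nbuf + 1L
    buf[[nbuf]] <<- fr
    if (nbuf == framesPerFile) flush()
  })
  flush()
  paths
}

#' Render idealized per-cell traces
#'
#' The trace-level shortcut of the renderer: for each planted cell, the mean
#' fluorescence over its mask is computed in closed form (resting level plus
#' transient kernels, scaled by the bleaching curve) and perturbed by
#' Gaussian noise with the variance expected from averaging independent
#' pixel noise over the mask. Useful for testing trial statistics at session
#' lengths where rendering full frames would be wasteful; it shares the
#' event/schedule ground truth with \code{\link{renderMovie}} but has no
#' motion, illumination or quantization.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param params the matching \linkS4class{SimParams}.
#' @return A \linkS4class{TraceMatrix} with raw traces (one row per cell).
#' @export
renderCellTraces <- function(gt, params) {
  p <- params
  nCells <- nrow(gt@cellCenters)
  Tn <- as.integer(p@nFrames)
  tt <- (seq_len(Tn) - 1) / p@frameRate
  areas <- tabulate(gt@cellMasks[gt@cellMasks > 0], nbins = max(nCells, 1L))
  areas[areas == 0] <- 1L
  bleach <- bleachCurve(Tn, p@bleachEndFraction)
  support <- kernelSupport(p@tauRise, p@tauDecay)
  seeds <- subSeeds(p@seed, c("placement", "schedule", "labels", "events",
                              "motion", "noise", "eyelid", "traceNoise"))
  raw <- matrix(0, nCells, Tn)
  withSeed(seeds$traceNoise, {
    for (k in seq_len(nCells)) {
      f <- p@background + p@cellF0
      ev <- gt@eventTimes[[k]]
      tr <- rep(f, Tn)
      for (te in ev) {
        f0 <- max(1L, floor(te * p@frameRate) + 1L)
        f1 <- min(Tn, ceiling((te + support) * p@frameRate))
        if (f0 > f1) next
        tr[f0:f1] <- tr[f0:f1] + p@transientAmplitude *
          transientKernel(tt[f0:f1] - te, p@tauRise, p@tauDecay)
      }
      tr <- bleach * tr
      if (p@readNoiseSigma > 0)
        tr <- tr + stats::rnorm(Tn) *
          sqrt((p@readNoiseSigma^2 + pmax(tr, 0)) / areas[k])
      raw[k, ] <- tr
    }
  })
  new("TraceMatrix", raw = raw, dff = matrix(0, 0, 0), fAvg = numeric(0),
      times = tt, frameRate = p@frameRate)
}

#' Render a synthetic eyelid-reflection trace
#'
#' Eyelid closure is recorded as an increase in reflection. The trace is
#' Gaussian baseline noise; on planted-correct trials a conditioned-response
#' deflection of \code{crAmplitude} (in baseline-SD units) begins at a
#' random time inside the 0-0.6 s post-tone window; every trial additionally
#' carries an unconditioned blink just after the air puff (which is outside
#' the scoring window). Incorrect trials have no pre-puff deflection.
#' Deterministic given the ground truth's seed.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param params the matching \linkS4class{SimParams}.
#' @param crAmplitude conditioned-response amplitude, in units of the
#'   baseline SD.
#' @param urAmplitude unconditioned (post-puff) blink amplitude, same units.
#' @param baselineSd baseline noise SD (arbitrary reflection units).
#' @return numeric vector of length \code{nFrames} (the reflection trace).
#' @export
renderEyelid <- function(gt, params, crAmplitude = 10, urAmplitude = 15,
                         baselineSd = 1) {
  p <- params
  Tn <- as.integer(p@nFrames)
  rate <- p@frameRate
  seeds <- subSeeds(p@seed, c("placement", "schedule", "labels", "events",
                              "motion", "noise", "eyelid", "traceNoise"))
  # deflection shape: 0.1 s linear rise, 0.25 s plateau, 0.3 s linear decay
  bump <- function(trace, onset, amp) {
    tt <- (seq_len(Tn) - 1) / rate - onset
    shape <- ifelse(tt < 0, 0,
             ifelse(tt < 0.1, tt / 0.1,
             ifelse(tt < 0.35, 1,
             ifelse(tt < 0.65, 1 - (tt - 0.35) / 0.3, 0))))
    trace + amp * shape
  }
  withSeed(seeds$eyelid, {
    trace <- stats::rnorm(Tn, 0, baselineSd)
    for (i in seq_len(nrow(gt@schedule))) {
      tone <- gt@schedule$toneOnset[i]
      puff <- gt@schedule$puffOnset[i]
      if (gt@schedule$outcome[i] == "correct" && crAmplitude > 0)
        trace <- bump(trace, tone + stats::runif(1, 0.05, 0.40),
                      crAmplitude * baselineSd)
      if (urAmplitude > 0)
        trace <- bump(trace, puff + 0.05, urAmplitude * baselineSd)
    }
    trace
  })
}
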