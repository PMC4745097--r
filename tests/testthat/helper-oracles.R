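# Shared fixtures and independent reference implementations used as oracles.

withSeed <- widecal:::withSeed
windowIndices <- widecal:::windowIndices

# small simulator configurations ---------------------------------------------

tinySim <- function(...) {
  args <- utils::modifyList(
    list(frameHeight = 96, frameWidth = 96, nFrames = 120, nCells = 4,
         respAmplitude = 0, jumpRate = 0, illumAmplitude = 0,
         bleachEndFraction = 1, seed = 7),
    list(...))
  do.call(simParams, args)
}

# a noise-free single-cell scene with a hand-planted event list
plantedSingleCell <- function(center = c(48.5, 40.5), events = 2.0,
                              nFrames = 160, ...) {
  p <- simParams(frameHeight = 96, frameWidth = 96, nFrames = nFrames,
                 nCells = 1, readNoiseSigma = 0, respAmplitude = 0,
                 jumpRate = 0, illumAmplitude = 0, bleachEndFraction = 1,
                 backgroundRate = 0, fracPositive = 0, fracNegative = 0,
                 seed = 5, ...)
  gt <- makeGroundTruth(p)
  gt@cellCenters[1, ] <- center
  gt@eventTimes[[1]] <- events
  # rebuild the label mask around the overridden center
  d2 <- outer((seq_len(96) - center[1])^2, (seq_len(96) - center[2])^2, `+`)
  gt@cellMasks <- matrix(as.integer(d2 <= p@somaRadius^2), 96, 96)
  list(gt = gt, params = p)
}

# single-frame ROI fixtures ---------------------------------------------------

# a square detection of side `side` whose top-left corner is at (r, c)
sfroiRow <- function(frame, r, c, side = 10, H = 512) {
  px <- as.vector(outer(r:(r + side - 1), (c:(c + side - 1) - 1) * H, `+`))
  df <- data.frame(frame = frame, area = side^2,
                   centroidR = r + (side - 1) / 2,
                   centroidC = c + (side - 1) / 2,
                   r0 = r, r1 = r + side, c0 = c, c1 = c + side,
                   meanIntensity = 1, maxIntensity = 1)
  df$pixels <- list(sort(px))
  df
}

# n detections of one cell jittered around (r, c) over frames 1..n
sfroiCell <- function(r, c, n, side = 10, H = 512, jitter = 0, seed = 1) {
  jr <- withSeed(seed, round(stats::runif(2 * n, -jitter, jitter)))
  do.call(rbind, lapply(seq_len(n), function(f)
    sfroiRow(f, r + jr[f], c + jr[n + f], side, H)))
}

# reference single-linkage clustering: no blocking, same join rule
# (frame order, nearest similar cluster by centroid distance); returns the
# partition as a list of sorted row-index vectors
refCluster <- function(sf, params) {
  sf <- sf[order(sf$frame), , drop = FALSE]
  cen <- list(); box <- list(); members <- list()
  for (i in seq_len(nrow(sf))) {
    bestK <- 0; bestD <- Inf
    for (k in seq_along(members)) {
      d <- sqrt((cen[[k]][1] - sf$centroidR[i])^2 +
                (cen[[k]][2] - sf$centroidC[i])^2)
      if (d > params$centroidTol) next
      dUL <- sqrt((box[[k]][1] - sf$r0[i])^2 + (box[[k]][3] - sf$c0[i])^2)
      dLR <- sqrt((box[[k]][2] - sf$r1[i])^2 + (box[[k]][4] - sf$c1[i])^2)
      if (dUL > params$bboxTol || dLR > params$bboxTol) next
      if (d < bestD) { bestD <- d; bestK <- k }
    }
    if (bestK == 0) {
      cen <- c(cen, list(c(sf$centroidR[i], sf$centroidC[i])))
      box <- c(box, list(c(sf$r0[i], sf$r1[i], sf$c0[i], sf$c1[i])))
      members <- c(members, list(i))
    } else {
      m <- length(members[[bestK]])
      cen[[bestK]] <- (cen[[bestK]] * m +
                       c(sf$centroidR[i], sf$centroidC[i])) / (m + 1)
      box[[bestK]] <- (box[[bestK]] * m +
                       c(sf$r0[i], sf$r1[i], sf$c0[i], sf$c1[i])) / (m + 1)
      members[[bestK]] <- c(members[[bestK]], i)
    }
  }
  lapply(members, sort)
}

# reference overlap filter: repeated full rescan, same drop rule
refFilterSeparated <- function(masks, nApp, maxIou) {
  alive <- rep(TRUE, length(masks))
  iou <- function(a, b) {
    i <- length(intersect(a, b))
    i / (length(a) + length(b) - i)
  }
  repeat {
    worst <- 0; wi <- 0; wj <- 0
    idx <- which(alive)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      v <- iou(masks[[i]], masks[[j]])
      if (v > maxIou && v > worst) { worst <- v; wi <- i; wj <- j }
    }
    if (worst == 0) break
    ai <- nApp[wi]; aj <- nApp[wj]
    loser <- if (ai != aj) { if (ai < aj) wi else wj }
      else if (length(masks[[wi]]) != length(masks[[wj]])) {
        if (length(masks[[wi]]) < length(masks[[wj]])) wi else wj
      } else max(wi, wj)
    alive[loser] <- FALSE
  }
  which(alive)
}

# exhaustive permutation two-sided p for the rank-sum statistic, plus the
# probability mass of the null atom at the observed value (the resolution
# limit any continuous approximation can be held to)
permRankSumP <- function(a, b) {
  x <- c(a, b)
  na <- length(a); N <- length(x)
  r <- rank(x)
  mu <- na * (N + 1) / 2
  obs <- abs(sum(r[seq_len(na)]) - mu)
  combs <- utils::combn(N, na)
  stat <- apply(combs, 2, function(idx) abs(sum(r[idx]) - mu))
  p <- mean(stat >= obs - 1e-12)
  attr(p, "atom") <- mean(abs(stat - obs) < 1e-12)
  p
}

# shift an image by (dx, dy) in the Fourier domain (periodic, band-limited)
fourierShift <- function(x, dx, dy) {
  H <- nrow(x); W <- ncol(x)
  ky <- c(0:floor(H / 2), -(ceiling(H / 2) - 1):-1)
  kx <- c(0:floor(W / 2), -(ceiling(W / 2) - 1):-1)
  ph <- exp(-2i * pi * (outer(ky, rep(1, W)) * dy / H +
                        outer(rep(1, H), kx) * dx / W))
  Re(stats::fft(stats::fft(x) * ph, inverse = TRUE)) / (H * W)
}

# smooth periodic test image (band-limited so Fourier shifts are exact)
smoothPeriodicImage <- function(n = 128, seed = 11, cut = 10) {
  z <- withSeed(seed, matrix(stats::rnorm(n * n), n, n))
  Fz <- stats::fft(z)
  # zero all frequencies above `cut` cycles per image
  ky <- pmin(0:(n - 1), n - 0:(n - 1))
  mask <- outer(ky <= cut, ky <= cut)
  x <- Re(stats::fft(Fz * mask, inverse = TRUE)) / (n * n)
  100 + 10 * x / stats::sd(x)
}
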