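# z-scoring, adaptive thresholding, morphology, component labeling.

test_that("z-scores match the definition and a brute-force oracle", {
  set.seed(5)
  fr <- array(rnorm(8 * 8 * 100, 50, 5), c(8, 8, 100))
  v <- VideoSequence(fr)
  st <- computePixelStats(v)
  expect_true(all(abs(zscoreFrame(st@mean, st)) < 1e-12))
  z15 <- zscoreFrame(st@mean + 1.5 * st@sd, st)
  expect_equal(max(abs(z15 - 1.5)), 0, tolerance = 1e-12)
  z <- zscoreFrame(fr[, , 7], st)
  for (i in 1:8) for (j in 1:8) {
    x <- fr[i, j, ]
    expect_equal(z[i, j],
                 (fr[i, j, 7] - mean(x)) / sqrt(mean((x - mean(x))^2)))
  }
  # zero-SD pixels are flagged, not infinite
  cv <- VideoSequence(array(3, c(2, 2, 5)))
  zc <- zscoreFrame(matrix(9, 2, 2), computePixelStats(cv))
  expect_true(all(zc == 0))
  expect_equal(length(attr(zc, "flagged")), 4)
})

test_that("the adaptive threshold stays put, floors, and rises as needed", {
  set.seed(6)
  # active fraction already inside bounds at z0 = 1.5
  z <- matrix(0, 100, 100)
  z[sample.int(10000, 50)] <- 3      # 0.5% active
  m <- adaptiveThreshold(z)
  expect_equal(attr(m, "threshold"), 1.5)
  expect_equal(sum(m), 50)

  # all-zero map: threshold walks down to the floor, mask stays empty
  m0 <- adaptiveThreshold(matrix(0, 50, 50))
  expect_equal(attr(m0, "threshold"), 1.0)
  expect_false(any(m0))

  # global brightening: half the pixels well above 1.5 forces the
  # threshold up until the active fraction is inside the target
  zb <- matrix(abs(rnorm(10000, 0, 2)), 100, 100)
  mb <- adaptiveThreshold(zb)
  th <- attr(mb, "threshold")
  expect_gt(th, 1.5)
  expect_lte(mean(zb > th), 0.01)
})

test_that("threshold adjustment terminates inside the target or at the cap", {
  set.seed(61)
  for (i in 1:10) {
    z <- matrix(rnorm(2500, sample(c(0, 2, 5), 1), runif(1, 0.5, 3)), 50, 50)
    m <- adaptiveThreshold(z)
    th <- attr(m, "threshold")
    expect_true(mean(z > th) <= 0.01 || th == 6.0)
  }
})

test_that("morphological cleanup removes speckle and fills pinholes", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_identical(cleanBinary(sq), sq)

  speck <- matrix(FALSE, 20, 20); speck[10, 10] <- TRUE
  expect_false(any(cleanBinary(speck)))

  holed <- sq; holed[10, 10] <- FALSE
  expect_identical(cleanBinary(holed), sq)
})

test_that("component labeling respects area bounds, bboxes and connectivity", {
  m <- matrix(FALSE, 60, 60)
  m[5:16, 5:14] <- TRUE            # 120 px
  m[30:41, 40:49] <- TRUE          # 120 px
  fr <- matrix(1, 60, 60)
  rois <- labelComponents(m, fr, detectionParams(), frameIndex = 3L)
  expect_equal(nrow(rois), 2)
  expect_equal(rois$area, c(120, 120))
  expect_equal(rois$frame, c(3L, 3L))
  expect_equal(rois$centroidR[1], mean(5:16))
  expect_equal(unlist(rois[1, c("r0", "r1", "c0", "c1")], use.names = FALSE),
               c(5, 17, 5, 15))

  # below and above the area bounds
  small <- matrix(FALSE, 20, 20); small[1:2, 1:5] <- TRUE   # 10 px
  expect_equal(nrow(labelComponents(small, fr[1:20, 1:20])), 0)
  big <- matrix(FALSE, 30, 30); big[2:21, 2:21] <- TRUE     # 400 px
  expect_equal(nrow(labelComponents(big, matrix(1, 30, 30))), 0)

  # a pure diagonal: one component under 8-connectivity, six under 4
  di <- matrix(FALSE, 10, 10)
  di[cbind(2:7, 2:7)] <- TRUE
  p8 <- detectionParams(areaBounds = c(1, 100), connectivity = 8)
  p4 <- detectionParams(areaBounds = c(1, 100), connectivity = 4)
  expect_equal(nrow(labelComponents(di, matrix(1, 10, 10), p8)), 1)
  expect_equal(nrow(labelComponents(di, matrix(1, 10, 10), p4)), 6)
})

test_that("detection is translation-covariant under circular shifts", {
  p <- tinySim(backgroundRate = 0.4, seed = 17)
  gt <- makeGroundTruth(p)
  m <- renderMovie(gt, p)
  roll <- function(a, dy, dx) {
    H <- dim(a)[1]; W <- dim(a)[2]
    a[((seq_len(H) - 1 - dy) %% H) + 1, ((seq_len(W) - 1 - dx) %% W) + 1, ,
      drop = FALSE]
  }
  shifted <- VideoSequence(roll(m@frames, 7, 5))
  s1 <- detectRois(m, computePixelStats(m))
  s2 <- detectRois(shifted, computePixelStats(shifted))
  expect_equal(nrow(s2), nrow(s1))
  # compare as sets: every shifted centroid must reappear exactly
  key <- function(fr, r, cc)
    sort(sprintf("%d:%.3f:%.3f", fr, r, cc))
  expect_identical(
    key(s2$frame, s2$centroidR, s2$centroidC),
    key(s1$frame, ((s1$centroidR + 7 - 1) %% 96) + 1,
        ((s1$centroidC + 5 - 1) %% 96) + 1))
})

test_that("frames without active cells yield no detections", {
  p <- tinySim(backgroundRate = 0, readNoiseSigma = 0, fracPositive = 0,
               fracNegative = 0, nFrames = 10)
  gt <- makeGroundTruth(p)
  m <- renderMovie(gt, p)
  # constant movie: every pixel has zero SD, z = 0 everywhere
  sf <- detectRois(m, computePixelStats(m))
  expect_equal(nrow(sf), 0)
})

test_that("events well above the noise are detected near the planted center", {
  p <- simParams(frameHeight = 128, frameWidth = 128, nFrames = 300,
                 nCells = 8, respAmplitude = 0, jumpRate = 0,
                 illumAmplitude = 0.1, bleachEndFraction = 1,
                 backgroundRate = 0.1, fracPositive = 0, fracNegative = 0,
                 seed = 19)
  gt <- makeGroundTruth(p)
  m <- renderMovie(gt, p)
  sf <- detectRois(m, computePixelStats(m))
  # per-event recall: an event is detected if a single-frame ROI centroid
  # falls within one soma radius of its cell within 0.5 s of onset
  events <- do.call(rbind, lapply(seq_len(8), function(k)
    if (length(gt@eventTimes[[k]]))
      data.frame(cell = k, t = gt@eventTimes[[k]])))
  events <- events[events$t < (p@nFrames / p@frameRate) - 1, ]
  hit <- vapply(seq_len(nrow(events)), function(i) {
    k <- events$cell[i]
    f0 <- floor(events$t[i] * p@frameRate) + 1
    cand <- sf[sf$frame >= f0 & sf$frame <= f0 + 10, ]
    any(sqrt((cand$centroidR - gt@cellCenters[k, 1])^2 +
             (cand$centroidC - gt@cellCenters[k, 2])^2) <= p@somaRadius)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
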