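# Homomorphic enhancement, phase correlation, shifting, motion correction.

test_that("enhancement leaves a constant frame unchanged", {
  f <- matrix(123.4, 64, 64)
  out <- homomorphicEnhance(f, 16)
  expect_equal(out, f, tolerance = 1e-10)
  expect_error(homomorphicEnhance(matrix(c(1, NA, 1, 1), 2, 2), 4),
               "non-finite")
})

test_that("enhancement flattens a multiplicative illumination ramp", {
  ramp <- matrix(rep(seq(0.8, 1.2, length.out = 256), each = 256), 256, 256)
  x <- 100 * ramp                       # flat tissue times illumination
  y <- homomorphicEnhance(x, 32)
  cv <- function(m) sd(m) / mean(m)
  expect_lt(cv(y), cv(x) / 10)
})

test_that("enhancement preserves the local contrast of a small bright spot", {
  ramp <- matrix(rep(seq(0.8, 1.2, length.out = 256), each = 256), 256, 256)
  x <- 100 * ramp
  spot <- cbind(c(128, 127, 129, 128, 128), c(64, 64, 64, 63, 65))
  x[spot] <- 3 * x[spot]                # 5-px spot, local contrast 3
  y <- homomorphicEnhance(x, 32)
  win <- y[118:138, 54:74]
  isSpot <- matrix(FALSE, 21, 21)
  isSpot[cbind(spot[, 1] - 117, spot[, 2] - 53)] <- TRUE
  contrast <- y[128, 64] / mean(win[!isSpot])
  inContrast <- x[128, 64] / mean((x[118:138, 54:74])[!isSpot])
  expect_equal(contrast, inContrast, tolerance = 0.05)
})

test_that("integer circular shifts are recovered exactly", {
  x <- smoothPeriodicImage(128)
  roll <- function(m, dy, dx) {
    n <- nrow(m); w <- ncol(m)
    m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
  }
  p <- registrationParams(subpixel = FALSE)
  expect_equal(unname(estimateDisplacement(x, x, p)[1:2]), c(0, 0))
  s <- estimateDisplacement(roll(x, -2, 3), x, p)
  expect_equal(unname(s[1:2]), c(3, -2))
  # equivariance over several integer shifts
  for (sh in list(c(5, 1), c(-4, 7), c(0, -6), c(12, -9))) {
    est <- estimateDisplacement(roll(x, sh[2], sh[1]), x, p)
    expect_equal(unname(est[1:2]), sh)
  }
})

test_that("subpixel shifts are recovered within a quarter pixel", {
  x <- smoothPeriodicImage(128)
  moved <- fourierShift(x, 0.50, 0.25)
  s <- estimateDisplacement(moved, x, registrationParams(subpixel = TRUE))
  expect_lt(abs(s[["dx"]] - 0.50), 0.25)
  expect_lt(abs(s[["dy"]] - 0.25), 0.25)
})

test_that("degenerate all-zero frames are rejected", {
  z <- matrix(0, 32, 32)
  expect_error(estimateDisplacement(z, z), "degenerate")
})

test_that("applyShift is exact for identity and integer round trips", {
  set.seed(8)
  x <- matrix(rnorm(40 * 40), 40, 40)
  expect_identical(applyShift(x, 0, 0), x)
  y <- applyShift(applyShift(x, 3, -2), -3, 2)
  expect_equal(y[6:35, 6:35], x[6:35, 6:35])
  # half-pixel shift of a ramp: interior values are neighbor midpoints
  ramp <- matrix(rep(1:20, each = 20), 20, 20)  # increases along columns
  half <- applyShift(ramp, 0.5, 0)
  expect_equal(half[10, 5:15], (ramp[10, 5:15] + ramp[10, 4:14]) / 2)
})

test_that("template updates follow the capped running mean", {
  A <- matrix(1, 4, 4); B <- matrix(3, 4, 4)
  p <- registrationParams(templateWindow = 2)
  expect_identical(updateTemplate(NULL, A, 0, p), A)
  expect_identical(updateTemplate(A, A, 5, p), A)
  expect_equal(updateTemplate(A, B, 1, p), (A + B) / 2)
  # beyond the window the weight is capped at 1/window
  expect_equal(updateTemplate(A, B, 10, p), A + (B - A) / 2)
})

test_that("known sinusoidal motion is recovered with low error", {
  p <- simParams(frameHeight = 128, frameWidth = 128, nFrames = 80,
                 nCells = 8, readNoiseSigma = 0, respAmplitude = 2,
                 respFreq = 2.5, jumpRate = 0, illumAmplitude = 0.2,
                 bleachEndFraction = 1, backgroundRate = 0.5,
                 fracPositive = 0, fracNegative = 0, seed = 21)
  gt <- makeGroundTruth(p)
  m <- renderMovie(gt, p)
  res <- correctSequence(m, registrationParams(maxShift = 10))
  # shifts are estimated relative to the template anchored on frame 1
  rel <- sweep(gt@motionTrace, 2, gt@motionTrace[1, ])
  err <- cbind(res$displacement$dx - rel[, 1],
               res$displacement$dy - rel[, 2])
  rmse <- sqrt(mean(err^2))
  expect_lte(rmse, 0.25)
})

test_that("a motion-free movie reports essentially zero displacement", {
  p <- tinySim(readNoiseSigma = 0, backgroundRate = 0.3)
  gt <- makeGroundTruth(p)
  m <- renderMovie(gt, p)
  res <- correctSequence(m)
  expect_lte(mean(res$displacement$magnitudeUm), 0.1)
})

test_that("a biphasic jump is corrected to sub-pixel residual", {
  p <- simParams(frameHeight = 128, frameWidth = 128, nFrames = 60,
                 nCells = 8, readNoiseSigma = 0, respAmplitude = 0,
                 jumpRate = 0, illumAmplitude = 0, bleachEndFraction = 1,
                 backgroundRate = 0.5, fracPositive = 0, fracNegative = 0,
                 seed = 22)
  gt <- makeGroundTruth(p)
  # plant a 5-px biphasic jump over frames 30-31
  gt@motionTrace[30, ] <- c(5, -5)
  gt@motionTrace[31, ] <- -0.4 * gt@motionTrace[30, ]
  m <- renderMovie(gt, p)
  res <- correctSequence(m, registrationParams(maxShift = 10))
  # re-estimate each jump frame against the corrected-movie template
  template <- homomorphicEnhance(apply(res$video@frames, c(1, 2), mean), 32)
  for (f in c(30, 31)) {
    e <- homomorphicEnhance(getFrame(res$video, f), 32)
    s <- estimateDisplacement(e, template, registrationParams(maxShift = 10))
    expect_lte(sqrt(s[["dx"]]^2 + s[["dy"]]^2), 0.5)
  }
})

test_that("correction is idempotent up to the first pass's residual", {
  p <- simParams(frameHeight = 96, frameWidth = 96, nFrames = 50, nCells = 5,
                 readNoiseSigma = 0, respAmplitude = 1.5, jumpRate = 0,
                 illumAmplitude = 0, bleachEndFraction = 1,
                 backgroundRate = 0.5, fracPositive = 0, fracNegative = 0,
                 seed = 23)
  gt <- makeGroundTruth(p)
  m <- renderMovie(gt, p)
  pass1 <- correctSequence(m, registrationParams(maxShift = 10))
  pass2 <- correctSequence(pass1$video, registrationParams(maxShift = 10))
  expect_lte(mean(pass2$displacement$magnitudeUm),
             mean(pass1$displacement$magnitudeUm) + 1e-9)
})

test_that("enhancement does not shift an unshifted pair", {
  x <- smoothPeriodicImage(96, seed = 31) + 50
  s <- estimateDisplacement(homomorphicEnhance(x, 24), x)
  expect_lte(sqrt(s[["dx"]]^2 + s[["dy"]]^2), 0.1)
})

test_that("two-pass fixed template mode also recovers motion", {
  p <- simParams(frameHeight = 96, frameWidth = 96, nFrames = 40, nCells = 5,
                 readNoiseSigma = 0, respAmplitude = 1.5, jumpRate = 0,
                 illumAmplitude = 0, bleachEndFraction = 1,
                 backgroundRate = 0.5, fracPositive = 0, fracNegative = 0,
                 seed = 24)
  gt <- makeGroundTruth(p)
  m <- renderMovie(gt, p)
  res <- correctSequence(m, registrationParams(maxShift = 10,
    templateMode = "two_pass_fixed", fixedSampleFrames = 10), seed = 4)
  rel <- sweep(gt@motionTrace, 2, gt@motionTrace[1, ])
  err <- cbind(res$displacement$dx - rel[, 1],
               res$displacement$dy - rel[, 2])
  expect_lte(sqrt(mean(err^2)), 0.35)
})

test_that("streamed file input gives bit-identical correction", {
  p <- tinySim(backgroundRate = 0.4, respAmplitude = 1, nFrames = 50,
               seed = 25)
  gt <- makeGroundTruth(p)
  m <- renderMovie(gt, p)
  parts <- renderMovieFiles(gt, p, withr::local_tempdir(),
                            framesPerFile = 12L)
  expect_equal(length(parts), 5)       # 12*4 + 2
  rp <- registrationParams(maxShift = 8)
  inMem <- correctSequence(m, rp)
  streamed <- correctSequence(parts, rp, frameRate = p@frameRate,
                              pixelPitch = p@pixelPitch, chunkFrames = 7L)
  expect_identical(streamed$video@frames, inMem$video@frames)
  expect_equal(streamed$displacement, inMem$displacement)
})
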