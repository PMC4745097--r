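# Trial alignment, paired-t modulation classification, latency, summaries.

alignedFromAucs <- function(baseAuc, taskAuc, rate = 20) {
  # rows constant within each 2-s window so the window AUC is value * 2
  times <- seq(-2, 2 - 1 / rate, by = 1 / rate)
  m <- t(vapply(seq_along(baseAuc), function(i)
    ifelse(times < 0, baseAuc[i] / 2, taskAuc[i] / 2), numeric(length(times))))
  attr(m, "times") <- times
  attr(m, "trials") <- seq_along(baseAuc)
  m
}

test_that("trial alignment matches direct index arithmetic", {
  rate <- 20
  trace <- rnorm(400)
  sch <- data.frame(toneOnset = c(3, 9, 15), outcome = "correct")
  al <- alignTrials(trace, sch, window = c(-2, 3), frameRate = rate)
  expect_equal(dim(al), c(3, 100))
  for (i in 1:3) {
    iOn <- sch$toneOnset[i] * rate + 1
    expect_equal(al[i, ], trace[(iOn - 40):(iOn + 59)])
  }
  expect_equal(attr(al, "times")[41], 0)

  # constant trace aligns to a constant matrix
  alc <- alignTrials(rep(2.5, 400), sch, c(-2, 3), rate)
  expect_true(all(alc == 2.5))

  # a delta planted 1 s after each tone lands in the +1 s column of every row
  delta <- rep(0, 400)
  delta[sch$toneOnset * rate + rate + 1] <- 7
  ald <- alignTrials(delta, sch, c(-2, 3), rate)
  expect_true(all(ald[, attr(ald, "times") == 1] == 7))
  expect_equal(sum(ald != 0), 3)

  # truncated trials are excluded with a warning
  expect_warning(
    alShort <- alignTrials(trace[1:130], sch, c(-2, 3), rate), "excluded")
  expect_equal(nrow(alShort), 1)
  expect_equal(attr(alShort, "trials"), 1L)
})

test_that("window AUC follows the rectangle rule", {
  rate <- 20
  row <- rep(1, 80)
  attr(row, "times") <- seq(-2, 2 - 1 / rate, by = 1 / rate)
  expect_equal(windowAuc(row, c(0, 2), rate), 2.0)
  expect_equal(windowAuc(0 * row, c(0, 2), rate,
                         times = attr(row, "times")), 0)
  # against the trapezoid rule on a smooth signal
  tt <- attr(row, "times")
  smooth <- sin(tt) + 2
  rect <- windowAuc(smooth, c(-2, 2), rate, times = tt)
  trap <- sum((smooth[-1] + smooth[-length(smooth)]) / 2) / rate
  expect_lt(abs(rect - trap), max(abs(smooth)) / rate)
})

test_that("the paired t classification matches the closed form", {
  al <- alignedFromAucs(c(1, 2, 3), c(3, 5, 4))
  res <- classifyModulation(al, 1:3)
  # diffs (2, 3, 1): mean 2, sd 1, t = 2 sqrt(3)
  expect_equal(res$tStat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$pValue, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(res$label, "none")          # p ~ 0.074 at alpha 0.05
  expect_equal(res$baselineAuc, c(1, 2, 3))
  expect_equal(res$taskAuc, c(3, 5, 4))

  # task == baseline per trial: no modulation
  same <- alignedFromAucs(c(1, 2, 3), c(1, 2, 3))
  expect_equal(classifyModulation(same, 1:3)$label, "none")

  # constant nonzero difference: exact, significant
  ex <- classifyModulation(alignedFromAucs(c(1, 1, 1), c(2, 2, 2)), 1:3)
  expect_true(ex$exactDifference)
  expect_equal(ex$label, "positive")
  ex2 <- classifyModulation(alignedFromAucs(c(2, 2, 2), c(1, 1, 1)), 1:3)
  expect_equal(ex2$label, "negative")

  expect_error(classifyModulation(al, 1), "2 correct trials")
})

test_that("paired t p-values match the reference implementation to 1e-10", {
  set.seed(46)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    b <- rnorm(n); tk <- rnorm(n, sd = runif(1, 0.5, 2))
    res <- classifyModulation(alignedFromAucs(b, tk), seq_len(n))
    ref <- t.test(tk * 2, b * 2, paired = TRUE)
    # windows span 2 s, so AUCs are 2x the constructed values; the paired
    # t statistic is scale-invariant
    expect_lt(abs(res$pValue - ref$p.value), 1e-10)
    expect_equal(res$tStat, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("labels are invariant to positive rescaling of the trace", {
  set.seed(47)
  for (i in 1:10) {
    b <- rnorm(12, 10); tk <- rnorm(12, 10 + rnorm(1))
    al <- alignedFromAucs(b, tk)
    al2 <- al * 37.5
    attributes(al2) <- attributes(al)
    expect_equal(classifyModulation(al2, 1:12)$label,
                 classifyModulation(al, 1:12)$label)
  }
})

test_that("latency to peak picks the first maximum in the window", {
  rate <- 20
  times <- seq(-2, 8 - 1 / rate, by = 1 / rate)
  mk <- function(f) {
    m <- rbind(f(times), f(times))
    attr(m, "times") <- times
    m
  }
  one <- mk(function(tt) ifelse(abs(tt - 1.2) < 1e-9, 5, 0))
  r1 <- latencyToPeak(one, 1:2)
  expect_equal(r1$latency, 1.2)
  expect_equal(r1$peakValue, 5)

  # equal maxima at +0.5 and +3.0: first occurrence wins
  two <- mk(function(tt) ifelse(abs(tt - 0.5) < 1e-9 |
                                abs(tt - 3.0) < 1e-9, 4, 0))
  expect_equal(latencyToPeak(two, 1:2)$latency, 0.5)

  # a planted kernel peaks where the kernel does
  kern <- mk(function(tt) transientKernel(tt - 0.1, 0.045, 0.4))
  lat <- latencyToPeak(kern, 1:2)$latency
  expect_gte(lat, 0.1)
  expect_lte(lat, 0.6)
  expect_equal(lat, times[which.max(kern[1, ])])
})

test_that("population summaries use half-away-from-zero percent rounding", {
  labs <- c(rep("positive", 81), rep("negative", 102), rep("none", 239))
  s <- summarizePopulation(labs)
  expect_equal(s$count, c(81L, 102L, 239L))
  expect_equal(s$percent[s$label == "positive"], 19.19)
  expect_equal(s$percent[s$label == "negative"], 24.17)

  labs2 <- c(rep("positive", 216), rep("negative", 374), rep("none", 496))
  s2 <- summarizePopulation(labs2)
  expect_equal(s2$percent[s2$label == "positive"], 19.89)
  expect_equal(s2$percent[s2$label == "negative"], 34.44)

  s3 <- summarizePopulation(rep("none", 5))
  expect_equal(s3$percent, c(0, 0, 100))
})

test_that("planted positive and negative cells are recovered from traces", {
  p <- simParams(frameHeight = 256, frameWidth = 256, nFrames = 27500,
                 nCells = 40, seed = 51)
  gt <- makeGroundTruth(p)
  tr <- normalizeTraces(renderCellTraces(gt, p))
  mod <- analyzeTaskModulation(tr, gt@schedule)
  modulated <- gt@modulationLabel != "none"
  expect_gte(mean(mod$label[modulated] == gt@modulationLabel[modulated]),
             0.9)
})
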