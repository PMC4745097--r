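# Median-distance resampling test, adjacency counts, rank-sum test.

test_that("median pairwise distance matches hand values and brute force", {
  expect_equal(pairwiseMedianDistance(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(pairwiseMedianDistance(rbind(c(0, 0), c(1, 0), c(2, 0))), 1)
  expect_error(pairwiseMedianDistance(rbind(c(0, 0))), "2 points")

  set.seed(52)
  pts <- matrix(runif(200, 0, 1000), 100, 2)
  dd <- numeric(0)
  for (i in 1:99) for (j in (i + 1):100)
    dd <- c(dd, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  expect_equal(pairwiseMedianDistance(pts), median(dd))
})

test_that("spatial statistics are rigid-motion invariant", {
  set.seed(53)
  pts <- matrix(rnorm(60, 0, 200), 30, 2)
  th <- 0.7
  rot <- pts %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(rot, 2, c(123, -456), `+`)
  expect_equal(pairwiseMedianDistance(moved), pairwiseMedianDistance(pts))
  labs <- rep(c("positive", "negative", "none"), 10)
  a1 <- adjacencyCounts(pts, labs)
  a2 <- adjacencyCounts(moved, labs)
  expect_equal(a1$mean, a2$mean)
  expect_equal(a1$sd, a2$sd)
})

test_that("the resampling test is seeded, calibrated, and flags sparse subsets", {
  set.seed(54)
  pts <- matrix(rnorm(400, 0, 100), 200, 2)
  sp <- spatialParams(seed = 99)
  r1 <- resamplingTest(pts, 1:20, sp)
  r2 <- resamplingTest(pts, 1:20, sp)
  expect_identical(r1$nullMedians, r2$nullMedians)
  expect_equal(length(r1$nullMedians), 500)

  # a subset planted on a coarse grid inside a dense cloud is sparser than
  # chance: upper-tail p small
  grid <- as.matrix(expand.grid(seq(-800, 800, length.out = 5),
                                seq(-800, 800, length.out = 4)))
  all <- rbind(grid, matrix(rnorm(360, 0, 100), 180, 2))
  rs <- resamplingTest(all, 1:20, spatialParams(seed = 7))
  expect_lte(rs$pValue, 0.05)
  expect_gt(rs$observedMedianUm, rs$nullMeanUm)

  # degenerate: subset == population can never look significantly sparse
  # (every resample reproduces the observed statistic exactly)
  expect_warning(rw <- resamplingTest(pts[1:30, ], 1:30,
                                      spatialParams(seed = 3)),
                 "uninformative")
  expect_equal(rw$pValue, 1)

  # under random labels the p-value is approximately uniform
  ps <- vapply(1:200, function(i) {
    sub <- sample.int(200, 25)
    resamplingTest(pts, sub, spatialParams(nResamples = 100,
                                           seed = 1000 + i))$pValue
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("adjacency counts match the definition and brute force", {
  # three mutually close positive cells: 2 positive neighbors each
  tri <- rbind(c(0, 0), c(8, 0), c(4, 6))
  a <- adjacencyCounts(tri, rep("positive", 3), spatialParams(radiusUm = 50))
  expect_equal(a$mean["positive", "positive"], 2)
  expect_equal(a$sd["positive", "positive"], 0)

  # everything farther than the radius: all zeros
  far <- 60 * rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2))
  af <- adjacencyCounts(far, c("positive", "negative", "none", "none"))
  expect_true(all(af$mean[!is.na(af$mean)] == 0))

  # random layout against an O(n^2) reference
  set.seed(55)
  pts <- matrix(runif(120, 0, 300), 60, 2)
  labs <- sample(c("positive", "negative", "none"), 60, TRUE)
  a2 <- adjacencyCounts(pts, labs)
  for (i in sample(60, 10)) {
    for (l in c("positive", "negative", "none")) {
      cnt <- 0
      for (j in seq_len(60)) {
        if (j == i || labs[j] != l) next
        if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= 50) cnt <- cnt + 1
      }
      expect_equal(unname(a2$perRoi[i, l]), cnt)
    }
  }
  # symmetry: cross-label adjacency sums agree in both directions
  for (la in c("positive", "negative")) for (lb in c("negative", "none")) {
    if (la == lb) next
    expect_equal(sum(a2$perRoi[labs == la, lb]),
                 sum(a2$perRoi[labs == lb, la]))
  }
})

test_that("the rank-sum z and p follow the tie-corrected normal form", {
  same <- rankSumTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z, 0)
  expect_equal(same$pValue, 1)

  flat <- rankSumTest(rep(4, 5), rep(4, 7))
  expect_equal(flat$pValue, 1)

  # complete separation at n = 10 per group: closed-form U and z
  a <- 11:20; b <- 1:10
  r <- rankSumTest(a, b)
  expect_equal(r$U, 100)
  expect_equal(r$W, sum(11:20))
  expect_equal(r$z, (155 - 105) / sqrt(10 * 10 * 21 / 12))
  expect_equal(r$pValue, 2 * pnorm(-r$z))

  # the implementation agrees exactly with an independent reference
  # implementation of the tie-corrected normal approximation
  set.seed(56)
  for (i in 1:20) {
    x <- sample(1:4, sample(5:12, 1), TRUE)
    y <- sample(1:5, sample(5:12, 1), TRUE)
    if (length(unique(c(x, y))) < 2) next
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = FALSE))
    expect_equal(rankSumTest(x, y)$pValue, ref$p.value, tolerance = 1e-12)
  }

  # ties-heavy inputs against the exhaustive permutation oracle; at n = 8
  # per group the exact null is discrete, so the normal approximation is
  # held to the local atom size plus a small continuous margin
  for (i in 1:5) {
    x <- sample(1:3, 8, TRUE)
    y <- sample(1:4, 8, TRUE) + 1
    approx <- rankSumTest(x, y)$pValue
    exact <- permRankSumP(x, y)
    expect_lt(abs(approx - as.numeric(exact)), attr(exact, "atom") + 0.05)
  }

  # the z-to-p mapping is the plain two-sided normal tail
  expect_equal(round(2 * pnorm(-2.97), 3), 0.003)
})
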