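# Single-frame to multi-frame ROI clustering and overlap filtering.

test_that("the similarity rule is the conjunction of centroid and corner tests", {
  p <- mergeParams()
  a <- list(centroidR = 50, centroidC = 50, r0 = 45, r1 = 56, c0 = 45,
            c1 = 56)
  expect_true(roiSimilar(a, a, p))
  # 100 um apart (about 76 px at 1.312 um/px): clearly different cells
  b <- a; b$centroidR <- a$centroidR + 76; b$r0 <- a$r0 + 76; b$r1 <- a$r1 + 76
  expect_false(roiSimilar(a, b, p))
  # close centroids but one bbox corner 20 px off
  d <- a; d$centroidR <- a$centroidR + 5; d$r1 <- a$r1 + 20
  expect_false(roiSimilar(a, d, p))
})

test_that("one flashing cell becomes a single multi-frame ROI", {
  sf <- sfroiCell(100, 200, n = 10, H = 512)
  attr(sf, "dim.frame") <- c(512L, 512L)
  rs <- clusterRois(sf)
  expect_equal(length(rs), 1)
  expect_equal(rs@nAppearances, 10L)
  expect_equal(rs@centroids[1, ], c(100 + 4.5, 200 + 4.5))
  expect_equal(rs@frameIndices[[1]], 1:10)

  # two cells 100 um apart stay separate
  sf2 <- rbind(sf, sfroiCell(100, 276, n = 8, H = 512))
  rs2 <- clusterRois(sf2, dim = c(512, 512))
  expect_equal(length(rs2), 2)
  expect_equal(sort(rs2@nAppearances), c(8L, 10L))
})

test_that("short-lived clusters are dropped and masks follow the frequency rule", {
  sf <- rbind(sfroiCell(100, 100, n = 3, H = 512),
              sfroiCell(300, 300, n = 6, H = 512))
  rs <- clusterRois(sf, dim = c(512, 512), mergeParams(minFrames = 5))
  expect_equal(length(rs), 1)
  # stable square seen in all frames: mask is the full square
  expect_equal(length(rs@masks[[1]]), 100)
})

test_that("blocked clustering equals the unblocked single-linkage oracle", {
  # many cells scattered across block boundaries, jittered detections
  set.seed(33)
  centers <- cbind(sample(20:490, 60), sample(20:490, 60))
  sf <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sfroiCell(centers[k, 1], centers[k, 2], n = sample(3:9, 1), H = 512,
              jitter = 2, seed = k)))
  expect_lte(nrow(sf), 500)
  p <- mergeParams(minFrames = 1)
  rs <- clusterRois(sf, dim = c(512, 512), p)
  ref <- refCluster(sf, p)
  # compare partitions via sorted centroid signatures
  sig <- function(cenMat) sort(apply(round(cenMat, 6), 1, paste,
                                     collapse = ","))
  refCen <- t(vapply(ref, function(m)
    c(mean(sf$centroidR[order(sf$frame)][m]),
      mean(sf$centroidC[order(sf$frame)][m])), numeric(2)))
  expect_equal(length(rs), length(ref))
  expect_identical(sig(rs@centroids), sig(refCen))
})

test_that("a cell in a block overlap is not duplicated", {
  # default blocks are 128 px with 32 px overlap: centroid at 100 lands in
  # two blocks along each axis
  sf <- sfroiCell(96, 96, n = 6, H = 512)
  rs <- clusterRois(sf, dim = c(512, 512))
  expect_equal(length(rs), 1)
  expect_equal(rs@nAppearances, 6L)
})

test_that("the overlap filter drops the weaker member of redundant pairs", {
  mk <- function(px, napp) list(mask = sort(px), napp = napp)
  # build a RoiSet by hand: A and B overlap (IoU 0.5+), C disjoint
  masks <- list(1:30, 11:40, 101:130)
  roiset <- new("RoiSet", masks = masks,
                centroids = rbind(c(1, 1), c(1, 2), c(5, 5)),
                bboxes = rbind(c(1, 31, 1, 2), c(11, 41, 1, 2),
                               c(1, 31, 2, 3)),
                frameIndices = list(1:30, 1:5, 1:7),
                nAppearances = c(30L, 5L, 7L), dim = c(64L, 64L),
                pixelPitch = 1.312)
  out <- filterSeparated(roiset, mergeParams(maxIou = 0.3))
  expect_equal(length(out), 2)
  expect_equal(out@nAppearances, c(30L, 7L))     # the 5-appearance ROI lost

  # disjoint sets pass through untouched
  dis <- roiset[c(1, 3)]
  expect_equal(length(filterSeparated(dis)), 2)
})

test_that("chained overlaps match the brute-force greedy oracle", {
  set.seed(34)
  for (rep in 1:5) {
    n <- 8
    masks <- lapply(seq_len(n), function(i) {
      st <- sample(1:60, 1)
      sort(st:(st + sample(20:40, 1)))
    })
    napp <- sample(3:30, n, replace = TRUE)
    rois <- new("RoiSet", masks = masks,
                centroids = cbind(rep(1, n), seq_len(n)),
                bboxes = t(vapply(masks, function(m)
                  c(min(m), max(m) + 1, 1, 2), numeric(4))),
                frameIndices = lapply(napp, seq_len),
                nAppearances = as.integer(napp),
                dim = c(128L, 128L), pixelPitch = 1.312)
    out <- filterSeparated(rois, mergeParams(maxIou = 0.3))
    ref <- refFilterSeparated(masks, napp, 0.3)
    expect_identical(out@masks, masks[ref])
    # no surviving pair exceeds the cap
    if (length(out) > 1) {
      for (i in 1:(length(out) - 1)) for (j in (i + 1):length(out)) {
        ii <- length(intersect(out@masks[[i]], out@masks[[j]]))
        expect_lte(ii / (length(out@masks[[i]]) + length(out@masks[[j]]) - ii),
                   0.3)
      }
    }
  }
})

test_that("a stricter overlap cap never increases the survivor count", {
  set.seed(35)
  n <- 10
  masks <- lapply(seq_len(n), function(i) {
    st <- sample(1:80, 1)
    sort(st:(st + sample(15:35, 1)))
  })
  rois <- new("RoiSet", masks = masks,
              centroids = cbind(rep(1, n), seq_len(n)),
              bboxes = t(vapply(masks, function(m)
                c(min(m), max(m) + 1, 1, 2), numeric(4))),
              frameIndices = lapply(seq_len(n), function(i) 1:(i + 2)),
              nAppearances = as.integer(3:12), dim = c(128L, 128L),
              pixelPitch = 1.312)
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.8), function(mi)
    length(filterSeparated(rois, mergeParams(maxIou = mi))), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ROI sets round trip through JSON and the label image", {
  sf <- rbind(sfroiCell(40, 40, n = 6, H = 128),
              sfroiCell(80, 90, n = 7, H = 128))
  rs <- clusterRois(sf, dim = c(128, 128))
  f <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tif")
  writeRois(rs, f, labelTiff = ft)
  back <- readRois(f)
  expect_equal(back@centroids, rs@centroids)
  expect_identical(back@masks, rs@masks)
  expect_identical(back@nAppearances, rs@nAppearances)
  lab <- tiff::readTIFF(ft, as.is = TRUE)
  expect_equal(sort(unique(as.vector(lab))), 0:2)
})
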