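# Cluster single-frame ROIs into per-neuron multi-frame ROIs.

#' Merge parameters
#'
#' @param centroidTol maximum centroid distance (px) for two detections to
#'   be considered the same cell.
#' @param bboxTol maximum Euclidean distance (px) between corresponding
#'   bounding-box corners (upper-left and lower-right).
#' @param blockSize,blockOverlap pre-grouping blocks (px): detections are
#'   clustered inside overlapping tiles, then a redundancy pass merges
#'   clusters across tiles.
#' @param minFrames minimum number of contributing frames for a cluster to
#'   survive.
#' @param maskFreqThreshold fraction of contributing frames a pixel must
#'   appear in to enter the final mask.
#' @param maxIou overlap cap for \code{\link{filterSeparated}}.
#' @param sizeBucketing if TRUE, only detections whose areas fall in the
#'   same or adjacent powers-of-two bucket are compared (a speed heuristic;
#'   off by default because it can split clusters whose member areas
#'   straddle a bucket edge).
#' @return A validated parameter list of class \code{MergeParams}.
#' @export
mergeParams <- function(centroidTol = 8, bboxTol = 12, blockSize = 128,
                        blockOverlap = 32, minFrames = 5,
                        maskFreqThreshold = 0.25, maxIou = 0.3,
                        sizeBucketing = FALSE) {
  stopIfNot(centroidTol <= bboxTol, "'centroidTol' must be <= 'bboxTol'")
  stopIfNot(blockOverlap < blockSize, "'blockOverlap' must be < 'blockSize'")
  stopIfNot(maskFreqThreshold > 0 && maskFreqThreshold <= 1,
            "'maskFreqThreshold' must be in (0, 1]")
  stopIfNot(maxIou > 0 && maxIou < 1, "'maxIou' must be in (0, 1)")
  structure(list(centroidTol = centroidTol, bboxTol = bboxTol,
                 blockSize = blockSize, blockOverlap = blockOverlap,
                 minFrames = as.integer(minFrames),
                 maskFreqThreshold = maskFreqThreshold, maxIou = maxIou,
                 sizeBucketing = isTRUE(sizeBucketing)),
            class = "MergeParams")
}

#' Are two ROIs the same cell?
#'
#' TRUE iff the centroid distance is at most \code{centroidTol} and both the
#' upper-left and lower-right bounding-box corners are within \code{bboxTol}
#' (Euclidean) of each other.
#'
#' @param a,b ROIs given as lists/rows with fields \code{centroidR},
#'   \code{centroidC}, \code{r0}, \code{r1}, \code{c0}, \code{c1}.
#' @param params a \code{\link{mergeParams}} list.
#' @return logical.
#' @export
roiSimilar <- function(a, b, params = mergeParams()) {
  dc <- sqrt((a$centroidR - b$centroidR)^2 + (a$centroidC - b$centroidC)^2)
  if (dc > params$centroidTol) return(FALSE)
  dUL <- sqrt((a$r0 - b$r0)^2 + (a$c0 - b$c0)^2)
  dLR <- sqrt((a$r1 - b$r1)^2 + (a$c1 - b$c1)^2)
  dUL <= params$bboxTol && dLR <= params$bboxTol
}

# incremental single-linkage pass over single-frame ROIs (already in frame
# order): each detection joins the closest existing cluster it is similar
# to, else seeds a new one. Clusters track running means of centroid and
# bbox corners. Returns cluster membership (list of sfroi row indices).
incrementalCluster <- function(sf, rowsIdx, params) {
  n <- length(rowsIdx)
  if (n == 0L) return(list())
  cen <- matrix(0, 0, 2)
  box <- matrix(0, 0, 4)
  cnt <- integer(0)
  members <- list()
  areas <- sf$area[rowsIdx]
  buckets <- floor(log2(pmax(areas, 1)))
  cBucket <- numeric(0)
  for (j in seq_len(n)) {
    i <- rowsIdx[j]
    cand <- seq_along(cnt)
    if (params$sizeBucketing && length(cand))
      cand <- cand[abs(cBucket[cand] - buckets[j]) <= 1]
    joined <- FALSE
    if (length(cand)) {
      dc2 <- (cen[cand, 1] - sf$centroidR[i])^2 +
             (cen[cand, 2] - sf$centroidC[i])^2
      ok <- dc2 <= params$centroidTol^2
      if (any(ok)) {
        cnd <- cand[ok]
        dUL <- (box[cnd, 1] - sf$r0[i])^2 + (box[cnd, 3] - sf$c0[i])^2
        dLR <- (box[cnd, 2] - sf$r1[i])^2 + (box[cnd, 4] - sf$c1[i])^2
        ok2 <- dUL <= params$bboxTol^2 & dLR <= params$bboxTol^2
        if (any(ok2)) {
          cnd <- cnd[ok2]
          k <- cnd[which.min(dc2[ok][ok2])]
          # running means
          w <- cnt[k]
          cen[k, ] <- (cen[k, ] * w +
                       c(sf$centroidR[i], sf$centroidC[i])) / (w + 1)
          box[k, ] <- (box[k, ] * w +
                       c(sf$r0[i], sf$r1[i], sf$c0[i], sf$c1[i])) / (w + 1)
          cBucket[k] <- floor(log2(max(mean(c(areas[j],
            sf$area[rowsIdx[members[[k]]]])), 1)))
          cnt[k] <- w + 1L
          members[[k]] <- c(members[[k]], j)
          joined <- TRUE
        }
      }
    }
    if (!joined) {
      cen <- rbind(cen, c(sf$centroidR[i], sf$centroidC[i]))
      box <- rbind(box, c(sf$r0[i], sf$r1[i], sf$c0[i], sf$c1[i]))
      cnt <- c(cnt, 1L)
      cBucket <- c(cBucket, buckets[j])
      members <- c(members, list(j))
    }
  }
  lapply(members, function(m) rowsIdx[m])
}

#' Cluster single-frame ROIs into multi-frame ROIs
#'
#' Detections are pre-grouped into overlapping spatial blocks by centroid;
#' inside each block an incremental single-linkage pass (frame order, ties
#' to the nearest cluster) assigns each detection to a cluster. A second
#' pass merges clusters across blocks that satisfy \code{\link{roiSimilar}}
#' on their aggregate centroid/bbox, removing the redundancy introduced by
#' the overlaps. The final mask keeps pixels present in at least
#' \code{maskFreqThreshold} of the contributing frames; clusters seen in
#' fewer than \code{minFrames} frames are dropped. ROIs are ordered by
#' centroid (row, then column).
#'
#' @param sfrois single-frame ROI data.frame from \code{\link{detectRois}}.
#' @param dim frame dimensions \code{c(H, W)}; defaults to the
#'   \code{dim.frame} attribute of \code{sfrois}.
#' @param params a \code{\link{mergeParams}} list.
#' @param pixelPitch micrometres per pixel, stored in the result.
#' @return A \linkS4class{RoiSet}.
#' @export
clusterRois <- function(sfrois, dim = attr(sfrois, "dim.frame"),
                        params = mergeParams(), pixelPitch = 1.312) {
  stopIfNot(!is.null(dim) && length(dim) == 2L,
            "frame dimensions required ('dim' or attr(sfrois, 'dim.frame'))")
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  empty <- new("RoiSet", masks = list(), centroids = matrix(0, 0, 2),
               bboxes = matrix(0, 0, 4), frameIndices = list(),
               nAppearances = integer(0), dim = c(H, W),
               pixelPitch = pixelPitch)
  if (is.null(sfrois) || nrow(sfrois) == 0L) return(empty)
  sf <- sfrois[order(sfrois$frame), , drop = FALSE]

  # block decomposition: origins every blockSize - blockOverlap
  step <- params$blockSize - params$blockOverlap
  orR <- seq(1, max(H - params$blockOverlap, 1), by = step)
  orC <- seq(1, max(W - params$blockOverlap, 1), by = step)
  clusters <- list()
  for (br in orR) for (bc in orC) {
    inBlock <- which(sf$centroidR >= br &
                     sf$centroidR < br + params$blockSize &
                     sf$centroidC >= bc &
                     sf$centroidC < bc + params$blockSize)
    if (length(inBlock))
      clusters <- c(clusters, incrementalCluster(sf, inBlock, params))
  }
  if (!length(clusters)) return(empty)

  # aggregate cluster summaries
  agg <- function(mem) {
    c(centroidR = mean(sf$centroidR[mem]), centroidC = mean(sf$centroidC[mem]),
      r0 = mean(sf$r0[mem]), r1 = mean(sf$r1[mem]),
      c0 = mean(sf$c0[mem]), c1 = mean(sf$c1[mem]))
  }
  A <- t(vapply(clusters, agg, numeric(6)))

  # redundancy pass: union-find over similar cluster pairs
  K <- length(clusters)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      dc2 <- (A[i, 1] - A[j, 1])^2 + (A[i, 2] - A[j, 2])^2
      if (dc2 > params$centroidTol^2) next
      dUL <- (A[i, 3] - A[j, 3])^2 + (A[i, 5] - A[j, 5])^2
      dLR <- (A[i, 4] - A[j, 4])^2 + (A[i, 6] - A[j, 6])^2
      if (dUL <= params$bboxTol^2 && dLR <= params$bboxTol^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(K), find, 1L)
  merged <- lapply(split(seq_len(K), roots), function(ks)
    sort(unique(unlist(clusters[ks]))))

  # finalize: frequency-thresholded mask, centroid = mean of member
  # single-frame centroids, drop short-lived clusters
  build <- function(mem) {
    frames <- sort(unique(sf$frame[mem]))
    nApp <- length(frames)
    if (nApp < params$minFrames) return(NULL)
    # count distinct frames in which each pixel appears
    pf <- unique(data.frame(
      px = unlist(sf$pixels[mem]),
      fr = rep(sf$frame[mem], lengths(sf$pixels[mem]))))
    cnt <- table(pf$px)
    mask <- sort(as.integer(names(cnt)[cnt >= params$maskFreqThreshold * nApp]))
    if (!length(mask)) return(NULL)
    rows <- (mask - 1L) %% H + 1L
    cols <- (mask - 1L) %/% H + 1L
    list(mask = mask,
         centroid = c(mean(sf$centroidR[mem]), mean(sf$centroidC[mem])),
         bbox = c(min(rows), max(rows) + 1L, min(cols), max(cols) + 1L),
         frames = frames, nApp = nApp)
  }
  built <- Filter(Negate(is.null), lapply(merged, build))
  if (!length(built)) return(empty)
  built <- unname(built)
  cen <- t(vapply(built, `[[`, numeric(2), "centroid"))
  ord <- order(cen[, 1], cen[, 2])
  built <- built[ord]
  new("RoiSet",
      masks = lapply(built, `[[`, "mask"),
      centroids = unname(cen[ord, , drop = FALSE]),
      bboxes = unname(t(vapply(built, `[[`, numeric(4), "bbox"))),
      frameIndices = lapply(built, function(b) as.integer(b$frames)),
      nAppearances = unname(vapply(built, function(b) as.integer(b$nApp),
                                   1L)),
      dim = c(H, W), pixelPitch = pixelPitch)
}

maskIou <- function(a, b) {
  i <- length(intersect(a, b))
  if (i == 0L) return(0)
  i / (length(a) + length(b) - i)
}

#' Drop spatially redundant ROIs
#'
#' Greedy overlap filter: while any pair of ROIs has mask IoU above
#' \code{maxIou}, the pair with the largest IoU is resolved by dropping the
#' member with fewer appearances (ties: smaller area, then larger index).
#' No surviving pair exceeds \code{maxIou}. This is the algorithmic
#' surrogate for manual curation of overlapping cells.
#'
#' @param rois a \linkS4class{RoiSet}.
#' @param params a \code{\link{mergeParams}} list.
#' @return the filtered \linkS4class{RoiSet}.
#' @export
filterSeparated <- function(rois, params = mergeParams()) {
  n <- length(rois)
  if (n < 2L) return(rois)
  # candidate pairs: bounding boxes must intersect
  bb <- rois@bboxes
  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bb[i, 1] < bb[j, 2] && bb[j, 1] < bb[i, 2] &&
        bb[i, 3] < bb[j, 4] && bb[j, 3] < bb[i, 4])
      pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (!length(pairs)) return(rois)
  P <- do.call(rbind, pairs)
  iou <- vapply(seq_len(nrow(P)), function(k)
    maskIou(rois@masks[[P[k, 1]]], rois@masks[[P[k, 2]]]), numeric(1))
  alive <- rep(TRUE, n)
  repeat {
    act <- which(alive[P[, 1]] & alive[P[, 2]] & iou > params$maxIou)
    if (!length(act)) break
    k <- act[which.max(iou[act])]
    i <- P[k, 1]; j <- P[k, 2]
    loser <- pickLoser(rois, i, j)
    alive[loser] <- FALSE
  }
  rois[which(alive)]
}

# which member of an over-overlapping pair is dropped: fewer appearances;
# ties by smaller area, then larger index
pickLoser <- function(rois, i, j) {
  ai <- rois@nAppearances[i]; aj <- rois@nAppearances[j]
  if (ai != aj) return(if (ai < aj) i else j)
  si <- length(rois@masks[[i]]); sj <- length(rois@masks[[j]])
  if (si != sj) return(if (si < sj) i else j)
  max(i, j)
}
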