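# Spatial statistics on ROI centroids.

#' Spatial-statistics parameters
#'
#' @param nResamples resampling-test null draws (default 500).
#' @param radiusUm adjacency radius in micrometres (default 50).
#' @param seed seed for the resampling draws.
#' @param tail "upper" tests whether the subset is sparser than chance
#'   (p = fraction of null medians at or above the observed median);
#'   "lower" counts null values below the observed statistic.
#' @return A validated parameter list of class \code{SpatialParams}.
#' @export
spatialParams <- function(nResamples = 500, radiusUm = 50, seed = 1,
                          tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopIfNot(isCount(nResamples) && nResamples >= 1,
            "'nResamples' must be a positive count")
  stopIfNot(isScalar(radiusUm) && radiusUm > 0, "'radiusUm' must be positive")
  structure(list(nResamples = as.integer(nResamples), radiusUm = radiusUm,
                 seed = seed, tail = tail), class = "SpatialParams")
}

#' Median pairwise distance
#'
#' Median over all C(n, 2) Euclidean distances; for an even count the
#' median is the mean of the central pair.
#'
#' @param points n x 2 coordinate matrix (micrometres).
#' @return median distance in the same units.
#' @examples
#' pairwiseMedianDistance(rbind(c(0, 0), c(3, 4)))   # 5
#' @export
pairwiseMedianDistance <- function(points) {
  stopIfNot(nrow(points) >= 2, "at least 2 points required")
  stats::median(stats::dist(points))
}

#' Resampling test on the median ROI distance
#'
#' The observed statistic is the median pairwise distance of the labelled
#' subset. The null distribution is built by drawing, \code{nResamples}
#' times, an equal number of ROIs without replacement from the whole
#' population (with replacement between resamples) and recomputing the
#' statistic. With \code{tail = "upper"} the p-value is the fraction of
#' null medians at or above the observed value, i.e. the test that the
#' subset is spatially sparser than chance; \code{tail = "lower"} counts
#' null values below the observed statistic instead. A p of 0 means
#' p < 1/nResamples (no smoothing is applied).
#'
#' @param points n x 2 coordinates of the whole ROI population
#'   (micrometres).
#' @param subset indices of the test population within \code{points}.
#' @param params a \code{\link{spatialParams}} list.
#' @return list: observedMedianUm, nullMedians, pValue, nullMeanUm,
#'   nullSdUm, tail.
#' @export
resamplingTest <- function(points, subset, params = spatialParams()) {
  n <- nrow(points)
  k <- length(subset)
  stopIfNot(k >= 2, "subset must contain at least 2 ROIs")
  stopIfNot(all(subset >= 1 & subset <= n), "subset indices out of range")
  if (k == n)
    warning("subset equals the whole population: the test is uninformative")
  observed <- pairwiseMedianDistance(points[subset, , drop = FALSE])
  nulls <- withSeed(params$seed, vapply(seq_len(params$nResamples),
    function(i) pairwiseMedianDistance(
      points[sample.int(n, k), , drop = FALSE]),
    numeric(1)))
  p <- if (params$tail == "upper") mean(nulls >= observed)
       else mean(nulls < observed)
  list(observedMedianUm = observed, nullMedians = nulls, pValue = p,
       nullMeanUm = mean(nulls), nullSdUm = stats::sd(nulls),
       tail = params$tail)
}

#' Neighbor counts within a fixed radius, by modulation type
#'
#' For each reference ROI, counts the neighbors of each label whose centers
#' lie within \code{radiusUm} (self excluded), then aggregates the mean and
#' SD of those counts by the reference ROI's label.
#'
#' @param points n x 2 coordinates (micrometres).
#' @param labels per-ROI labels in {"positive", "negative", "none"}.
#' @param params a \code{\link{spatialParams}} list.
#' @return list of two 3 x 3 matrices (\code{mean}, \code{sd}; rows =
#'   reference label, columns = neighbor label) and \code{perRoi}, the
#'   n x 3 matrix of raw neighbor counts.
#' @export
adjacencyCounts <- function(points, labels, params = spatialParams()) {
  n <- nrow(points)
  stopIfNot(length(labels) == n, "labels must align with points")
  lv <- c("positive", "negative", "none")
  D <- as.matrix(stats::dist(points))
  within <- D <= params$radiusUm
  diag(within) <- FALSE
  perRoi <- vapply(lv, function(l) {
    if (!any(labels == l)) return(numeric(n))
    rowSums(within[, labels == l, drop = FALSE])
  }, numeric(n))
  if (is.null(dim(perRoi))) perRoi <- matrix(perRoi, nrow = n)
  colnames(perRoi) <- lv
  mn <- matrix(NA_real_, 3, 3, dimnames = list(lv, lv))
  sd_ <- mn
  for (l in lv) {
    sel <- labels == l
    if (!any(sel)) next
    mn[l, ] <- colMeans(perRoi[sel, , drop = FALSE])
    sd_[l, ] <- apply(perRoi[sel, , drop = FALSE], 2, stats::sd)
  }
  list(mean = mn, sd = sd_, perRoi = perRoi)
}

#' Wilcoxon-Mann-Whitney rank-sum test (normal approximation)
#'
#' Midranks are used for ties; the z statistic uses the tie-corrected
#' variance of the rank sum and no continuity correction; the p-value is
#' two-sided. If all values across both groups are identical, z = 0 and
#' p = 1.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list: z, pValue, U (Mann-Whitney U of group \code{a}), W (rank
#'   sum of group \code{a}).
#' @export
rankSumTest <- function(a, b) {
  stopIfNot(length(a) >= 1 && length(b) >= 1, "both groups must be nonempty")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))                          # midranks
  W <- sum(r[seq_len(na)])
  U <- W - na * (na + 1) / 2
  muW <- na * (N + 1) / 2
  ties <- table(c(a, b))
  tieCorr <- sum(ties^3 - ties)
  v <- na * nb / 12 * ((N + 1) - tieCorr / (N * (N - 1)))
  if (v <= 0) return(list(z = 0, pValue = 1, U = U, W = W))
  z <- (W - muW) / sqrt(v)
  list(z = z, pValue = 2 * stats::pnorm(-abs(z)), U = U, W = W)
}
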