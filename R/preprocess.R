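# Point-cloud preprocessing: colour-threshold ground removal (Otsu),
# statistical outlier removal, farthest point sampling, normal estimation
# and centring/normalization.

# brute-force k-nearest-neighbour indices of `query` among `ref`
# (self-matches are NOT excluded); returns n_query x k index matrix,
# distance-sorted.  Pure vectorized base R; fine for the cloud sizes used.
knnIndices <- function(ref, query, k) {
  stopifnot(k <= nrow(ref))
  .cppKnn(ref, query, as.integer(k))
}

pairwiseSqDist <- function(a, b) {
  # |a_i - b_j|^2 = |a_i|^2 + |b_j|^2 - 2 a_i . b_j
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- matrix(bn, nrow(a), nrow(b), byrow = TRUE) - 2 * tcrossprod(a, b) + an
  d2[d2 < 0] <- 0
  d2
}

#' Otsu threshold of a scalar sample over a 256-bin histogram
#'
#' Exhaustively evaluates all 256 candidate thresholds and returns the one
#' maximizing the between-class variance.
#'
#' @param x numeric vector, rescaled internally to \[0, 255\].
#' @return list with `threshold` (on the original scale) and `bin`
#'   (0-based bin index), or `NULL` when the histogram is degenerate
#'   (a single occupied bin).
#' @export
otsuThreshold <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NULL)
  bins <- pmin(floor((x - lo) / (hi - lo) * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  denom <- omega * (1 - omega)
  sigmaB <- (muT * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  if (all(is.na(sigmaB))) return(NULL)
  kbin <- which.max(sigmaB) # threshold: bins <= kbin-1 are class 0
  thr <- lo + (kbin / 256) * (hi - lo)
  list(threshold = thr, bin = kbin - 1L)
}

#' Colour-threshold ground removal by Otsu's method
#'
#' Computes a scalar per point (excess green `2G - R - B` by default, or a
#' grayscale mean, or one raw channel), finds the Otsu threshold of its
#' 256-bin histogram, and keeps the class on the plant side (higher excess
#' green by default).
#'
#' @param cloud a [PointCloud-class] with colours.
#' @param scalar `"exg"`, `"gray"`, or a channel index 1-3.
#' @param keep `"above"` (default: plant has the larger scalar) or
#'   `"below"`.
#' @return the retained subset of `cloud`.  If the histogram is degenerate
#'   (all points in one bin), the cloud is returned unchanged with a warning.
#' @export
otsuGroundRemoval <- function(cloud, scalar = "exg", keep = c("above", "below")) {
  keep <- match.arg(keep)
  cols <- pointColors(cloud)
  if (is.null(cols)) stop("otsuGroundRemoval requires colours")
  s <- if (identical(scalar, "exg")) {
    2 * cols[, 2] - cols[, 1] - cols[, 3]
  } else if (identical(scalar, "gray")) {
    rowMeans(cols)
  } else if (is.numeric(scalar) && scalar %in% 1:3) {
    cols[, scalar]
  } else stop("scalar must be 'exg', 'gray', or a channel index 1-3")
  ot <- otsuThreshold(s)
  if (is.null(ot)) {
    warning("degenerate colour histogram; cloud returned unchanged")
    return(cloud)
  }
  mask <- if (keep == "above") s > ot$threshold else s <= ot$threshold
  if (!any(mask)) {
    warning("Otsu threshold left one class empty; cloud returned unchanged")
    return(cloud)
  }
  cloud[mask]
}

#' Statistical outlier removal
#'
#' For each point, the mean Euclidean distance to its `k` nearest neighbours
#' is computed; points whose mean distance exceeds
#' `mean + alpha * sd` of these values (over the whole cloud) are removed.
#'
#' @param cloud a [PointCloud-class].
#' @param k neighbour count (`1 <= k < nPoints(cloud)`).
#' @param alpha standard-deviation multiplier.
#' @return the surviving subset of `cloud`.
#' @export
statisticalOutlierRemoval <- function(cloud, k = 16L, alpha = 2.5) {
  n <- nPoints(cloud)
  if (k >= n) stop("k must be smaller than the number of points")
  if (k < 1) stop("k must be >= 1")
  pos <- positions(cloud)
  d2 <- pairwiseSqDist(pos, pos)
  diag(d2) <- Inf
  meanDist <- apply(d2, 1L, function(r) mean(sqrt(sort(r, partial = k)[seq_len(k)])))
  thr <- mean(meanDist) + alpha * stats::sd(meanDist)
  cloud[meanDist <= thr]
}

#' Farthest point sampling
#'
#' Greedy max-min subsampling: starting from `start`, each subsequent index
#' maximizes the minimum distance to the already-selected set.
#'
#' @param cloud a [PointCloud-class], or an `N x 3` position matrix.
#' @param m target count (`1 <= m <= N`).
#' @param start index of the first selected point; the default `"canonical"`
#'   picks the lexicographically smallest (x, y, z), which is stable under
#'   point permutations.
#' @return integer vector of `m` selected indices in selection order.
#' @export
farthestPointSampling <- function(cloud, m, start = "canonical") {
  pos <- if (is(cloud, "PointCloud")) positions(cloud) else as.matrix(cloud)
  n <- nrow(pos)
  if (m > n) stop("m must not exceed the number of points")
  if (m < 1) stop("m must be >= 1")
  if (identical(start, "canonical")) {
    start <- do.call(order, as.data.frame(pos))[1]
  }
  .cppFps(pos, as.integer(m), as.integer(start))
}

#' Estimate per-point normals from local PCA
#'
#' The normal of each point is the eigenvector of the smallest eigenvalue of
#' its `k`-nearest-neighbour covariance; orientation is flipped to a positive
#' z-component (ties broken toward positive x).
#'
#' @param cloud a [PointCloud-class].
#' @param k neighbour count (`3 <= k < nPoints(cloud)`).
#' @return `cloud` with the `normals` channel replaced.
#' @export
estimateNormals <- function(cloud, k = 16L) {
  n <- nPoints(cloud)
  if (k < 3) stop("k must be >= 3")
  if (k >= n) stop("k must be smaller than the number of points")
  pos <- positions(cloud)
  idx <- knnIndices(pos, pos, k + 1L) # includes self
  nrm <- matrix(0, n, 3)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    nb <- pos[idx[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300)) {
      degenerate <- TRUE
      nrm[i, ] <- c(0, 0, 1)
    } else {
      v <- ev$vectors[, 3]
      if (v[3] < 0 || (v[3] == 0 && v[1] < 0)) v <- -v
      nrm[i, ] <- v
    }
  }
  if (degenerate) warning("degenerate neighbourhood(s): normal set to (0,0,1)")
  initialize(cloud, normals = nrm)
}

#' Centre and normalize a point cloud
#'
#' Subtracts the centroid and divides by the maximum point norm, recording
#' the transform so positions can be inverted exactly.
#'
#' @param cloud a [PointCloud-class].
#' @return list with `cloud` (normalized) and `transform`
#'   (`list(center, scale)`; the inverse map is `x * scale + center`).
#' @export
centerNormalize <- function(cloud) {
  pos <- positions(cloud)
  ctr <- colMeans(pos)
  pos <- sweep(pos, 2, ctr)
  sc <- sqrt(max(rowSums(pos^2)))
  if (sc == 0) {
    warning("all points coincident; scale set to 1")
    sc <- 1
  }
  list(cloud = initialize(cloud, positions = pos / sc),
       transform = list(center = ctr, scale = sc))
}

#' Invert a centre/normalize transform
#'
#' @param cloud a normalized [PointCloud-class].
#' @param transform the `transform` record from [centerNormalize()].
#' @return the cloud mapped back to original coordinates.
#' @export
denormalize <- function(cloud, transform) {
  pos <- sweep(positions(cloud) * transform$scale, 2, transform$center, `+`)
  initialize(cloud, positions = pos)
}
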