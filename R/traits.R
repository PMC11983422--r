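# Geometric trait extraction from a segmented plant cloud: stem height and
# diameter after PCA alignment, and leaf length / width from PCA-segmented
# polylines snapped onto the leaf surface.

#' Measurement polyline
#'
#' @slot vertices ordered `n x 3` matrix (n >= 2).
#' @slot role `"length"` or `"width"`.
#' @slot smoothed whether Gaussian smoothing has been applied.
#' @export
setClass("Polyline",
  representation(vertices = "matrix", role = "character", smoothed = "logical"),
  prototype(role = "length", smoothed = FALSE))

setValidity("Polyline", function(object) {
  if (nrow(object@vertices) < 2) return("a polyline needs at least 2 vertices")
  if (ncol(object@vertices) != 3) return("vertices must be 3-D")
  if (!object@role %in% c("length", "width")) return("role must be length/width")
  TRUE
})

Polyline <- function(vertices, role = "length", smoothed = FALSE) {
  new("Polyline", vertices = as.matrix(vertices), role = role,
      smoothed = smoothed)
}

#' Length of a polyline
#' @param x a [Polyline-class].
#' @return sum of consecutive segment lengths.
#' @export
setGeneric("polylineLength", function(x) standardGeneric("polylineLength"))

#' @rdname polylineLength
#' @export
setMethod("polylineLength", "Polyline", function(x) {
  sum(sqrt(rowSums(diff(x@vertices)^2)))
})

#' Extracted trait report
#'
#' @slot stem_height stem extent along the aligned axis.
#' @slot stem_diameter twice the median absolute plane-fit residual of the
#'   basal stem quarter (the procedural stem thickness measure).
#' @slot leaves list of per-leaf records: `leaf_id`, `length`, `width`,
#'   `length_polyline`, `width_polyline`.
#' @slot rotation the 3 x 3 alignment rotation applied to the cloud.
#' @export
setClass("TraitReport",
  representation(stem_height = "numeric", stem_diameter = "numeric",
                 leaves = "list", rotation = "matrix"))

setValidity("TraitReport", function(object) {
  R <- object@rotation
  if (any(abs(crossprod(R) - diag(3)) > 1e-6)) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must have det +1")
  TRUE
})

setMethod("show", "TraitReport", function(object) {
  cat(sprintf("TraitReport: stem height %.3f, stem diameter %.3f, %d leaves\n",
              object@stem_height, object@stem_diameter, length(object@leaves)))
  for (lf in object@leaves) {
    cat(sprintf("  leaf %d: length %.3f, width %.3f\n",
                lf$leaf_id, lf$length, lf$width))
  }
})

#' Flatten a trait report to a data.frame
#'
#' One row per leaf; stem traits repeated.
#'
#' @param report a [TraitReport-class].
#' @param plant_id identifier column value.
#' @return data.frame with columns plant_id, stem_height, stem_diameter,
#'   leaf_id, leaf_length, leaf_width.
#' @export
traitsAsDataFrame <- function(report, plant_id = 1L) {
  if (!length(report@leaves)) {
    return(data.frame(plant_id = plant_id, stem_height = report@stem_height,
                      stem_diameter = report@stem_diameter,
                      leaf_id = NA_integer_, leaf_length = NA_real_,
                      leaf_width = NA_real_))
  }
  do.call(rbind, lapply(report@leaves, function(lf) {
    data.frame(plant_id = plant_id, stem_height = report@stem_height,
               stem_diameter = report@stem_diameter, leaf_id = lf$leaf_id,
               leaf_length = lf$length, leaf_width = lf$width)
  }))
}

# Rodrigues rotation taking unit vector a onto unit vector b
rotationBetween <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-18) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * a) * a
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

#' Align the stem's principal axis with +z
#'
#' The first PCA axis of the stem-labelled points defines the stem
#' direction (sign chosen so the cloud's mass lies upward of the stem
#' base); the whole cloud is rotated so this direction becomes +z.
#'
#' @param cloud a labelled [PointCloud-class].
#' @param stemClass stem label value (default 0).
#' @return list with `cloud` (rotated) and `rotation` (3 x 3).
#' @export
alignStemToZ <- function(cloud, stemClass = 0L) {
  lab <- pointLabels(cloud)
  if (is.null(lab)) stop("alignStemToZ requires labels")
  stem <- positions(cloud)[lab == stemClass, , drop = FALSE]
  if (nrow(stem) < 3) stop("need at least 3 stem points")
  pc <- stats::prcomp(stem, center = TRUE)
  v <- pc$rotation[, 1]
  # orient upward: the non-stem mass (or, failing that, +z) points along v
  other <- positions(cloud)[lab != stemClass, , drop = FALSE]
  refdir <- if (nrow(other)) colMeans(other) - colMeans(stem) else c(0, 0, 1)
  if (sum(v * refdir) < 0) v <- -v
  R <- rotationBetween(v, c(0, 0, 1))
  pos <- positions(cloud) %*% t(R)
  out <- initialize(cloud, positions = pos,
                    normals = if (!is.null(normals(cloud)))
                      normals(cloud) %*% t(R) else cloud@normals)
  list(cloud = out, rotation = R)
}

#' Stem height of an aligned cloud
#'
#' @param cloud an aligned, labelled [PointCloud-class].
#' @param stemClass stem label value.
#' @return `max(z) - min(z)` over stem points.
#' @export
stemHeight <- function(cloud, stemClass = 0L) {
  z <- positions(cloud)[pointLabels(cloud) == stemClass, 3]
  if (length(z) < 2) {
    warning("degenerate stem (fewer than 2 points); height 0")
    return(0)
  }
  max(z) - min(z)
}

#' Procedural stem diameter of an aligned cloud
#'
#' The stem's z-range is split into four equal-height bins; in the lowest
#' bin a least-squares plane `z = a x + b y + c` is fitted and the stem
#' diameter is reported as twice the median absolute residual.
#'
#' @param cloud an aligned, labelled [PointCloud-class].
#' @param stemClass stem label value.
#' @return the diameter estimate.
#' @export
stemDiameter <- function(cloud, stemClass = 0L) {
  p <- positions(cloud)[pointLabels(cloud) == stemClass, , drop = FALSE]
  z <- p[, 3]
  zcut <- min(z) + (max(z) - min(z)) / 4
  base <- p[z <= zcut, , drop = FALSE]
  if (nrow(base) < 8) stop("need at least 8 stem points in the lowest quarter")
  X <- cbind(1, base[, 1], base[, 2])
  qx <- qr(X)
  if (qx$rank < 3) {
    warning("rank-deficient basal fit; falling back to z = mean(z)")
    res <- base[, 3] - mean(base[, 3])
  } else {
    coef <- qr.coef(qx, base[, 3])
    res <- base[, 3] - X %*% coef
  }
  d <- 2 * stats::median(abs(res))
  if (d == 0) warning("all basal residuals zero; diameter 0")
  d
}

#' Partition a leaf cloud into segments along its principal direction
#'
#' Points are projected onto the leaf's first PCA axis and cut into
#' `n_segments` equal-width projection intervals; empty intervals are merged
#' into their neighbours.
#'
#' @param pts `N x 3` leaf positions.
#' @param n_segments number of segments (>= 2, <= N).
#' @return list of integer index vectors (into `pts`), ordered along the
#'   principal direction; attribute `axis` holds the unit principal vector.
#' @export
leafSegments <- function(pts, n_segments = 15L) {
  if (n_segments < 2) stop("n_segments must be >= 2")
  if (n_segments > nrow(pts)) stop("n_segments exceeds the number of points")
  pc <- stats::prcomp(pts, center = TRUE)
  axis <- pc$rotation[, 1]
  proj <- as.numeric(pts %*% axis)
  br <- seq(min(proj), max(proj), length.out = n_segments + 1)
  bin <- pmin(pmax(findInterval(proj, br, rightmost.closed = TRUE), 1L),
              n_segments)
  segs <- split(seq_len(nrow(pts)), factor(bin, levels = seq_len(n_segments)))
  segs <- segs[lengths(segs) > 0]        # empty intervals merge away
  names(segs) <- NULL
  attr(segs, "axis") <- axis
  segs
}

snapToCloud <- function(q, pts) {
  # nearest neighbour, ties by lowest index (order() is stable)
  d2 <- colSums((t(pts) - q)^2)
  pts[which.min(d2), ]
}

# project a chord point onto the cloud: among the K points whose coordinate
# along `u` is closest to q's, take the Euclidean-nearest.  This follows the
# surface transversally to the chord (an arched section snaps to the arch
# above the chord, not to the chord ends).
snapProjected <- function(q, pts, u, K = 8L) {
  ax <- abs(as.numeric(pts %*% u) - sum(q * u))
  K <- min(K, nrow(pts))
  cand <- order(ax)[seq_len(K)]
  sub <- pts[cand, , drop = FALSE]
  sub[which.min(colSums((t(sub) - q)^2)), ]
}

#' Width polyline of one leaf segment
#'
#' The segment's own first PCA axis defines the transverse direction; the
#' extreme-projection points are the chord ends, `m_insert` uniform points
#' on the chord are snapped to the nearest cloud point, and the polyline
#' start -> snapped points -> end measures the (possibly arched) width.
#'
#' @param segPts `n x 3` segment positions (n >= 2).
#' @param m_insert number of inserted chord points (0 gives the chord).
#' @return a [Polyline-class] with role `"width"`.
#' @export
segmentWidthPolyline <- function(segPts, m_insert = 20L) {
  stopifnot(nrow(segPts) >= 2)
  pc <- stats::prcomp(segPts, center = TRUE)
  axis <- pc$rotation[, 1]
  proj <- as.numeric(segPts %*% axis)
  ctr <- colMeans(segPts)
  # chord ends: the extreme projection values, taken on the axis line
  # through the segment centroid and projected back onto the surface
  # (prevents the chord from running diagonally across the segment)
  a <- snapProjected(ctr + (min(proj) - sum(ctr * axis)) * axis, segPts, axis)
  b <- snapProjected(ctr + (max(proj) - sum(ctr * axis)) * axis, segPts, axis)
  verts <- rbind(a, deparse.level = 0)
  if (m_insert > 0) {
    tt <- seq_len(m_insert) / (m_insert + 1)
    for (t in tt) {
      q <- a + t * (b - a)
      verts <- rbind(verts, snapProjected(q, segPts, axis))
    }
  }
  verts <- rbind(verts, b)
  Polyline(verts, role = "width")
}

#' Length polyline of a leaf from its segments
#'
#' Per segment, the midpoint of its extreme-projection points (the chord
#' centre) is snapped to the nearest point of that segment, giving one
#' centreline vertex per segment.  The polyline runs from the leaf's extreme
#' projection at one end, through the snapped midpoints, to the opposite
#' extreme (end vertices are re-centred transversally by projecting the
#' extreme parameter onto the cloud).  `m_insert` points are then inserted
#' uniformly on each chord and projected onto the cloud, so the polyline
#' follows the leaf's curvature between midpoints.
#'
#' @param pts `N x 3` leaf positions.
#' @param segs segment index list from [leafSegments()].
#' @param m_insert inserted points per chord (default 4).
#' @return a [Polyline-class] with role `"length"`.
#' @export
leafLengthPolyline <- function(pts, segs, m_insert = 4L) {
  stopifnot(length(segs) >= 2)
  axis <- attr(segs, "axis")
  gproj <- as.numeric(pts %*% axis)
  mids <- t(vapply(segs, function(idx) {
    sp <- pts[idx, , drop = FALSE]
    if (nrow(sp) == 1) return(sp[1, ])
    pc <- stats::prcomp(sp, center = TRUE)
    proj <- as.numeric(sp %*% pc$rotation[, 1])
    q <- (sp[which.min(proj), ] + sp[which.max(proj), ]) / 2
    snapToCloud(q, sp)
  }, numeric(3)))
  # end vertices: extreme projection values, centred at the adjacent midline
  tgt1 <- mids[1, ] + (min(gproj) - sum(mids[1, ] * axis)) * axis
  tgtN <- mids[nrow(mids), ] + (max(gproj) - sum(mids[nrow(mids), ] * axis)) * axis
  verts <- rbind(snapToCloud(tgt1, pts), mids, snapToCloud(tgtN, pts),
                 deparse.level = 0)
  if (m_insert > 0) {
    out <- verts[1, , drop = FALSE]
    for (i in 2:nrow(verts)) {
      a <- verts[i - 1, ]; b <- verts[i, ]
      u <- b - a
      nu <- sqrt(sum(u^2))
      if (nu > 0) {
        u <- u / nu
        for (t in seq_len(m_insert) / (m_insert + 1)) {
          out <- rbind(out, snapProjected(a + t * nu * u, pts, u))
        }
      }
      out <- rbind(out, b)
    }
    verts <- out
  }
  Polyline(verts, role = "length")
}

#' Gaussian-smooth a polyline
#'
#' Each coordinate sequence is convolved with a 1-D Gaussian kernel
#' (reflect boundary).  `sigma <= 0` returns the polyline unchanged.
#'
#' @param polyline a [Polyline-class] (>= 3 vertices to have any effect).
#' @param sigma kernel standard deviation in vertex units.
#' @param anchor keep the two end vertices fixed (used for length
#'   polylines, whose ends are the leaf extremities).
#' @return the smoothed [Polyline-class] (flag set).
#' @export
gaussianSmoothPolyline <- function(polyline, sigma = 1.0, anchor = FALSE) {
  if (sigma <= 0) return(polyline)
  v <- polyline@vertices
  n <- nrow(v)
  if (n < 3) return(polyline)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  # mirror indices about the ends (period 2n - 2)
  reflectIdx <- function(i) {
    j <- (i - 1) %% (2 * n - 2)
    j <- ifelse(j >= n, 2 * n - 2 - j, j)
    j + 1L
  }
  padIdx <- reflectIdx((1 - r):(n + r))
  sm <- apply(v, 2, function(x) {
    as.numeric(stats::filter(x[padIdx], kern, sides = 2))[r + seq_len(n)]
  })
  if (anchor) {
    sm[1, ] <- v[1, ]
    sm[n, ] <- v[n, ]
  }
  initialize(polyline, vertices = sm, smoothed = TRUE)
}

#' Euclidean connected components of a point set
#'
#' Single-linkage components under a distance threshold.
#'
#' @param pts `N x 3` positions.
#' @param threshold linkage distance; default 3x the median nearest-
#'   neighbour spacing.
#' @return integer component id per point (1-based, ordered by component
#'   minimum index).
#' @export
euclideanComponents <- function(pts, threshold = NULL) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  d2 <- pairwiseSqDist(pts, pts)
  diag(d2) <- Inf
  if (is.null(threshold)) {
    # surface sampling is much denser transversally than along sparse
    # regions, so the linkage needs ample headroom over the median spacing
    nn <- sqrt(apply(d2, 1, min))
    threshold <- 5 * stats::median(nn)
  }
  adj <- d2 <= threshold^2
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      nbr <- which(adj[j, ] & comp == 0L)
      comp[nbr] <- cur
      queue <- c(queue, nbr)
    }
  }
  comp
}

#' Separate leaf instances from semantically labelled leaf points
#'
#' Connected components of the symmetric k-nearest-neighbour graph.  Unlike
#' a fixed distance threshold, the kNN graph adapts to the large density
#' differences between small and large leaves.
#'
#' @param pts `N x 3` leaf positions.
#' @param k neighbour count of the graph (default 10).
#' @return integer component id per point.
#' @export
leafInstances <- function(pts, k = 10L) {
  n <- nrow(pts)
  if (n <= k) return(rep(1L, n))
  idx <- knnIndices(pts, pts, k + 1L)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (p in seq_len(n)) {
    for (j in 2:(k + 1L)) {
      rp <- find(p); rq <- find(idx[p, j])
      if (rp != rq) parent[rp] <- rq
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

#' Extract phenotypic traits from a segmented cloud
#'
#' Aligns the stem to +z, measures stem height and (procedural) stem
#' diameter, separates leaf instances by Euclidean connected components,
#' and measures each leaf's length and width from smoothed PCA polylines.
#' Width is the maximum over per-segment width polylines.
#'
#' @param cloud a labelled [PointCloud-class].
#' @param stemClass,leafClass label values for stem and leaf.
#' @param n_segments leaf segments (default 15).
#' @param m_insert inserted chord points per width polyline (default 20).
#' @param sigma polyline smoothing sd in vertex units (default 1).
#' @param min_leaf_points leaf components smaller than this are ignored.
#' @return a [TraitReport-class].
#' @export
extractTraits <- function(cloud, stemClass = 0L, leafClass = 1L,
                          n_segments = 15L, m_insert = 20L, sigma = 1.0,
                          min_leaf_points = 30L) {
  lab <- pointLabels(cloud)
  if (is.null(lab)) stop("extractTraits requires labels")
  if (!any(lab == stemClass)) stop("no stem-labelled points")
  al <- alignStemToZ(cloud, stemClass)
  aligned <- al$cloud
  sh <- stemHeight(aligned, stemClass)
  sd_ <- tryCatch(stemDiameter(aligned, stemClass), error = function(e) NA_real_)
  leaves <- list()
  lpts <- positions(aligned)[pointLabels(aligned) == leafClass, , drop = FALSE]
  if (nrow(lpts) >= min_leaf_points) {
    comp <- leafInstances(lpts)
    for (ci in seq_len(max(comp))) {
      pts <- lpts[comp == ci, , drop = FALSE]
      if (nrow(pts) < min_leaf_points) next
      ns <- min(n_segments, max(2L, nrow(pts) %/% 4L))
      segs <- leafSegments(pts, ns)
      # width polylines carry more per-vertex snapping jitter relative to
      # their length, so they get a wider (anchored) kernel
      widths <- lapply(segs, function(idx) {
        if (length(idx) < 2) return(NULL)
        gaussianSmoothPolyline(
          segmentWidthPolyline(pts[idx, , drop = FALSE], m_insert),
          2 * sigma, anchor = TRUE)
      })
      widths <- Filter(Negate(is.null), widths)
      wlen <- vapply(widths, polylineLength, numeric(1))
      wbest <- which.max(wlen)
      lenPoly <- gaussianSmoothPolyline(leafLengthPolyline(pts, segs), sigma,
                                        anchor = TRUE)
      leaves[[length(leaves) + 1L]] <- list(
        leaf_id = length(leaves) + 1L,
        length = polylineLength(lenPoly), width = wlen[wbest],
        length_polyline = lenPoly, width_polyline = widths[[wbest]])
    }
  }
  new("TraitReport", stem_height = sh, stem_diameter = sd_,
      leaves = leaves, rotation = al$rotation)
}

#' Coefficient of determination and root-mean-square error
#'
#' `R^2 = 1 - sum((v - vhat)^2) / sum((v - mean(v))^2)`;
#' `RMSE = sqrt(mean((v - vhat)^2))`.
#'
#' @param measured,predicted equal-length numeric vectors.
#' @return named vector `c(r2, rmse)`.
#' @export
r2Rmse <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) > 0)
  ssTot <- sum((measured - mean(measured))^2)
  if (ssTot == 0) stop("R^2 undefined: measured values are constant")
  ssRes <- sum((measured - predicted)^2)
  c(r2 = 1 - ssRes / ssTot,
    rmse = sqrt(mean((measured - predicted)^2)))
}
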