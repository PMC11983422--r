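# Expected-depth point-cloud extraction from an implicit density/colour
# field.  Discrete volume rendering along each ray:
#   alpha_i = 1 - exp(-sigma_i * delta_i)
#   T_i     = prod_{j < i} (1 - alpha_j)
#   w_i     = T_i * alpha_i
#   t*      = sum(d_i w_i) / sum(w_i)
# and the surface point is p = o + t* d, coloured by querying the field at p.

#' Per-ray samples for depth compositing
#'
#' @slot depths strictly increasing sample depths (length M).
#' @slot deltas positive interval lengths (length M).
#' @slot densities non-negative densities (length M).
#' @slot colors optional M x 3 sample colours (`0 x 3` when absent).
#' @export
setClass("RaySamples",
  representation(depths = "numeric", deltas = "numeric",
                 densities = "numeric", colors = "matrix"),
  prototype(colors = matrix(numeric(0), ncol = 3)))

setValidity("RaySamples", function(object) {
  msg <- character(0)
  m <- length(object@depths)
  if (m < 1) msg <- c(msg, "at least one sample required")
  if (any(diff(object@depths) <= 0)) msg <- c(msg, "depths must be strictly increasing")
  if (length(object@deltas) != m) msg <- c(msg, "deltas must match depths")
  if (any(object@deltas <= 0)) msg <- c(msg, "deltas must be positive")
  if (length(object@densities) != m) msg <- c(msg, "densities must match depths")
  if (any(object@densities < 0)) msg <- c(msg, "densities must be non-negative")
  if (nrow(object@colors) > 0 && nrow(object@colors) != m) {
    msg <- c(msg, "colors must match depths")
  }
  if (length(msg)) msg else TRUE
})

#' Construct RaySamples
#'
#' @param depths ascending sample depths.
#' @param densities non-negative densities at the samples.
#' @param deltas sample intervals; by default `diff(depths)` with the final
#'   interval extended to `far` (or replicating the last interval when `far`
#'   is `NULL`).
#' @param colors optional M x 3 colour matrix.
#' @param far optional far bound defining the last interval.
#' @return a [RaySamples-class].
#' @export
raySamples <- function(depths, densities, deltas = NULL, colors = NULL, far = NULL) {
  if (is.null(deltas)) {
    d <- diff(depths)
    last <- if (!is.null(far)) far - depths[length(depths)]
            else if (length(d)) d[length(d)] else 1
    deltas <- c(d, last)
  }
  if (is.null(colors)) colors <- matrix(numeric(0), ncol = 3)
  new("RaySamples", depths = as.numeric(depths), deltas = as.numeric(deltas),
      densities = as.numeric(densities), colors = as.matrix(colors))
}

#' Per-sample opacities
#'
#' `alpha_i = 1 - exp(-sigma_i * delta_i)`, each in `[0, 1)`.
#'
#' @param samples a [RaySamples-class].
#' @return numeric vector of opacities.
#' @export
alphas <- function(samples) {
  1 - exp(-samples@densities * samples@deltas)
}

#' Accumulated transmittance
#'
#' `T_1 = 1`; `T_i = prod_{j < i} (1 - alpha_j)`; non-increasing.
#'
#' @param a vector of opacities in `[0, 1)`.
#' @return numeric vector of transmittances.
#' @export
transmittance <- function(a) {
  m <- length(a)
  if (m == 1L) return(1)
  c(1, cumprod(1 - a[-m]))
}

#' Volume-rendering weights
#'
#' `w_i = T_i * alpha_i`; their sum is `1 - prod(1 - alpha_j) <= 1`.
#'
#' @param samples a [RaySamples-class].
#' @return numeric vector of weights.
#' @export
renderWeights <- function(samples) {
  a <- alphas(samples)
  transmittance(a) * a
}

#' Expected depth of a ray
#'
#' `t* = sum(d_i w_i) / sum(w_i)` when the accumulated weight reaches
#' `weight_floor`; otherwise the ray is flagged invalid (no surface).
#'
#' @param samples a [RaySamples-class].
#' @param weight_floor minimum accumulated weight for a valid surface hit.
#' @return list with `t_surface` (NA when invalid), `weights`,
#'   `total_weight` and `valid`.
#' @export
expectedDepth <- function(samples, weight_floor = 0.5) {
  w <- renderWeights(samples)
  tw <- sum(w)
  valid <- tw >= weight_floor && tw > 0
  list(
    t_surface = if (valid) sum(samples@depths * w) / tw else NA_real_,
    weights = w, total_weight = tw, valid = valid)
}

#' Back-project a depth along a ray
#'
#' `p = o + t * d`.
#'
#' @param origin ray origin (3-vector).
#' @param direction unit ray direction (3-vector).
#' @param t depth (> 0).
#' @return 3-vector position.
#' @export
backproject <- function(origin, direction, t) {
  stopifnot(t > 0, abs(sqrt(sum(direction^2)) - 1) < 1e-9)
  origin + t * direction
}

#' Orthographic ray grid
#'
#' A `res x res` grid of parallel rays covering a square of half-width
#' `extent`, looking along `-normal` toward the origin from distance
#' `distance`.
#'
#' @param res rays per side.
#' @param extent half-width of the covered square.
#' @param distance distance of the ray origins from the world origin.
#' @param direction common unit viewing direction.
#' @return list of rays, each `list(origin, direction)`.
#' @export
orthographicRays <- function(res = 32, extent = 1, distance = 4,
                             direction = c(0, 0, -1)) {
  direction <- direction / sqrt(sum(direction^2))
  # build an orthonormal frame around the direction
  up <- if (abs(direction[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  right <- c(up[2] * direction[3] - up[3] * direction[2],
             up[3] * direction[1] - up[1] * direction[3],
             up[1] * direction[2] - up[2] * direction[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(direction[2] * right[3] - direction[3] * right[2],
           direction[3] * right[1] - direction[1] * right[3],
           direction[1] * right[2] - direction[2] * right[1])
  g <- seq(-extent, extent, length.out = res)
  rays <- vector("list", res * res)
  k <- 1L
  base <- -distance * direction
  for (i in seq_len(res)) for (j in seq_len(res)) {
    rays[[k]] <- list(origin = base + g[i] * right + g[j] * upv,
                      direction = direction)
    k <- k + 1L
  }
  rays
}

#' Orbiting orthographic views
#'
#' `n_views` orthographic ray grids looking inward from directions evenly
#' spaced on a horizontal orbit (with slight elevation).
#'
#' @param n_views number of views.
#' @param res rays per side per view.
#' @param extent half-width of each view's square.
#' @param distance origin distance.
#' @param elevation_deg elevation of the orbit above the horizon.
#' @return list of rays pooled over all views.
#' @export
orbitRays <- function(n_views = 6, res = 32, extent = 1, distance = 4,
                      elevation_deg = 15) {
  el <- elevation_deg * pi / 180
  out <- list()
  for (v in seq_len(n_views)) {
    az <- 2 * pi * (v - 1) / n_views
    dir <- -c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    out <- c(out, orthographicRays(res, extent, distance, dir))
  }
  out
}

#' Extract a point cloud from an implicit field
#'
#' Samples each ray uniformly (stratified midpoints) in `[t1, t2]`, queries
#' the field density, composites the expected depth, and back-projects one
#' surface point per valid ray, coloured by querying the field colour at the
#' surface point.  Rays whose accumulated weight falls below `weight_floor`
#' are dropped.
#'
#' @param field a field adapter: `list(density = function(p), color =
#'   function(p, d))` with `p` an `n x 3` matrix (e.g. [makeSlabField()]).
#' @param rays list of rays (`list(origin, direction)`), e.g. from
#'   [orbitRays()].
#' @param t1,t2 near/far sampling bounds (`t1 < t2`).
#' @param M samples per ray (>= 2).
#' @param weight_floor minimum accumulated weight for a surface point.
#' @return a [PointCloud-class] of the valid rays' surface points, or `NULL`
#'   with a warning when no ray reaches the weight floor.
#' @export
extractPointCloud <- function(field, rays, t1, t2, M = 128, weight_floor = 0.5) {
  stopifnot(length(rays) >= 1, t1 < t2, M >= 2)
  edges <- seq(t1, t2, length.out = M + 1)
  mids <- (edges[-1] + edges[-(M + 1)]) / 2
  delta <- rep(diff(edges)[1], M)
  pts <- matrix(NA_real_, length(rays), 3)
  cols <- matrix(NA_real_, length(rays), 3)
  valid <- logical(length(rays))
  for (i in seq_along(rays)) {
    r <- rays[[i]]
    p <- outer(mids, r$direction) + rep(r$origin, each = M)
    sig <- field$density(p)
    rs <- raySamples(mids, sig, deltas = delta)
    ed <- expectedDepth(rs, weight_floor)
    if (ed$valid) {
      valid[i] <- TRUE
      sp <- backproject(r$origin, r$direction, ed$t_surface)
      pts[i, ] <- sp
      cols[i, ] <- field$color(matrix(sp, 1, 3), r$direction)
    }
  }
  if (!any(valid)) {
    warning("no valid rays; returning NULL (empty cloud)")
    return(NULL)
  }
  PointCloud(pts[valid, , drop = FALSE],
             colors = cols[valid, , drop = FALSE], colorScale = "unit")
}
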