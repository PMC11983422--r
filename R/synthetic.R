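# Procedural generation of labelled plants and analytic density fields.
#
# Plants are built from a cylindrical stem plus leaf ribbons: a parametric
# centerline curve swept by a transverse segment of width w(s).  Both organ
# surfaces have closed-form arc length (or quadrature to machine precision),
# so stem height / diameter and leaf length / width ground truth is analytic.

#' Specify a leaf ribbon
#'
#' The centerline is either an arc of a circle (`"arc"`: radius `R`, sweep
#' angle `sweep_deg`, rising from horizontal) or a parabola
#' (`"parabola"`: z = -a x^2 over x in \[0, xmax\]).  The ribbon is the
#' centerline swept by a flat transverse segment of width `w(s)`; taper
#' `"flat"` keeps `w = max_width`, taper `"sine"` uses
#' `w(s) = max_width * sin(pi * s)` with `s` the normalized arc parameter.
#'
#' @param attach_height_frac attachment height as a fraction of stem length.
#' @param azimuth_deg azimuth of the leaf direction, degrees.
#' @param centerline `"arc"` or `"parabola"`.
#' @param R arc radius (centerline `"arc"`).
#' @param sweep_deg arc sweep in degrees (centerline `"arc"`).
#' @param a,xmax parabola coefficient and extent (centerline `"parabola"`).
#' @param max_width maximum ribbon width (length units).
#' @param taper `"flat"` or `"sine"` width profile.
#' @return a `LeafSpec` list.
#' @export
leafSpec <- function(attach_height_frac = 0.5, azimuth_deg = 0,
                     centerline = c("arc", "parabola"),
                     R = 10, sweep_deg = 90, a = 0.05, xmax = 10,
                     max_width = 2, taper = c("flat", "sine")) {
  centerline <- match.arg(centerline)
  taper <- match.arg(taper)
  stopifnot(attach_height_frac >= 0, attach_height_frac <= 1, max_width > 0)
  if (centerline == "arc") stopifnot(R > 0, sweep_deg > 0, sweep_deg <= 180)
  if (centerline == "parabola") stopifnot(xmax > 0)
  structure(list(
    attach_height_frac = attach_height_frac, azimuth_deg = azimuth_deg,
    centerline = centerline, R = R, sweep_deg = sweep_deg, a = a, xmax = xmax,
    max_width = max_width, taper = taper), class = "LeafSpec")
}

#' Specify a synthetic plant
#'
#' @param stem_radius stem cylinder radius (> 0).
#' @param stem_length stem length (> 0).
#' @param stem_tilt_deg stem tilt from vertical, in \[0, 90).
#' @param leaves list of [leafSpec()] objects.
#' @param points_per_organ exact number of surface samples per organ.
#' @param noise_sd isotropic Gaussian noise sd; default 0.1% of stem length.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return a `PlantSpec` list.
#' @export
plantSpec <- function(stem_radius = 1.2, stem_length = 80, stem_tilt_deg = 0,
                      leaves = list(leafSpec()), points_per_organ = 1024,
                      noise_sd = 0.001 * stem_length, seed = 1L) {
  stopifnot(stem_radius > 0, stem_length > 0,
            stem_tilt_deg >= 0, stem_tilt_deg < 90,
            noise_sd >= 0, points_per_organ >= 1)
  af <- vapply(leaves, `[[`, numeric(1), "attach_height_frac")
  if (anyDuplicated(af)) {
    stop("degenerate duplicate organ: identical leaf attach heights")
  }
  structure(list(
    stem_radius = stem_radius, stem_length = stem_length,
    stem_tilt_deg = stem_tilt_deg, leaves = leaves,
    points_per_organ = as.integer(points_per_organ),
    noise_sd = noise_sd, seed = as.integer(seed)), class = "PlantSpec")
}

# rotation about +y axis by ang (radians), then about +z by az
rotY <- function(ang) {
  c <- cos(ang); s <- sin(ang)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rotZ <- function(ang) {
  c <- cos(ang); s <- sin(ang)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# centerline in the leaf's local frame: starts at origin, initial direction
# +x, curving upward in the x-z plane; returns position, unit tangent and
# unit in-plane normal for parameter t in [0,1]
leafCenterline <- function(spec, t) {
  if (spec$centerline == "arc") {
    sweep <- spec$sweep_deg * pi / 180
    th <- t * sweep
    # circle centre at (0, 0, R): starts at origin moving along +x, bending up
    pos <- cbind(spec$R * sin(th), 0, spec$R * (1 - cos(th)))
    tan <- cbind(cos(th), 0, sin(th))
  } else {
    x <- t * spec$xmax
    pos <- cbind(x, 0, -spec$a * x^2)
    dz <- -2 * spec$a * x
    nrm <- sqrt(1 + dz^2)
    tan <- cbind(1 / nrm, 0, dz / nrm)
  }
  list(pos = pos, tangent = tan)
}

# arc length of the centerline by Gauss-Legendre-free quadrature
# (fine trapezoid on speed; exact for the arc)
leafArcLength <- function(spec) {
  if (spec$centerline == "arc") {
    return(spec$R * spec$sweep_deg * pi / 180)
  }
  f <- function(x) sqrt(1 + (2 * spec$a * x)^2)
  stats::integrate(f, 0, spec$xmax, rel.tol = 1e-10)$value
}

leafWidthAt <- function(spec, t) {
  if (spec$taper == "flat") rep(spec$max_width, length(t))
  else spec$max_width * sin(pi * pmin(pmax(t, 0), 1))
}

# the analytic leaf width ground truth: max over s of w(s)
leafMaxWidth <- function(spec) spec$max_width

#' Generate a labelled plant point cloud with analytic ground truth
#'
#' Samples `points_per_organ` points uniformly (in surface parameters) on the
#' stem cylinder and on each leaf ribbon, adds isotropic Gaussian noise, and
#' returns both the cloud (labels 0 = stem, 1 = leaf) and the analytic trait
#' ground truth: stem height (= stem length), stem diameter (= 2 radius),
#' per-leaf arc length and maximum width.
#'
#' @param spec a [plantSpec()].
#' @param ground add a brown ground disk (label 2) of `points_per_organ`
#'   points, used to exercise colour-threshold ground removal.
#' @return list with elements `cloud` ([PointCloud-class]) and `traits`
#'   (a `GroundTruthTraits` list: `stem_height`, `stem_diameter`,
#'   `leaf_lengths`, `leaf_widths`).
#' @export
generatePlant <- function(spec, ground = FALSE) {
  stopifnot(inherits(spec, "PlantSpec"))
  set.seed(spec$seed)
  n <- spec$points_per_organ
  tilt <- spec$stem_tilt_deg * pi / 180
  Rt <- rotY(tilt)

  # stem: lateral surface of a cylinder along local +z
  h <- stats::runif(n, 0, spec$stem_length)
  th <- stats::runif(n, 0, 2 * pi)
  stemLocal <- cbind(spec$stem_radius * cos(th), spec$stem_radius * sin(th), h)
  stemNrm <- cbind(cos(th), sin(th), 0)
  stemPos <- stemLocal %*% t(Rt)
  stemN <- stemNrm %*% t(Rt)
  stemCol <- cbind(stats::runif(n, 60, 90), stats::runif(n, 150, 180),
                   stats::runif(n, 40, 70))

  leafParts <- lapply(spec$leaves, function(lf) {
    s <- stats::runif(n)           # arc parameter
    u <- stats::runif(n, -0.5, 0.5) # transverse parameter
    cl <- leafCenterline(lf, s)
    w <- leafWidthAt(lf, s)
    # transverse direction = local +y (ribbon lies in the curve's osculating
    # plane swept sideways); surface normal = tangent x transverse
    pts <- cl$pos + cbind(0, u * w, 0)
    nrm <- cbind(-cl$tangent[, 3], 0, cl$tangent[, 1]) # rotate tangent 90 deg in x-z
    Raz <- rotZ(lf$azimuth_deg * pi / 180)
    pts[, 1] <- pts[, 1] + spec$stem_radius # emerge from the stem surface
    pts <- pts %*% t(Raz)
    pts[, 3] <- pts[, 3] + lf$attach_height_frac * spec$stem_length
    pts <- pts %*% t(Rt)
    nrm <- nrm %*% t(Raz) %*% t(Rt)
    col <- cbind(stats::runif(n, 40, 70), stats::runif(n, 170, 210),
                 stats::runif(n, 30, 60))
    list(pos = pts, nrm = nrm, col = col)
  })

  pos <- rbind(stemPos, do.call(rbind, lapply(leafParts, `[[`, "pos")))
  nrm <- rbind(stemN, do.call(rbind, lapply(leafParts, `[[`, "nrm")))
  col <- rbind(stemCol, do.call(rbind, lapply(leafParts, `[[`, "col")))
  lab <- c(rep(0L, n), rep(1L, n * length(spec$leaves)))

  if (ground) {
    r <- spec$stem_length * 0.6 * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    gpos <- cbind(r * cos(a), r * sin(a), 0)
    gnrm <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
    gcol <- cbind(stats::runif(n, 120, 150), stats::runif(n, 80, 110),
                  stats::runif(n, 50, 80))
    pos <- rbind(pos, gpos); nrm <- rbind(nrm, gnrm); col <- rbind(col, gcol)
    lab <- c(lab, rep(2L, n))
  }

  if (spec$noise_sd > 0) {
    pos <- pos + matrix(stats::rnorm(length(pos), sd = spec$noise_sd), ncol = 3)
  }
  nn <- sqrt(rowSums(nrm^2)); nrm <- nrm / nn

  traits <- list(
    stem_height = spec$stem_length,
    stem_diameter = 2 * spec$stem_radius,
    leaf_lengths = vapply(spec$leaves, leafArcLength, numeric(1)),
    leaf_widths = vapply(spec$leaves, leafMaxWidth, numeric(1)))
  class(traits) <- "GroundTruthTraits"
  list(cloud = PointCloud(pos, normals = nrm, colors = col, labels = lab),
       traits = traits)
}

#' Generate a reproducible toy dataset of labelled plants
#'
#' Per-plant specifications are drawn uniformly from `spec_ranges`, and an
#' 80/20 train/validation split of the plant indices is returned alongside.
#'
#' @param n_plants number of plants (>= 1).
#' @param seed integer seed for the specification draws and per-plant seeds.
#' @param spec_ranges named list of ranges: `stem_length`, `stem_radius`,
#'   `stem_tilt_deg`, `n_leaves` (integer range), `leaf_R`, `leaf_sweep_deg`,
#'   `leaf_width`; each a length-2 numeric `c(lo, hi)`.
#' @param points_per_organ samples per organ per plant.
#' @param noise_frac noise sd as a fraction of stem length.
#' @return list with `plants` (list of `list(cloud, traits)`), `specs`,
#'   `train` and `val` index vectors.
#' @export
makeToyDataset <- function(n_plants, seed = 1L,
                           spec_ranges = list(
                             stem_length = c(60, 100),
                             stem_radius = c(1.0, 1.6),
                             stem_tilt_deg = c(0, 15),
                             n_leaves = c(2, 4),
                             leaf_R = c(30, 60),
                             leaf_sweep_deg = c(60, 120),
                             leaf_width = c(6, 10)),
                           points_per_organ = 512L,
                           noise_frac = 0.001) {
  stopifnot(n_plants >= 1)
  set.seed(seed)
  ru <- function(rg) stats::runif(1, rg[1], rg[2])
  specs <- lapply(seq_len(n_plants), function(i) {
    nl <- sample(seq(spec_ranges$n_leaves[1], spec_ranges$n_leaves[2]), 1)
    af <- seq(0.3, 0.9, length.out = nl) + stats::runif(nl, -0.03, 0.03)
    leaves <- lapply(seq_len(nl), function(j) {
      leafSpec(attach_height_frac = af[j],
               azimuth_deg = stats::runif(1, 0, 360),
               centerline = "arc",
               R = ru(spec_ranges$leaf_R),
               sweep_deg = ru(spec_ranges$leaf_sweep_deg),
               max_width = ru(spec_ranges$leaf_width),
               taper = "sine")
    })
    sl <- ru(spec_ranges$stem_length)
    plantSpec(stem_radius = ru(spec_ranges$stem_radius), stem_length = sl,
              stem_tilt_deg = ru(spec_ranges$stem_tilt_deg), leaves = leaves,
              points_per_organ = points_per_organ,
              noise_sd = noise_frac * sl,
              seed = sample.int(.Machine$integer.max, 1))
  })
  plants <- lapply(specs, generatePlant)
  nTrain <- floor(0.8 * n_plants)
  if (nTrain < 1L) {
    warning("degenerate split: single plant assigned to the training set")
    nTrain <- n_plants
  }
  perm <- sample.int(n_plants)
  list(plants = plants, specs = specs,
       train = sort(perm[seq_len(nTrain)]),
       val = sort(perm[setdiff(seq_len(n_plants), seq_len(nTrain))]))
}

# --- analytic density fields -------------------------------------------

#' Analytic constant-density slab field
#'
#' Density is `sigma0` wherever the ray depth lies in `[near, far]` measured
#' along the ray (the slab is normal to each axis-aligned ray's direction),
#' and 0 outside.  The closed-form expected depth of a ray entering at
#' `near` is the mass-weighted mean of the continuous rendering weights,
#' available symbolically for the constant-density case:
#' `t* = near + 1/sigma0 - L * exp(-sigma0 L) / (1 - exp(-sigma0 L))` with
#' `L = far - near`.
#'
#' @param near,far slab bounds along the ray, `0 < near < far`.
#' @param sigma0 slab density (> 0).
#' @return an `AnalyticField` list with `density`, `color` and
#'   `closed_form_depth` functions.  `density(p)` here depends on the
#'   z-coordinate (slab normal +z), matching downward axis-aligned rays;
#'   `closed_form_depth(origin, direction)` is exact for any ray whose
#'   direction is unit length.
#' @export
makeSlabField <- function(near, far, sigma0) {
  stopifnot(near > 0, far > near, sigma0 > 0)
  L <- far - near
  field <- list(
    # slab occupies z in [-Inf, +Inf] x depth band: we realize it as the
    # region between two planes perpendicular to +z at z = near..far
    density = function(p) {
      sigma0 * as.numeric(p[, 3] >= near & p[, 3] <= far)
    },
    color = function(p, d) {
      matrix(rep(c(0.2, 0.8, 0.2), each = nrow(p)), ncol = 3)
    },
    # exact expected depth for a +z unit ray from the origin:
    # t* = near + 1/sigma0 - L exp(-sigma0 L) / (1 - exp(-sigma0 L))
    closed_form_depth = function(origin = c(0, 0, 0), direction = c(0, 0, 1)) {
      em <- exp(-sigma0 * L)
      near + 1 / sigma0 - L * em / (1 - em)
    })
  class(field) <- "AnalyticField"
  field
}

#' Analytic constant-density sphere field
#'
#' Density `sigma0` inside a sphere of radius `radius` centred at `center`,
#' 0 outside.
#'
#' @param center sphere centre (3-vector).
#' @param radius sphere radius (> 0).
#' @param sigma0 interior density (> 0).
#' @return an `AnalyticField` list with `density` and `color` functions.
#' @export
makeSphereField <- function(center = c(0, 0, 0), radius = 1, sigma0 = 200) {
  stopifnot(radius > 0, sigma0 > 0)
  field <- list(
    density = function(p) {
      d2 <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 + (p[, 3] - center[3])^2
      sigma0 * as.numeric(d2 <= radius^2)
    },
    color = function(p, d) {
      matrix(rep(c(0.8, 0.2, 0.2), each = nrow(p)), ncol = 3)
    },
    closed_form_depth = NULL)
  class(field) <- "AnalyticField"
  field
}
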