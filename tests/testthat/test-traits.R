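# Trait extraction: alignment, stem measures, leaf polylines, scoring.

cylinderStem <- function(n = 600, r = 0.5, L = 10, tilt = 0, seed = 51) {
  set.seed(seed)
  h <- runif(n, 0, L); th <- runif(n, 0, 2 * pi)
  pts <- cbind(r * cos(th), r * sin(th), h)
  if (tilt != 0) {
    a <- tilt * pi / 180
    Rt <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
    pts <- pts %*% Rt
  }
  pts
}

test_that("stem alignment maps the principal axis to +z", {
  pts <- cylinderStem(tilt = 45)
  cl <- PointCloud(rbind(pts, sweep(matrix(rnorm(60, sd = 0.2), ncol = 3), 2,
                                    c(0, 0, 12), `+`)),
                   labels = c(rep(0L, 600), rep(1L, 20)))
  al <- alignStemToZ(cl)
  R <- al$rotation
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
  stem <- positions(al$cloud)[pointLabels(al$cloud) == 0L, ]
  ax <- prcomp(stem)$rotation[, 1]
  angle <- acos(min(1, abs(ax[3]))) * 180 / pi
  expect_lt(angle, 0.5)
  # vertical stems are already aligned (rotation ~ identity up to sign)
  vert <- PointCloud(cylinderStem(tilt = 0), labels = rep(0L, 600))
  alv <- alignStemToZ(vert)
  expect_equal(abs(alv$rotation[3, 3]), 1, tolerance = 1e-3)
  expect_error(alignStemToZ(PointCloud(matrix(0, 2, 3) + runif(6),
                                       labels = c(0L, 0L))), "3 stem points")
})

test_that("stem height is the aligned axial extent", {
  vert <- PointCloud(cylinderStem(L = 10), labels = rep(0L, 600))
  expect_equal(stemHeight(vert), 10, tolerance = 0.02)
  tilted <- PointCloud(cylinderStem(L = 10, tilt = 30), labels = rep(0L, 600))
  al <- alignStemToZ(tilted)
  expect_equal(stemHeight(al$cloud), 10, tolerance = 0.1)
  single <- PointCloud(matrix(c(0, 0, 1), 1, 3), labels = 0L)
  expect_warning(h <- stemHeight(single), "degenerate")
  expect_equal(h, 0)
})

test_that("stem diameter doubles the median plane-fit residual", {
  set.seed(52)
  n <- 200
  x <- rep(runif(n / 2), 2); y <- rep(runif(n / 2), 2)
  eta <- rep(c(-0.3, 0.3), each = n / 2) # balanced pairs: exact plane fit
  pts <- cbind(x, y, 0.1 * x + 0.2 * y + eta)
  # spread z so the lowest quarter is the whole constructed set
  cl <- PointCloud(rbind(pts, cbind(0.5, 0.5, 10 + runif(24))),
                   labels = rep(0L, n + 24))
  d <- stemDiameter(cl)
  X <- cbind(1, x, y)
  res <- pts[, 3] - X %*% qr.coef(qr(X), pts[, 3])
  expect_equal(d, 2 * median(abs(res)))
  expect_equal(d, 0.6, tolerance = 1e-6)
  flat <- PointCloud(cbind(runif(32), runif(32), 0), labels = rep(0L, 32))
  expect_warning(d0 <- stemDiameter(flat), "zero")
  expect_equal(d0, 0)
})

test_that("rank-deficient basal sets fall back to the mean plane", {
  set.seed(53)
  pts <- cbind(runif(40), 0, runif(40, 0, 0.1)) # collinear in xy
  cl <- PointCloud(rbind(pts, cbind(0, 0, 10 + runif(10))),
                   labels = rep(0L, 50))
  expect_warning(d <- stemDiameter(cl), "rank-deficient")
  expect_equal(d, 2 * median(abs(pts[, 3] - mean(pts[, 3]))))
})

test_that("leaf segmentation slices along the principal direction", {
  set.seed(54)
  ribbon <- cbind(runif(400, 0, 10), runif(400, -1, 1), 0)
  segs <- leafSegments(ribbon, 10)
  expect_length(segs, 10L)
  exts <- vapply(segs, function(i) diff(range(ribbon[i, 1])), numeric(1))
  expect_true(all(exts < 1.2))
  ords <- vapply(segs, function(i) mean(ribbon[i, 1]), numeric(1))
  expect_true(all(diff(ords) > 0) || all(diff(ords) < 0))
  expect_error(leafSegments(ribbon, 1), ">= 2")
  expect_error(leafSegments(ribbon[1:5, ], 10), "exceeds")
})

test_that("quarter-circle leaves keep segment ordering along the curve", {
  th <- seq(0, pi / 2, length.out = 500)
  arc <- cbind(10 * sin(th), runif(500, -1, 1), 10 * (1 - cos(th)))
  segs <- leafSegments(arc, 12)
  expect_length(segs, 12L)
  par <- vapply(segs, function(i) mean(th[i]), numeric(1))
  expect_true(all(diff(par) > 0) || all(diff(par) < 0))
})

test_that("segment width polylines follow arched cross-sections", {
  # flat segment: polyline length equals the transverse chord
  set.seed(55)
  flat <- cbind(runif(200, -0.2, 0.2), seq(-1.5, 1.5, length.out = 200), 0)
  w <- segmentWidthPolyline(flat, m_insert = 10)
  expect_equal(polylineLength(w), 3, tolerance = 0.05)
  expect_equal(polylineLength(segmentWidthPolyline(flat, m_insert = 0)), 3,
               tolerance = 0.05)
  # semicircular arch of radius 1: length approaches pi, above the chord 2
  phi <- seq(0, pi, length.out = 400)
  arch <- cbind(0, cos(phi), sin(phi))
  lens <- vapply(c(0, 5, 20, 60), function(m) {
    polylineLength(segmentWidthPolyline(arch, m_insert = m))
  }, numeric(1))
  expect_equal(lens[1], 2, tolerance = 0.01)
  expect_true(all(diff(lens) >= -1e-9)) # monotone in insertions
  expect_gt(lens[4], 2.9)
  expect_lt(lens[4], pi + 0.1)
})

test_that("leaf length polylines recover straight and curved ribbon lengths", {
  set.seed(56)
  straight <- cbind(runif(600, 0, 12), runif(600, -0.8, 0.8), 0)
  segs <- leafSegments(straight, 10)
  pl <- leafLengthPolyline(straight, segs)
  expect_equal(polylineLength(pl), 12, tolerance = 0.4)
  # quarter circle R = 10: arc length ~ 15.708 within 3% after smoothing
  th <- runif(4000, 0, pi / 2)
  arc <- cbind(10 * sin(th), runif(4000, -1, 1), 10 * (1 - cos(th)))
  segs2 <- leafSegments(arc, 15)
  pl2 <- gaussianSmoothPolyline(leafLengthPolyline(arc, segs2), 1.0,
                                anchor = TRUE)
  expect_equal(polylineLength(pl2), pi * 10 / 2, tolerance = 0.03)
  # two segments: ends plus two midpoints (no insertions)
  segs3 <- leafSegments(straight, 2)
  pl3 <- leafLengthPolyline(straight, segs3, m_insert = 0)
  expect_equal(nrow(pl3@vertices), 4L)
})

test_that("smoothing behaviour: identity at sigma 0, contraction of zig-zags", {
  zig <- cbind(seq(0, 10, length.out = 21), rep(c(0.3, -0.3), length.out = 21), 0)
  pl <- new("Polyline", vertices = zig, role = "length", smoothed = FALSE)
  expect_equal(gaussianSmoothPolyline(pl, 0)@vertices, zig)
  sm <- gaussianSmoothPolyline(pl, 1)
  expect_true(sm@smoothed)
  expect_lt(abs(polylineLength(sm) - 10), abs(polylineLength(pl) - 10))
  const <- new("Polyline", vertices = matrix(1, 5, 3), role = "length",
               smoothed = FALSE)
  expect_equal(gaussianSmoothPolyline(const, 2)@vertices, matrix(1, 5, 3))
})

test_that("R^2 and RMSE follow their definitions", {
  expect_equal(unname(r2Rmse(c(1, 2, 3), c(1, 2, 3))), c(1, 0))
  st <- r2Rmse(c(1, 2, 3), c(1, 2, 4))
  expect_equal(unname(st["rmse"]), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(unname(st["r2"]), 0.5, tolerance = 1e-12)
  v <- c(2, 4, 9)
  expect_equal(unname(r2Rmse(v, rep(mean(v), 3))["r2"]), 0)
  expect_error(r2Rmse(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("a two-leaf plant yields a two-leaf report", {
  out <- fixturePlant()
  rep <- extractTraits(out$cloud)
  expect_s4_class(rep, "TraitReport")
  expect_length(rep@leaves, 2L)
  df <- traitsAsDataFrame(rep, plant_id = 7L)
  expect_equal(nrow(df), 2L)
  expect_equal(df$plant_id, c(7L, 7L))
})

test_that("traits recover generator ground truth on a toy population", {
  ds <- makeToyDataset(20, seed = 57, points_per_organ = 512L)
  relErrH <- relErrL <- relErrW <- numeric(0)
  for (i in seq_along(ds$plants)) {
    pl <- ds$plants[[i]]
    rep <- extractTraits(pl$cloud)
    relErrH <- c(relErrH, abs(rep@stem_height - pl$traits$stem_height) /
                            pl$traits$stem_height)
    got <- sort(vapply(rep@leaves, `[[`, numeric(1), "length"))
    want <- sort(pl$traits$leaf_lengths)
    if (length(got) == length(want)) {
      relErrL <- c(relErrL, abs(got - want) / want)
      gw <- sort(vapply(rep@leaves, `[[`, numeric(1), "width"))
      ww <- sort(pl$traits$leaf_widths)
      relErrW <- c(relErrW, abs(gw - ww) / ww)
    }
  }
  expect_gte(length(relErrL) / 20, 0.8) # leaf instances found in most plants
  expect_lte(median(relErrH), 0.01)
  expect_lte(median(relErrL), 0.03)
  expect_lte(median(relErrW), 0.05)
})

test_that("trait extraction is rotation invariant and scale equivariant", {
  out <- fixturePlant(seed = 58)
  base <- extractTraits(out$cloud)
  ang <- c(0.4, -0.3, 1.1)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, 3)
  R <- Rx %*% Rz
  rot <- initialize(out$cloud, positions = positions(out$cloud) %*% t(R),
                    normals = normals(out$cloud) %*% t(R))
  rrep <- extractTraits(rot)
  expect_equal(rrep@stem_height, base@stem_height, tolerance = 0.01)
  expect_equal(sort(vapply(rrep@leaves, `[[`, numeric(1), "length")),
               sort(vapply(base@leaves, `[[`, numeric(1), "length")),
               tolerance = 0.01)
  sc <- initialize(out$cloud, positions = positions(out$cloud) * 2.5)
  srep <- extractTraits(sc)
  expect_equal(srep@stem_height, 2.5 * base@stem_height, tolerance = 0.01)
  expect_equal(srep@stem_diameter, 2.5 * base@stem_diameter, tolerance = 0.01)
  expect_equal(sort(vapply(srep@leaves, `[[`, numeric(1), "width")),
               2.5 * sort(vapply(base@leaves, `[[`, numeric(1), "width")),
               tolerance = 0.01)
})
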