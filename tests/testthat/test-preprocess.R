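# Otsu ground removal, statistical filtering, FPS, normals, normalization.

test_that("Otsu threshold separates a two-value histogram", {
  # 100 points with excess green 10, 100 with 200 (R = B = 0 so exg = 2G)
  g <- c(rep(5, 100), rep(100, 100))
  cl <- PointCloud(matrix(runif(600), ncol = 3),
                   colors = cbind(0, g, 0))
  ot <- otsuThreshold(2 * g)
  expect_gt(ot$threshold, 10)
  expect_lt(ot$threshold, 200)
  kept <- otsuGroundRemoval(cl)
  expect_equal(nPoints(kept), 100L)
  expect_true(all(pointColors(kept)[, 2] == 100))
})

test_that("Otsu bin choice matches the exhaustive between-class-variance search", {
  set.seed(8)
  for (rep in 1:5) {
    x <- c(rnorm(200, 50, 12), rnorm(300, 180, 20))
    expect_equal(otsuThreshold(x)$bin, oracleOtsu(x))
  }
})

test_that("a degenerate colour histogram leaves the cloud unchanged", {
  cl <- PointCloud(matrix(runif(30), ncol = 3),
                   colors = matrix(100, 10, 3))
  expect_warning(out <- otsuGroundRemoval(cl), "degenerate")
  expect_equal(nPoints(out), 10L)
  expect_error(otsuGroundRemoval(randomCloud(5)), "colour")
})

test_that("Otsu on excess green strips the ground disk from a plant scene", {
  out <- generatePlant(plantSpec(points_per_organ = 400L, seed = 5),
                       ground = TRUE)
  kept <- otsuGroundRemoval(out$cloud)
  expect_setequal(unique(pointLabels(kept)), c(0L, 1L))
  expect_equal(nPoints(kept), sum(pointLabels(out$cloud) != 2L))
})

test_that("statistical filtering removes exactly an isolated far point", {
  set.seed(10)
  pos <- rbind(matrix(runif(300), ncol = 3), c(100, 100, 100))
  cl <- PointCloud(pos, labels = c(rep(0L, 100), 1L))
  kept <- statisticalOutlierRemoval(cl, k = 8, alpha = 2)
  expect_equal(nPoints(kept), 100L)
  expect_false(1L %in% pointLabels(kept))
  # oracle agreement: survivors are those below mean + 2 sd of mean k-NN dist
  md <- oracleMeanKnnDist(pos, 8)
  expect_equal(which(md <= mean(md) + 2 * sd(md)), seq_len(100))
})

test_that("an infinite alpha never removes points; identical clusters shed symmetrically", {
  cl <- randomCloud(60, seed = 3)
  expect_equal(nPoints(statisticalOutlierRemoval(cl, k = 5, alpha = Inf)), 60L)
  set.seed(4)
  base <- matrix(runif(150), ncol = 3)
  two <- rbind(base, sweep(base, 2, c(10, 0, 0), `+`))
  cl2 <- PointCloud(two, labels = rep(c(0L, 1L), each = 50))
  kept <- statisticalOutlierRemoval(cl2, k = 6, alpha = 1)
  expect_equal(sum(pointLabels(kept) == 0L), sum(pointLabels(kept) == 1L))
  expect_error(statisticalOutlierRemoval(cl, k = 60), "smaller")
})

test_that("FPS greedily maximizes the min distance", {
  pos <- cbind(c(0, 1, 2, 10), 0, 0)
  sel <- farthestPointSampling(pos, 2, start = 1)
  expect_equal(sort(sel), c(1L, 4L))
  expect_equal(sort(farthestPointSampling(pos, 4, start = 1)), 1:4)
  expect_error(farthestPointSampling(pos, 5), "exceed")
})

test_that("FPS equals the exhaustive max-min oracle on small clouds", {
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(5:64, 1)
    pos <- matrix(runif(3 * n), ncol = 3)
    m <- sample(2:n, 1)
    start <- sample(n, 1)
    expect_equal(farthestPointSampling(pos, m, start = start),
                 oracleFps(pos, m, start))
  }
})

test_that("FPS spreads points better than random subsets", {
  set.seed(7)
  pos <- matrix(runif(3 * 512), ncol = 3)
  minPairDist <- function(idx) {
    d <- as.matrix(dist(pos[idx, ]))
    diag(d) <- Inf
    min(d)
  }
  fpsScore <- minPairDist(farthestPointSampling(pos, 128))
  for (t in 1:20) {
    expect_gte(fpsScore, minPairDist(sample(512, 128)))
  }
})

test_that("normal estimation recovers plane and sphere normals", {
  set.seed(9)
  plane <- PointCloud(cbind(runif(80), runif(80), 0))
  est <- estimateNormals(plane, k = 8)
  expect_equal(normals(est), matrix(rep(c(0, 0, 1), each = 80), ncol = 3),
               tolerance = 1e-9)
  th <- acos(runif(400, -1, 1)); ph <- runif(400, 0, 2 * pi)
  sp <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  est2 <- estimateNormals(PointCloud(sp), k = 16)
  ang <- acos(pmin(1, abs(rowSums(normals(est2) * sp)))) * 180 / pi
  expect_lt(mean(ang), 10)
})

test_that("collinear neighbourhoods fall back to (0,0,1) with a warning", {
  line <- PointCloud(cbind(seq_len(10), 0, 0))
  expect_warning(est <- estimateNormals(line, k = 4), "degenerate")
  expect_equal(normals(est)[1, ], c(0, 0, 1))
})

test_that("centre/normalize is exactly invertible and unit-bounded", {
  cl <- fixturePlant()$cloud
  cn <- centerNormalize(cl)
  expect_equal(max(sqrt(rowSums(positions(cn$cloud)^2))), 1)
  back <- denormalize(cn$cloud, cn$transform)
  expect_equal(positions(back), positions(cl), tolerance = 1e-9)
  single <- PointCloud(matrix(c(3, 4, 5), 1, 3))
  expect_warning(cns <- centerNormalize(single), "coincident")
  expect_equal(positions(cns$cloud), matrix(0, 1, 3))
})

test_that("preprocessing keeps per-point channels aligned", {
  out <- generatePlant(plantSpec(points_per_organ = 200L, seed = 12),
                       ground = TRUE)
  cl <- out$cloud
  key <- function(c) paste(round(positions(c), 6)[, 1], pointLabels(c))
  ref <- setNames(pointLabels(cl), key(cl))
  for (op in list(function(c) otsuGroundRemoval(c),
                  function(c) statisticalOutlierRemoval(c, 8, 2),
                  function(c) c[farthestPointSampling(c, 150)])) {
    res <- op(cl)
    expect_identical(unname(ref[key(res)]), pointLabels(res))
  }
})

test_that("the default pipeline retains nearly all plant points", {
  out <- generatePlant(plantSpec(points_per_organ = 400L, seed = 13),
                       ground = TRUE)
  cl <- otsuGroundRemoval(out$cloud)
  cl <- statisticalOutlierRemoval(cl)
  cl <- cl[farthestPointSampling(cl, min(800L, nPoints(cl)))]
  nPlant <- sum(pointLabels(out$cloud) != 2L)
  retained <- sum(pointLabels(cl) != 2L)
  expect_gte(retained / min(nPlant, 800L), 0.99)
  expect_equal(sum(pointLabels(cl) == 2L), 0L)
})
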