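# Independent oracles used across the suite.  Each is a deliberately naive
# re-derivation (nested loops, exhaustive search) kept separate from the
# package's implementation paths.

# nested-loop volume rendering weights: w_i = prod_{j<i}(1 - a_j) * a_i
oracleRenderWeights <- function(sigma, delta) {
  M <- length(sigma)
  a <- 1 - exp(-sigma * delta)
  w <- numeric(M)
  for (i in seq_len(M)) {
    Ti <- 1
    if (i > 1) for (j in 1:(i - 1)) Ti <- Ti * (1 - a[j])
    w[i] <- Ti * a[i]
  }
  w
}

# exhaustive greedy max-min selection (recomputes all distances each pick)
oracleFps <- function(pos, m, start) {
  n <- nrow(pos)
  sel <- start
  while (length(sel) < m) {
    best <- -1; bi <- 0L
    for (i in seq_len(n)) {
      if (i %in% sel) next
      dmin <- Inf
      for (s in sel) dmin <- min(dmin, sum((pos[i, ] - pos[s, ])^2))
      if (dmin > best) { best <- dmin; bi <- i }
    }
    sel <- c(sel, bi)
  }
  sel
}

# exhaustive 256-bin Otsu: maximize between-class variance over thresholds
oracleOtsu <- function(x) {
  lo <- min(x); hi <- max(x)
  bins <- pmin(floor((x - lo) / (hi - lo) * 256), 255)
  best <- -Inf; bestK <- NA
  for (k in 0:254) {
    g0 <- bins <= k; g1 <- !g0
    if (!any(g0) || !any(g1)) next
    w0 <- mean(g0); w1 <- mean(g1)
    sb <- w0 * w1 * (mean(bins[g0]) - mean(bins[g1]))^2
    if (sb > best) { best <- sb; bestK <- k }
  }
  bestK
}

# brute-force mean k-NN distance per point
oracleMeanKnnDist <- function(pos, k) {
  n <- nrow(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(pos[-i, , drop = FALSE]) - pos[i, ])^2))
    out[i] <- mean(sort(d)[seq_len(k)])
  }
  out
}

# contingency-table metrics from first principles
oracleMetrics <- function(tp, fp, fn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  iou <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
  c(iou = iou, prec = prec, rec = rec, f1 = f1)
}

# quadrature arc length of an arc-of-circle centerline
oracleArcLength <- function(R, sweep_deg) {
  th <- sweep_deg * pi / 180
  f <- function(t) rep(R * th, length(t)) # |d pos / d t| with t in [0,1]
  stats::integrate(f, 0, 1)$value
}

# a small labelled random cloud
randomCloud <- function(n, seed = 1, labels = TRUE) {
  set.seed(seed)
  PointCloud(matrix(runif(3 * n, -1, 1), ncol = 3),
             labels = if (labels) sample(0:1, n, replace = TRUE))
}

# one deterministic small plant shared across tests
fixturePlant <- function(seed = 11, ...) {
  generatePlant(plantSpec(
    stem_radius = 1, stem_length = 50, stem_tilt_deg = 10,
    leaves = list(
      leafSpec(attach_height_frac = 0.5, azimuth_deg = 20, R = 40,
               sweep_deg = 80, max_width = 7, taper = "sine"),
      leafSpec(attach_height_frac = 0.8, azimuth_deg = 200, R = 35,
               sweep_deg = 70, max_width = 6, taper = "sine")),
    points_per_organ = 512L, seed = seed, ...))
}
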