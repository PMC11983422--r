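# Network architecture: neighbourhood ops, module properties, budgets.

miniModel <- function(seed = 1, ...) {
  cfg <- modelConfig(stem_width = 8L, stage_widths = c(8L, 16L, 16L, 16L),
                     decoder_widths = c(16L, 16L, 8L, 8L), head_hidden = 8L,
                     local_k = 6L, eafp_k = 4L, npoints = 64L, cam_rank = 2L,
                     ...)
  initPointSegNet(cfg, seed = seed)
}

test_that("ball query equals brute-force distance sort with radius mask", {
  set.seed(31)
  for (rep in 1:6) {
    pts <- matrix(runif(64 * 3), ncol = 3)
    ctr <- pts[sample(64, 10), , drop = FALSE]
    k <- sample(2:6, 1); radius <- runif(1, 0.1, 0.6)
    got <- ballQueryKnn(ctr, pts, k, radius)
    for (i in seq_len(nrow(ctr))) {
      d <- sqrt(colSums((t(pts) - ctr[i, ])^2))
      ord <- order(d)
      within <- ord[d[ord] <= radius][seq_len(k)]
      within <- within[!is.na(within)]
      if (!length(within)) within <- ord[1]
      exp_idx <- c(within, rep(within[1], k - length(within)))
      expect_equal(got[i, ], exp_idx)
    }
  }
})

test_that("an isolated centre is padded with its own index", {
  pts <- rbind(c(0, 0, 0), c(10, 10, 10), c(10.1, 10, 10))
  got <- ballQueryKnn(pts[1, , drop = FALSE], pts, k = 3, radius = 0.5)
  expect_equal(got[1, ], c(1L, 1L, 1L))
})

test_that("the local block pools symmetrically and honours the residual path", {
  model <- miniModel()
  set.seed(32)
  pos <- matrix(runif(60), ncol = 3)
  feats <- matrix(rnorm(20 * 8), ncol = 8)
  out <- resmlpBlock(model, 1, pos, feats)
  expect_equal(dim(out), c(20L, 8L))              # stage width contract
  # permuting the points permutes the output rows identically
  perm <- sample(20)
  out2 <- resmlpBlock(model, 1, pos[perm, ], feats[perm, ], centerIdx = order(perm))
  expect_equal(out2, out, tolerance = 1e-12)
  # zeroed MLP weights leave only the (relu of the) shortcut projection
  m0 <- model
  for (nm in c("enc1.l1.W", "enc1.l1.b", "enc1.l2.W", "enc1.l2.b")) {
    m0$params[[nm]][] <- 0
  }
  sc <- feats %*% m0$params[["enc1.sc.W"]]
  sc <- sweep(sc, 2, as.numeric(m0$params[["enc1.sc.b"]]), `+`)
  expect_equal(resmlpBlock(m0, 1, pos, feats), pmax(sc, 0), tolerance = 1e-12)
})

test_that("relative spatial attention is permutation equivariant and bounded", {
  model <- miniModel()
  set.seed(33)
  pos <- matrix(runif(45), ncol = 3)
  feats <- matrix(rnorm(15 * 8), ncol = 8)
  out <- rsaAttention(model, 1, pos, feats)
  perm <- sample(15)
  expect_equal(rsaAttention(model, 1, pos[perm, ], feats[perm, ]),
               out[perm, ], tolerance = 1e-12)
  one <- rsaAttention(model, 1, pos[1, , drop = FALSE],
                      feats[1, , drop = FALSE])
  # single point: both deviations are exactly zero, so attention input is 0
  W <- model$params[["enc1.rsa.a.W"]]
  b <- model$params[["enc1.rsa.a.b"]]
  att <- 1 / (1 + exp(-(matrix(0, 1, nrow(W)) %*% W +
                        matrix(b, 1, ncol(W)))))
  expect_true(all(att > 0 & att < 1))
  ref <- pmax(sweep((feats[1, , drop = FALSE] * att) %*%
                    model$params[["enc1.rsa.b.W"]], 2,
                    as.numeric(model$params[["enc1.rsa.b.b"]]), `+`), 0)
  expect_equal(one, ref, tolerance = 1e-12)
})

test_that("channel attention gates within (1, 2) x features and pools globally", {
  model <- miniModel()
  set.seed(34)
  feats <- matrix(abs(rnorm(30 * 8)), ncol = 8)
  out <- camSe(model, 1, feats)
  expect_true(all(out >= feats - 1e-12))
  expect_true(all(out <= 2 * feats + 1e-12))
  perm <- sample(30)
  expect_equal(camSe(model, 1, feats[perm, ]), out[perm, ], tolerance = 1e-12)
  # constant channels: the sd statistic collapses to sqrt(eps)
  cf <- matrix(rep(1:8, each = 5), ncol = 8)
  expect_equal(dim(camSe(model, 1, cf)), dim(cf))
})

test_that("feature interpolation is an inverse-distance convex combination", {
  coarse <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 2, 0))
  cf <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), ncol = 2)
  hit <- interpolateFeatures(coarse, cf, coarse[2, , drop = FALSE])
  expect_equal(hit, cf[2, , drop = FALSE], tolerance = 1e-6)
  const <- matrix(5, 4, 2)
  anywhere <- interpolateFeatures(coarse, const,
                                  matrix(runif(9), ncol = 3))
  expect_equal(anywhere, matrix(5, 3, 2), tolerance = 1e-9)
  mid <- interpolateFeatures(coarse[1:2, ], cf[1:2, , drop = FALSE],
                             matrix(c(0.5, 0, 0), 1))
  expect_equal(mid, (cf[1, , drop = FALSE] + cf[2, , drop = FALSE]) / 2,
               tolerance = 1e-6)
})

test_that("encoder stages halve the point count; four stages reach N/16", {
  model <- miniModel()
  set.seed(35)
  n <- 64
  pos <- matrix(runif(n * 3, -1, 1), ncol = 3)
  st <- glsaStage(model, 1, pos, matrix(rnorm(n * 8), ncol = 8))
  expect_equal(nrow(st$positions), 32L)
  expect_equal(ncol(st$features), 8L)
  fw <- pointSegNetForward(model, pos, cbind(pos, pos))
  expect_equal(dim(fw$scores$val), c(64L, 2L))
  cfg2 <- modelConfig(npoints = 2048L)
  sizes <- c(2048)
  for (s in 1:4) sizes <- c(sizes, ceiling(tail(sizes, 1) * cfg2$fps_rate))
  expect_equal(sizes, c(2048, 1024, 512, 256, 128))
})

test_that("ablation switches alter the wiring as advertised", {
  mLocal <- miniModel(ablation = list(rsa = FALSE))
  set.seed(36)
  pos <- matrix(runif(60), ncol = 3)
  feats <- matrix(rnorm(20 * 8), ncol = 8)
  st <- glsaStage(mLocal, 1, pos, feats)
  local <- resmlpBlock(mLocal, 1, pos, feats,
                       centerIdx = farthestPointSampling(pos, 10))
  # without the global branch (and cam-se off) the stage is the local branch
  mBoth <- miniModel(ablation = list(rsa = FALSE, cam_se = FALSE))
  mBoth$params <- mLocal$params[names(mBoth$params)]
  st2 <- glsaStage(mBoth, 1, pos, feats)
  expect_equal(st2$features, local, tolerance = 1e-12)
})

test_that("EAFP edge term vanishes on constant fields and acts locally", {
  model <- miniModel()
  set.seed(37)
  coarsePos <- matrix(runif(24), ncol = 3)
  skipPos <- matrix(runif(48), ncol = 3)
  cf <- matrix(1.5, 8, 8)   # decoder stage 4: coarse width 8, skip width 8
  sf <- matrix(0.5, 16, 8)
  out <- eafpStage(model, 4, coarsePos, cf, skipPos, sf)
  expect_equal(dim(out), c(16L, 8L))
  # constant input field -> constant output (edge features are all zero)
  expect_true(all(abs(sweep(out, 2, out[1, ])) < 1e-9))
  # permutation equivariance over skip points
  sf2 <- matrix(rnorm(16 * 8), ncol = 8)
  o1 <- eafpStage(model, 4, coarsePos, cf, skipPos, sf2)
  perm <- sample(16)
  o2 <- eafpStage(model, 4, coarsePos, cf, skipPos[perm, ], sf2[perm, ])
  expect_equal(o2, o1[perm, ], tolerance = 1e-10)
})

test_that("an outlier feature perturbs only its KNN neighbourhood", {
  model <- miniModel()
  # a line of points: neighbourhoods are index-local
  n <- 40
  skipPos <- cbind(seq_len(n) / n, 0, 0)
  coarsePos <- skipPos[seq(1, n, by = 2), ]
  cf <- matrix(0, nrow(coarsePos), 8)
  sf <- matrix(1, n, 8)
  base <- eafpStage(model, 4, coarsePos, cf, skipPos, sf)
  sf2 <- sf
  sf2[1, ] <- 25
  pert <- eafpStage(model, 4, coarsePos, cf, skipPos, sf2)
  delta <- rowSums(abs(pert - base))
  expect_gt(max(delta[1:4]), 0)
  expect_equal(delta[(model$config$eafp_k + 2):n], rep(0, n - model$config$eafp_k - 1),
               tolerance = 1e-10)
})

test_that("the full forward is permutation equivariant and finite", {
  model <- miniModel()
  set.seed(38)
  n <- 64
  pos <- matrix(runif(n * 3, -1, 1), ncol = 3)
  feats <- cbind(pos, matrix(rnorm(n * 3), ncol = 3))
  s1 <- pointSegNetForward(model, pos, feats)$scores$val
  perm <- sample(n)
  s2 <- pointSegNetForward(model, pos[perm, ], feats[perm, ])$scores$val
  expect_equal(s2, s1[perm, ], tolerance = 1e-9)
  expect_true(all(is.finite(s1)))
  expect_error(pointSegNetForward(model, pos, feats[, 1:4]), "channels")
})

test_that("every stage stays finite across many random inputs", {
  model <- miniModel()
  for (seed in 1:40) {
    set.seed(seed)
    n <- 48
    pos <- matrix(runif(n * 3, -1, 1), ncol = 3)
    feats <- cbind(pos, matrix(runif(n * 3, -1, 1), ncol = 3))
    sc <- pointSegNetForward(model, pos, feats)$scores$val
    expect_true(all(is.finite(sc)))
  }
})

test_that("one optimizer step moves the gate and every named module", {
  model <- miniModel()
  set.seed(39)
  n <- 64
  pos <- matrix(runif(n * 3, -1, 1), ncol = 3)
  feats <- cbind(pos, matrix(rnorm(n * 3), ncol = 3))
  lab <- sample(0:1, n, replace = TRUE)
  fw <- pointSegNetForward(model, pos, feats)
  stemleaf3d:::agBackward(polyFocalLoss(fw$scores, lab))
  grads <- lapply(fw$leaves, function(l) if (is.null(l$grad)) 0 else l$grad)
  st <- stemleaf3d:::adamwInit(model$params)
  upd <- stemleaf3d:::adamwStep(model$params, grads, st, lr = 1e-3,
                                weight_decay = 1e-4)
  moved <- vapply(names(model$params), function(nm) {
    any(upd$params[[nm]] != model$params[[nm]])
  }, logical(1))
  modules <- unique(sub("\\.[^.]+(\\.[^.]+)?$", "", names(model$params)))
  for (mod in c("stem", paste0("enc", 1:4), paste0("dec", 1:4), "head")) {
    expect_true(any(moved[grep(paste0("^", mod, "\\."), names(moved))]),
                label = paste("module", mod, "updated"))
  }
  for (s in 1:4) {
    expect_true(moved[[sprintf("enc%d.gate", s)]],
                label = sprintf("fusion gate %d updated", s))
  }
})

test_that("parameter and FLOP counts respect the reference budgets", {
  cfg <- referenceConfig()
  expect_equal(countParameters(cfg) / 1e6, 1.33, tolerance = 0.01)
  expect_equal(countFlops(cfg) / 1e9, 4.73, tolerance = 0.05)
  noRsa <- modelConfig(ablation = list(rsa = FALSE))
  expect_equal(countParameters(noRsa) / 1e6, 1.068, tolerance = 0.03)
  # quadratic growth in width
  wide <- modelConfig(stem_width = 64L, stage_widths = c(128L, 256L, 512L, 1024L),
                      decoder_widths = c(256L, 256L, 128L, 128L),
                      head_hidden = 256L)
  ratio <- countParameters(wide) / countParameters(referenceConfig())
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.3)
  # FLOPs scale linearly in the point count and drop without the ResMLP
  f1 <- countFlops(cfg, 2048)
  f2 <- countFlops(cfg, 4096)
  expect_equal(f2 / f1, 2, tolerance = 0.02)
  expect_lt(countFlops(modelConfig(ablation = list(resmlp = FALSE))), f1)
})

test_that("ablation variants order their parameter counts as published", {
  counts <- c(
    full = countParameters(modelConfig()),
    no_cam = countParameters(modelConfig(ablation = list(cam_se = FALSE))),
    no_eafp = countParameters(modelConfig(ablation = list(eafp = FALSE))),
    no_resmlp = countParameters(modelConfig(ablation = list(resmlp = FALSE))),
    no_rsa = countParameters(modelConfig(ablation = list(rsa = FALSE))),
    no_rsa_eafp = countParameters(modelConfig(ablation = list(rsa = FALSE,
                                                              eafp = FALSE))))
  expect_true(all(diff(counts) < 0))
})
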