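# The lightweight encoder-decoder point-cloud segmentation network.
#
# Encoder: four global-local set-abstraction (GLSA) stages, each = FPS
# downsampling (rate 0.5) -> parallel local branch (ResMLP: grouped
# expansion layer over a ball-query neighbourhood, max-pool, per-point
# layer, projected residual) and global branch (relative spatial attention,
# RSA) -> fusion by a learnable scalar gate -> channel attention with
# pooled mean/sd statistics (CAM-SE).
# Decoder: four edge-aware feature propagation (EAFP) stages, each =
# inverse-distance interpolation, skip concatenation, ResMLP over KNN
# neighbourhoods, KNN edge features (subtract, ReLU, mean), final MLP.
# Head: two MLP layers to per-point class scores.

#' Model configuration
#'
#' @param in_channels input feature channels (default 6: xyz + normals).
#' @param num_classes organ classes.
#' @param stem_width width of the stem MLP.
#' @param stage_widths encoder stage output widths (4 values).
#' @param decoder_widths decoder stage output widths (4 values).
#' @param head_hidden hidden width of the segmentation head.
#' @param fps_rate encoder downsampling rate (0.5).
#' @param local_k ball-query neighbour count in the encoder.
#' @param eafp_k KNN neighbour count in the decoder.
#' @param ball_radius base ball-query radius on the normalized cloud;
#'   doubles at each stage.
#' @param npoints nominal input point count.
#' @param cam_rank rank of the CAM-SE statistic mixing matrix.
#' @param ablation named logical list with entries `rsa`, `cam_se`, `eafp`,
#'   `resmlp`; switching one off reproduces the corresponding ablation
#'   variant.
#' @return a `ModelConfig` list.
#' @export
modelConfig <- function(in_channels = 6L, num_classes = 2L,
                        stem_width = 32L,
                        stage_widths = c(64L, 128L, 256L, 512L),
                        decoder_widths = c(128L, 128L, 64L, 64L),
                        head_hidden = 128L,
                        fps_rate = 0.5, local_k = 32L, eafp_k = 16L,
                        ball_radius = 0.1, npoints = 2048L,
                        cam_rank = 8L,
                        ablation = list(rsa = TRUE, cam_se = TRUE,
                                        eafp = TRUE, resmlp = TRUE)) {
  stopifnot(fps_rate > 0, fps_rate <= 1, eafp_k >= 1, local_k >= 1,
            length(stage_widths) == 4, length(decoder_widths) == 4,
            all(stage_widths > 0), all(decoder_widths > 0))
  abl <- list(rsa = TRUE, cam_se = TRUE, eafp = TRUE, resmlp = TRUE)
  abl[names(ablation)] <- ablation
  structure(list(
    in_channels = as.integer(in_channels), num_classes = as.integer(num_classes),
    stem_width = as.integer(stem_width),
    stage_widths = as.integer(stage_widths),
    decoder_widths = as.integer(decoder_widths),
    head_hidden = as.integer(head_hidden),
    fps_rate = fps_rate, local_k = as.integer(local_k),
    eafp_k = as.integer(eafp_k), ball_radius = ball_radius,
    npoints = as.integer(npoints), cam_rank = as.integer(cam_rank),
    ablation = abl), class = "ModelConfig")
}

#' The frozen reference configuration
#'
#' Reads `inst/extdata/reference.yaml`: the configuration whose instantiation
#' meets the published parameter (1.33 M) and compute (4.73 G) budgets.
#'
#' @return a `ModelConfig`.
#' @export
referenceConfig <- function() {
  path <- system.file("extdata", "reference.yaml", package = "stemleaf3d")
  y <- yaml::read_yaml(path)
  modelConfig(
    in_channels = y$in_channels, num_classes = y$num_classes,
    stem_width = y$stem_width, stage_widths = unlist(y$stage_widths),
    decoder_widths = unlist(y$decoder_widths), head_hidden = y$head_hidden,
    fps_rate = y$fps_rate, local_k = y$local_k, eafp_k = y$eafp_k,
    ball_radius = y$ball_radius, npoints = y$npoints, cam_rank = y$cam_rank)
}

#' A small configuration for desk-scale training
#'
#' Quarter-width everything, 256-point inputs, reduced neighbourhoods.
#'
#' @param num_classes organ classes.
#' @return a `ModelConfig`.
#' @export
tinyConfig <- function(num_classes = 2L) {
  modelConfig(
    num_classes = num_classes, stem_width = 8L,
    stage_widths = c(16L, 32L, 64L, 128L),
    decoder_widths = c(32L, 32L, 16L, 16L),
    head_hidden = 32L, local_k = 16L, eafp_k = 8L,
    npoints = 256L, cam_rank = 4L)
}

# encoder stage input widths: stem, then the previous stage outputs
encInWidths <- function(cfg) c(cfg$stem_width, cfg$stage_widths[-4])

# decoder stage d: coarse feature width, skip feature width
decIO <- function(cfg) {
  skipW <- c(cfg$stage_widths[3:1], cfg$stem_width)
  coarseW <- c(cfg$stage_widths[4], cfg$decoder_widths[-4])
  list(coarse = coarseW, skip = skipW, out = cfg$decoder_widths)
}

heNorm <- function(nin, nout, gain = 2) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(gain / nin)), nin, nout)
}

#' Initialize network parameters
#'
#' @param config a [modelConfig()].
#' @param seed integer seed for the weight draws.
#' @return a model: `list(params, config)`, with `params` a named list of
#'   matrices (the learnable arrays).
#' @export
initPointSegNet <- function(config, seed = 1L) {
  set.seed(seed)
  p <- list()
  lin <- function(name, nin, nout, gain = 2) {
    p[[paste0(name, ".W")]] <<- heNorm(nin, nout, gain)
    p[[paste0(name, ".b")]] <<- matrix(0, 1, nout)
  }
  sw <- config$stem_width
  lin("stem.l1", config$in_channels, sw)
  lin("stem.l2", sw, sw)
  cin <- encInWidths(config)
  for (s in 1:4) {
    C <- config$stage_widths[s]; Ci <- cin[s]
    pre <- sprintf("enc%d", s)
    lin(paste0(pre, ".l1"), Ci + 3L, C)
    lin(paste0(pre, ".l2"), C, C)
    if (config$ablation$resmlp) lin(paste0(pre, ".sc"), Ci, C)
    if (config$ablation$rsa) {
      lin(paste0(pre, ".rsa.a"), 3L + Ci, Ci, gain = 1)
      lin(paste0(pre, ".rsa.b"), Ci, C)
      p[[paste0(pre, ".gate")]] <- matrix(0, 1, 1)
    }
    if (config$ablation$cam_se) {
      r <- config$cam_rank
      lin(paste0(pre, ".cam.l1"), 2L * C, r, gain = 1)
      lin(paste0(pre, ".cam.l2"), r, C, gain = 1)
      p[[paste0(pre, ".cam.gamma")]] <- matrix(1, 1, C)
      p[[paste0(pre, ".cam.beta")]] <- matrix(0, 1, C)
    }
  }
  io <- decIO(config)
  for (d in 1:4) {
    Ci <- io$coarse[d] + io$skip[d]; Co <- io$out[d]
    pre <- sprintf("dec%d", d)
    lin(paste0(pre, ".l1"), Ci, Co)
    lin(paste0(pre, ".l2"), Co, Co)
    if (config$ablation$eafp) {
      lin(paste0(pre, ".sc"), io$skip[d], Co)
      lin(paste0(pre, ".edge"), 2L * Co, Co)
    }
  }
  lin("head.l1", config$decoder_widths[4], config$head_hidden)
  lin("head.l2", config$head_hidden, config$num_classes, gain = 1)
  list(params = p, config = config)
}

#' Count learnable parameters
#'
#' Sums the element counts of every learnable array of the instantiated
#' network.
#'
#' @param config a [modelConfig()] (or a model from [initPointSegNet()]).
#' @return integer parameter count.
#' @export
countParameters <- function(config) {
  model <- if (!is.null(config$params)) config else initPointSegNet(config)
  sum(vapply(model$params, length, numeric(1)))
}

#' Analytic FLOP count of one forward pass
#'
#' Walks the network's layers symbolically at input size `n_points`,
#' counting each multiply-accumulate of the dense layers as two operations
#' (bias additions and activations are not counted; the cheap elementwise
#' edge operations of the decoder are counted at one operation each).
#'
#' @param config a [modelConfig()].
#' @param n_points input point count (default: the config's).
#' @return FLOP count (numeric, in raw operations; divide by 1e9 for G).
#' @export
countFlops <- function(config, n_points = config$npoints) {
  fl <- 0
  mac <- function(rows, nin, nout) 2 * rows * nin * nout
  N <- n_points
  sw <- config$stem_width
  fl <- fl + mac(N, config$in_channels, sw) + mac(N, sw, sw)
  cin <- encInWidths(config)
  sizes <- integer(4)
  n <- N
  for (s in 1:4) {
    n <- ceiling(n * config$fps_rate)
    sizes[s] <- n
    C <- config$stage_widths[s]; Ci <- cin[s]
    fl <- fl + mac(n * config$local_k, Ci + 3, C)  # grouped expansion
    fl <- fl + mac(n, C, C)                        # post-pool layer
    if (config$ablation$resmlp) fl <- fl + mac(n, Ci, C)
    if (config$ablation$rsa) {
      fl <- fl + mac(n, 3 + Ci, Ci) + mac(n, Ci, C) + n * Ci # attn mul
    }
    if (config$ablation$cam_se) {
      r <- config$cam_rank
      fl <- fl + mac(1, 2 * C, r) + mac(1, r, C) + 2 * n * C # gate apply
    }
  }
  io <- decIO(config)
  fine <- c(sizes[3:1], N)
  for (d in 1:4) {
    Ci <- io$coarse[d] + io$skip[d]; Co <- io$out[d]; nf <- fine[d]
    fl <- fl + 2 * nf * 3 * io$coarse[d]           # 3-NN interpolation
    if (config$ablation$eafp) {
      fl <- fl + mac(nf * config$eafp_k, Ci, Co)   # grouped expansion
      fl <- fl + mac(nf, Co, Co)
      fl <- fl + mac(nf, io$skip[d], Co)           # skip shortcut
      fl <- fl + 2 * nf * config$eafp_k * Co       # edge subtract + mean
      fl <- fl + mac(nf, 2 * Co, Co)               # edge MLP
    } else {
      fl <- fl + mac(nf, Ci, Co) + mac(nf, Co, Co)
    }
  }
  fl <- fl + mac(N, config$decoder_widths[4], config$head_hidden)
  fl <- fl + mac(N, config$head_hidden, config$num_classes)
  fl
}

#' Ball query capped at the k nearest points
#'
#' For each centre, the `k` nearest points within `radius` (distance-sorted,
#' ties to the lowest index); a shortfall is padded by repeating the nearest
#' found (the centre itself when the centre belongs to `points`).
#'
#' @param centers `m x 3` query centres.
#' @param points `n x 3` reference points.
#' @param k neighbour count.
#' @param radius ball radius.
#' @return `m x k` integer index matrix into `points`.
#' @export
ballQueryKnn <- function(centers, points, k, radius) {
  .cppBallKnn(centers, points, as.integer(k), radius)
}

# inverse-distance-weighted 3-NN interpolation weights
interpWeights <- function(finePos, coarsePos) {
  k <- min(3L, nrow(coarsePos))
  idx <- knnIndices(coarsePos, finePos, k)
  if (k == 1L) idx <- matrix(idx, ncol = 1)
  d <- sqrt(pmax(matrix(
    pairwiseSqDist(finePos, coarsePos)[cbind(rep(seq_len(nrow(finePos)), k),
                                             as.vector(idx))],
    ncol = k), 0))
  w <- 1 / (d + 1e-8)
  w <- w / rowSums(w)
  list(idx = idx, w = w)
}

# shared dense layer application on the tape
agLinear <- function(x, params, leaves, name, act = "relu") {
  out <- agAddBias(agMatmul(x, leaves[[paste0(name, ".W")]]),
                   leaves[[paste0(name, ".b")]])
  switch(act, relu = agRelu(out), sigmoid = agSigmoid(out), none = out)
}

# --- tape-level stage bodies (single implementation, shared by the full
# forward pass and the exported module wrappers) -------------------------

# local branch: ball-query grouping, grouped expansion layer, max-pool,
# per-point layer, projected residual (when enabled)
.resmlpNode <- function(model, leaves, pre, p, fNode, pC, fCNode, k, radius,
                        resmlp = TRUE) {
  nOut <- nrow(pC)
  nb <- ballQueryKnn(pC, p, k, radius)
  flat <- as.vector(nb) # column-major: group i strided over rows i, i+m, ...
  rel <- p[flat, , drop = FALSE] - pC[rep(seq_len(nOut), k), ]
  gin <- agCbind(agGather(fNode, flat), agConst(rel))
  h <- agLinear(gin, model$params, leaves, paste0(pre, ".l1"))
  pooled <- agGroupMax(h, k)
  h2 <- agLinear(pooled, model$params, leaves, paste0(pre, ".l2"), act = "none")
  if (resmlp) {
    agRelu(agAdd(h2, agLinear(fCNode, model$params, leaves,
                              paste0(pre, ".sc"), act = "none")))
  } else agRelu(h2)
}

# global branch: relative spatial attention over the downsampled set
.rsaNode <- function(model, leaves, pre, pC, fCNode) {
  Prel <- sweep(pC, 2, colMeans(pC))
  Frel <- agSubRow(fCNode, agColMeans(fCNode))
  att <- agLinear(agCbind(agConst(Prel), Frel), model$params, leaves,
                  paste0(pre, ".rsa.a"), act = "sigmoid")
  agLinear(agMul(fCNode, att), model$params, leaves, paste0(pre, ".rsa.b"))
}

# channel attention from pooled per-channel mean/sd statistics
.camSeNode <- function(model, leaves, pre, fNode) {
  u <- agColMeans(fNode)
  cen <- agSubRow(fNode, u)
  sdv <- agSqrt(agAddScalar(agColMeans(agMul(cen, cen)), 1e-5))
  z <- agLinear(agCbind(u, sdv), model$params, leaves, paste0(pre, ".cam.l1"))
  z <- agLinear(z, model$params, leaves, paste0(pre, ".cam.l2"), act = "none")
  z <- agAdd(agMul(z, leaves[[paste0(pre, ".cam.gamma")]]),
             leaves[[paste0(pre, ".cam.beta")]])
  agAdd(agMulRow(fNode, agSigmoid(z)), fNode)
}

.glsaStageNode <- function(model, leaves, s, p, fNode) {
  cfg <- model$config
  abl <- cfg$ablation
  pre <- sprintf("enc%d", s)
  nOut <- ceiling(nrow(p) * cfg$fps_rate)
  if (nOut < 1) stop("insufficient points at encoder stage ", s)
  sel <- farthestPointSampling(p, nOut)
  pC <- p[sel, , drop = FALSE]
  fC <- agGather(fNode, sel)
  radius <- cfg$ball_radius * 2^(s - 1)
  local <- .resmlpNode(model, leaves, pre, p, fNode, pC, fC,
                       cfg$local_k, radius, abl$resmlp)
  fused <- local
  if (abl$rsa) {
    glob <- .rsaNode(model, leaves, pre, pC, fC)
    fused <- agGateMix(local, glob, leaves[[paste0(pre, ".gate")]])
  }
  if (abl$cam_se) fused <- .camSeNode(model, leaves, pre, fused)
  list(pos = pC, f = fused)
}

.interpolateNode <- function(fNode, coarsePos, finePos) {
  iw <- interpWeights(finePos, coarsePos)
  interp <- NULL
  for (j in seq_len(ncol(iw$idx))) {
    term <- agMulColConst(agGather(fNode, iw$idx[, j]), iw$w[, j])
    interp <- if (is.null(interp)) term else agAdd(interp, term)
  }
  interp
}

.eafpStageNode <- function(model, leaves, d, coarsePos, fNode, skipPos,
                           skipFNode) {
  cfg <- model$config
  pre <- sprintf("dec%d", d)
  interp <- .interpolateNode(fNode, coarsePos, skipPos)
  catf <- agCbind(interp, skipFNode)
  nf <- nrow(skipPos)
  if (cfg$ablation$eafp) {
    ke <- cfg$eafp_k
    if (ke > nf) {
      warning("eafp_k clamped to ", nf)
      ke <- nf
    }
    nb <- knnIndices(skipPos, skipPos, ke)
    flat <- as.vector(nb) # column-major strided groups
    h <- agLinear(agGather(catf, flat), model$params, leaves, paste0(pre, ".l1"))
    pooled <- agGroupMax(h, ke)
    h2 <- agLinear(pooled, model$params, leaves, paste0(pre, ".l2"), act = "none")
    local <- agRelu(agAdd(h2, agLinear(skipFNode, model$params, leaves,
                                       paste0(pre, ".sc"), act = "none")))
    fj <- agGather(local, flat)
    fi <- agGather(local, rep(seq_len(nf), ke))
    eagg <- agGroupMean(agRelu(agSub(fj, fi)), ke)
    agLinear(agCbind(local, eagg), model$params, leaves, paste0(pre, ".edge"))
  } else {
    h <- agLinear(catf, model$params, leaves, paste0(pre, ".l1"))
    agLinear(h, model$params, leaves, paste0(pre, ".l2"))
  }
}

#' Forward pass of the segmentation network
#'
#' Processes one cloud (positions should be centred and normalized, see
#' [centerNormalize()]).  Building the computation graph makes the result
#' differentiable; [agBackward()] on a loss over the returned scores
#' propagates gradients into `leaves`.
#'
#' @param model from [initPointSegNet()].
#' @param pos `N x 3` normalized positions.
#' @param feats `N x in_channels` input features (typically
#'   `cbind(pos, normals)`).
#' @param leaves optional pre-built leaf nodes for the parameters (used by
#'   the training loop); built on the fly otherwise.
#' @return list with `scores` (an `agNode`, `N x num_classes`) and `leaves`
#'   (named list of parameter leaf nodes).
#' @export
pointSegNetForward <- function(model, pos, feats, leaves = NULL) {
  cfg <- model$config
  if (ncol(feats) != cfg$in_channels) {
    stop("expected ", cfg$in_channels, " feature channels (xyz + normals), got ",
         ncol(feats))
  }
  if (is.null(leaves)) leaves <- lapply(model$params, agLeaf)

  f <- agLinear(agConst(feats), model$params, leaves, "stem.l1")
  f <- agLinear(f, model$params, leaves, "stem.l2")
  p <- pos
  trace <- list(list(pos = pos, f = f))
  for (s in 1:4) {
    st <- .glsaStageNode(model, leaves, s, p, f)
    p <- st$pos
    f <- st$f
    trace[[s + 1L]] <- st
  }
  for (d in 1:4) {
    skip <- trace[[5L - d]]
    f <- .eafpStageNode(model, leaves, d, p, f, skip$pos, skip$f)
    p <- skip$pos
  }
  s1 <- agLinear(f, model$params, leaves, "head.l1")
  scores <- agLinear(s1, model$params, leaves, "head.l2", act = "none")
  list(scores = scores, leaves = leaves)
}

#' Run individual network modules on plain matrices
#'
#' Convenience wrappers over the tape implementation, for inspecting and
#' testing the encoder/decoder building blocks in isolation.
#'
#' `glsaStage` runs one full encoder stage (FPS, local ResMLP branch over a
#' ball-query neighbourhood, RSA global branch, gated fusion, CAM-SE);
#' `resmlpBlock` the local branch alone for given centres; `rsaAttention`
#' the global branch alone; `camSe` the channel attention alone;
#' `interpolateFeatures` inverse-distance 3-NN interpolation; `eafpStage`
#' one full decoder stage.
#'
#' @param model from [initPointSegNet()].
#' @param stage encoder/decoder stage index 1-4.
#' @param pos,feats point positions and features at the stage input.
#' @param centerIdx indices of the grouping centres (`resmlpBlock`).
#' @param coarsePos,coarseFeats,skipPos,skipFeats decoder-side inputs.
#' @param finePos target positions (`interpolateFeatures`).
#' @return numeric feature matrix (plus `positions` for `glsaStage`).
#' @export
glsaStage <- function(model, stage, pos, feats) {
  leaves <- lapply(model$params, agLeaf)
  st <- .glsaStageNode(model, leaves, stage, pos, agConst(feats))
  list(positions = st$pos, features = st$f$val)
}

#' @rdname glsaStage
#' @export
resmlpBlock <- function(model, stage, pos, feats, centerIdx = NULL) {
  cfg <- model$config
  if (is.null(centerIdx)) centerIdx <- seq_len(nrow(pos))
  leaves <- lapply(model$params, agLeaf)
  pre <- sprintf("enc%d", stage)
  fNode <- agConst(feats)
  out <- .resmlpNode(model, leaves, pre, pos, fNode,
                     pos[centerIdx, , drop = FALSE],
                     agGather(fNode, centerIdx),
                     cfg$local_k, cfg$ball_radius * 2^(stage - 1),
                     cfg$ablation$resmlp)
  out$val
}

#' @rdname glsaStage
#' @export
rsaAttention <- function(model, stage, pos, feats) {
  leaves <- lapply(model$params, agLeaf)
  .rsaNode(model, leaves, sprintf("enc%d", stage), pos, agConst(feats))$val
}

#' @rdname glsaStage
#' @export
camSe <- function(model, stage, feats) {
  leaves <- lapply(model$params, agLeaf)
  .camSeNode(model, leaves, sprintf("enc%d", stage), agConst(feats))$val
}

#' @rdname glsaStage
#' @export
interpolateFeatures <- function(coarsePos, coarseFeats, finePos) {
  .interpolateNode(agConst(coarseFeats), coarsePos, finePos)$val
}

#' @rdname glsaStage
#' @export
eafpStage <- function(model, stage, coarsePos, coarseFeats, skipPos,
                      skipFeats) {
  leaves <- lapply(model$params, agLeaf)
  .eafpStageNode(model, leaves, stage, coarsePos, agConst(coarseFeats),
                 skipPos, agConst(skipFeats))$val
}

#' Predict per-point labels for a cloud
#'
#' Centres/normalizes, assembles xyz+normal features (estimating normals if
#' absent), farthest-point-samples to the configured input size, runs the
#' network, and propagates predicted labels back to all original points by
#' nearest neighbour.
#'
#' @param model a trained model.
#' @param cloud a [PointCloud-class].
#' @return `cloud` with predicted labels.
#' @export
predictLabels <- function(model, cloud) {
  cfg <- model$config
  cn <- centerNormalize(cloud)
  nc <- cn$cloud
  if (is.null(normals(nc))) nc <- estimateNormals(nc, k = 16L)
  n <- nPoints(nc)
  sel <- if (n > cfg$npoints) farthestPointSampling(nc, cfg$npoints) else seq_len(n)
  sub <- nc[sel]
  feats <- cbind(positions(sub), normals(sub))
  out <- pointSegNetForward(model, positions(sub), feats)
  pred <- max.col(out$scores$val) - 1L
  if (length(sel) < n) {
    nnIdx <- knnIndices(positions(sub), positions(nc), 1L)
    pred <- pred[nnIdx[, 1]]
  }
  pointLabels(cloud) <- pred
  cloud
}
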