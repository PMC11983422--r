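# Training protocol: polynomial focal loss, geometric augmentation,
# AdamW with a multistep learning-rate schedule, and segmentation metrics.

#' Polynomial focal loss
#'
#' One-vs-rest with sigmoid activation per class:
#' `p = sigmoid(scores)`; `P_t = y p + (1 - y)(1 - p)`;
#' `L_CE = -[y log p + (1 - y) log(1 - p)]`;
#' `L_FL = L_CE (1 - P_t)^gamma`;
#' `loss = mean(L_FL + eps_poly (1 - P_t)^(gamma + 1))`.
#' `p` is clamped to `[1e-7, 1 - 1e-7]` before logarithms.
#'
#' @param scores `N x K` raw scores: numeric matrix or an `agNode` (in which
#'   case the returned loss is differentiable).
#' @param labels integer vector of true classes in `0 .. K-1`, or an `N x K`
#'   one-hot matrix.
#' @param gamma_focal focus factor (default 2).
#' @param eps_poly polynomial coefficient (default 1).
#' @return scalar loss (numeric, or a 1x1 `agNode` when `scores` is a node).
#' @export
polyFocalLoss <- function(scores, labels, gamma_focal = 2, eps_poly = 1) {
  val <- agVal(scores)
  K <- ncol(val)
  if (is.null(dim(labels))) {
    stopifnot(all(labels >= 0), all(labels < K))
    y <- matrix(0, nrow(val), K)
    y[cbind(seq_len(nrow(val)), labels + 1L)] <- 1
  } else y <- labels
  if (inherits(scores, "agNode")) {
    p <- agClamp(agSigmoid(scores), 1e-7, 1 - 1e-7)
    yc <- agConst(y); ycm <- agConst(1 - y)
    pt <- agAdd(agMul(yc, p), agMul(ycm, agAddScalar(agScale(p, -1), 1)))
    lce <- agScale(agAdd(agMul(yc, agLog(p)),
                         agMul(ycm, agLog(agAddScalar(agScale(p, -1), 1)))), -1)
    onemPt <- agAddScalar(agScale(pt, -1), 1)
    lfl <- agMul(lce, agPow(onemPt, gamma_focal))
    agMeanAll(agAdd(lfl, agScale(agPow(onemPt, gamma_focal + 1), eps_poly)))
  } else {
    p <- pmin(pmax(1 / (1 + exp(-val)), 1e-7), 1 - 1e-7)
    pt <- y * p + (1 - y) * (1 - p)
    lce <- -(y * log(p) + (1 - y) * log(1 - p))
    mean(lce * (1 - pt)^gamma_focal + eps_poly * (1 - pt)^(gamma_focal + 1))
  }
}

#' Training configuration
#'
#' @param epochs training epochs (default 300).
#' @param batch_size clouds per optimization step (default 4).
#' @param lr initial AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay (default 1e-4).
#' @param milestones epochs at which the learning rate is multiplied by
#'   `gamma_lr` (default 210, 270).
#' @param gamma_lr multistep decay factor (default 0.1).
#' @param points input points per cloud (resampled by FPS).
#' @param scale_range random scaling range (default 0.8-1.2).
#' @param jitter_sd,jitter_clip Gaussian jitter sd and truncation.
#' @param gamma_focal,eps_poly loss parameters.
#' @param seed integer seed.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(epochs = 300L, batch_size = 4L, lr = 1e-3,
                        weight_decay = 1e-4, milestones = c(210L, 270L),
                        gamma_lr = 0.1, points = 2048L,
                        scale_range = c(0.8, 1.2),
                        jitter_sd = 0.001, jitter_clip = 0.005,
                        gamma_focal = 2, eps_poly = 1, seed = 1L) {
  stopifnot(all(milestones < epochs) || length(milestones) == 0,
            scale_range[1] < scale_range[2], jitter_clip >= jitter_sd)
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, weight_decay = weight_decay, milestones = as.integer(milestones),
    gamma_lr = gamma_lr, points = as.integer(points),
    scale_range = scale_range, jitter_sd = jitter_sd,
    jitter_clip = jitter_clip, gamma_focal = gamma_focal,
    eps_poly = eps_poly, seed = as.integer(seed)), class = "TrainConfig")
}

#' Learning rate at a given epoch under the multistep schedule
#'
#' @param config a [trainConfig()].
#' @param epoch 1-based epoch index.
#' @return the learning rate in force during `epoch`.
#' @export
lrAtEpoch <- function(config, epoch) {
  config$lr * config$gamma_lr^sum(epoch >= config$milestones)
}

#' Augment a cloud for training
#'
#' Random uniform scaling, centring/normalization, truncated Gaussian
#' jitter, and FPS resampling (random start) to the configured point count.
#' Labels and other channels follow their points; geometry only is altered.
#'
#' @param cloud a [PointCloud-class].
#' @param config a [trainConfig()].
#' @param detail also return the drawn scale and jitter.
#' @return augmented cloud with exactly `config$points` points (or, with
#'   `detail = TRUE`, a list `cloud`, `scale`, `jitter`).
#' @export
augmentCloud <- function(cloud, config, detail = FALSE) {
  s <- stats::runif(1, config$scale_range[1], config$scale_range[2])
  cl <- initialize(cloud, positions = positions(cloud) * s)
  cl <- centerNormalize(cl)$cloud
  jit <- matrix(stats::rnorm(3 * nPoints(cl), sd = config$jitter_sd),
                ncol = 3)
  jit <- pmin(pmax(jit, -config$jitter_clip), config$jitter_clip)
  cl <- initialize(cl, positions = positions(cl) + jit)
  n <- nPoints(cl)
  if (n != config$points) {
    if (n < config$points) {
      idx <- c(seq_len(n), sample.int(n, config$points - n, replace = TRUE))
    } else {
      idx <- farthestPointSampling(cl, config$points,
                                   start = sample.int(n, 1))
    }
    cl <- cl[idx]
  }
  if (detail) list(cloud = cl, scale = s, jitter = jit) else cl
}

#' One-vs-rest confusion counts per class
#'
#' @param pred,truth integer label vectors of equal length.
#' @param num_classes number of classes `K`; labels must lie in `0..K-1`.
#' @return `K x 4` matrix with columns TP, FP, FN, TN.
#' @export
confusionCounts <- function(pred, truth, num_classes) {
  stopifnot(length(pred) == length(truth))
  if (any(pred < 0 | pred >= num_classes | truth < 0 | truth >= num_classes)) {
    stop("label outside 0..", num_classes - 1)
  }
  out <- matrix(0L, num_classes, 4,
                dimnames = list(paste0("class", 0:(num_classes - 1)),
                                c("TP", "FP", "FN", "TN")))
  n <- length(pred)
  for (k in 0:(num_classes - 1)) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    out[k + 1, ] <- c(tp, fp, fn, n - tp - fp - fn)
  }
  out
}

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean) and
#' IoU `TP/(TP+FP+FN)` per class, plus macro means.  A class absent from
#' both prediction and truth scores 1 on every metric; an empty denominator
#' otherwise scores 0.
#'
#' @param counts from [confusionCounts()].
#' @return list with `per_class` (K x 4 matrix: IoU, Precision, Recall, F1)
#'   and `macro` (named means).
#' @export
segmentationMetrics <- function(counts) {
  safe <- function(num, den, absent) ifelse(den == 0, ifelse(absent, 1, 0), num / den)
  tp <- counts[, "TP"]; fp <- counts[, "FP"]; fn <- counts[, "FN"]
  absent <- (tp + fp + fn) == 0
  prec <- safe(tp, tp + fp, absent)
  rec <- safe(tp, tp + fn, absent)
  f1 <- ifelse(absent, 1, ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec)))
  iou <- safe(tp, tp + fp + fn, absent)
  per <- cbind(IoU = iou, Precision = prec, Recall = rec, F1 = f1)
  rownames(per) <- rownames(counts)
  list(per_class = per, macro = colMeans(per))
}

# AdamW step (decoupled weight decay); state carries first/second moments
adamwStep <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

adamwInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# assemble (pos, feats, labels) for one cloud, estimating normals if needed
cloudToSample <- function(cloud) {
  if (is.null(normals(cloud))) cloud <- estimateNormals(cloud, k = 8L)
  list(pos = positions(cloud),
       feats = cbind(positions(cloud), normals(cloud)),
       labels = pointLabels(cloud))
}

#' Train the segmentation network
#'
#' AdamW with decoupled weight decay, multistep learning-rate decay, random
#' scale/normalize/jitter augmentation and FPS resampling per epoch.
#' Gradients are accumulated over `batch_size` clouds per step.  The
#' checkpoint with the best validation mean IoU is retained.
#'
#' @param trainClouds,valClouds lists of labelled [PointCloud-class]s.
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `final` (last epoch), and
#'   `history` (data.frame: epoch, lr, loss, val_miou).
#' @export
trainModel <- function(trainClouds, valClouds, modelCfg, trainCfg,
                       verbose = FALSE) {
  if (!length(trainClouds)) stop("empty training split")
  set.seed(trainCfg$seed)
  model <- initPointSegNet(modelCfg, seed = trainCfg$seed)
  state <- adamwInit(model$params)
  trainCfgP <- trainCfg
  trainCfgP$points <- modelCfg$npoints
  valSamples <- lapply(valClouds, function(cl) {
    n <- nPoints(cl)
    idx <- if (n > modelCfg$npoints) farthestPointSampling(cl, modelCfg$npoints) else seq_len(n)
    cl <- centerNormalize(cl[idx])$cloud
    cloudToSample(cl)
  })
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0), val_miou = numeric(0))
  best <- list(miou = -Inf, params = model$params)
  nTrain <- length(trainClouds)
  for (epoch in seq_len(trainCfg$epochs)) {
    lr <- lrAtEpoch(trainCfg, epoch)
    perm <- sample.int(nTrain)
    losses <- numeric(0)
    i <- 1L
    while (i <= nTrain) {
      take <- perm[i:min(i + trainCfg$batch_size - 1L, nTrain)]
      grads <- NULL
      batchLoss <- 0
      for (ci in take) {
        sm <- cloudToSample(augmentCloud(trainClouds[[ci]], trainCfgP))
        fw <- pointSegNetForward(model, sm$pos, sm$feats)
        loss <- polyFocalLoss(fw$scores, sm$labels,
                              trainCfg$gamma_focal, trainCfg$eps_poly)
        agBackward(loss)
        g <- lapply(fw$leaves, function(l) {
          if (is.null(l$grad)) l$val * 0 else l$grad
        })
        grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
        batchLoss <- batchLoss + loss$val[1]
      }
      grads <- lapply(grads, `/`, length(take))
      upd <- adamwStep(model$params, grads, state, lr, trainCfg$weight_decay)
      model$params <- upd$params
      state <- upd$state
      losses <- c(losses, batchLoss / length(take))
      i <- i + trainCfg$batch_size
    }
    valMiou <- NA_real_
    if (length(valSamples)) {
      cc <- matrix(0L, modelCfg$num_classes, 4,
                   dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
      for (sm in valSamples) {
        fw <- pointSegNetForward(model, sm$pos, sm$feats)
        pred <- max.col(fw$scores$val) - 1L
        cc <- cc + confusionCounts(pred, sm$labels, modelCfg$num_classes)
      }
      valMiou <- segmentationMetrics(cc)$macro[["IoU"]]
      if (valMiou > best$miou) best <- list(miou = valMiou, params = model$params)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, loss = mean(losses), val_miou = valMiou))
    if (verbose) {
      message(sprintf("epoch %3d lr %.2g loss %.4f val mIoU %.4f",
                      epoch, lr, mean(losses), valMiou))
    }
  }
  bestModel <- model
  if (is.finite(best$miou)) bestModel$params <- best$params
  list(model = bestModel, final = model, history = history,
       best_val_miou = best$miou)
}

#' Save / load a trained model
#'
#' The serialized object embeds the model configuration alongside the
#' weights.
#'
#' @param model a model list (`params`, `config`).
#' @param path file path (`.rds`).
#' @return `path` / the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(params = model$params, config = unclass(model$config)), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(modelConfig, obj$config[setdiff(names(obj$config), "ablation")])
  cfg$ablation <- obj$config$ablation
  list(params = obj$params, config = cfg)
}
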