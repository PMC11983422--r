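# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Nodes are environments holding a value, an accumulated gradient, parent
# references and a backward closure.  Graphs are built eagerly during the
# forward pass; agBackward() propagates in reverse creation order.  Only the
# operations the segmentation network needs are provided; all are validated
# against finite differences in the test suite.

.agCounter <- new.env(parent = emptyenv())
.agCounter$n <- 0L
.agCounter$visit <- 0L

agNode <- function(val, parents = list(), backward = NULL, leaf = FALSE) {
  e <- new.env(parent = emptyenv())
  .agCounter$n <- .agCounter$n + 1L
  e$id <- .agCounter$n
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$leaf <- leaf
  class(e) <- "agNode"
  e
}

#' Wrap a matrix as a differentiable leaf
#' @param x numeric matrix (or vector, treated as 1-row matrix).
#' @return an `agNode` leaf.
#' @keywords internal
agLeaf <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  agNode(x, leaf = TRUE)
}

agConst <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  agNode(x, leaf = TRUE) # leaf with no consumer interest; grad simply unused
}

agVal <- function(x) if (inherits(x, "agNode")) x$val else x

.accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Reverse-mode gradient propagation
#'
#' Seeds the gradient of `loss` (a 1x1 node) with 1 and propagates to all
#' ancestors; afterwards each leaf's `$grad` holds d loss / d leaf.
#'
#' @param loss scalar `agNode`.
#' @keywords internal
agBackward <- function(loss) {
  # collect reachable nodes; visited marks use a per-call stamp stored on
  # the node itself (never a string key: installing fresh binding names
  # would intern symbols permanently and leak across training steps)
  stamp <- .agCounter$visit <- .agCounter$visit + 1L
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (identical(nd$visit, stamp)) next
    nd$visit <- stamp
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  loss$grad <- matrix(1, 1, 1)
  for (nd in nodes) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (k in seq_along(gs)) {
      if (!is.null(gs[[k]])) .accum(nd$parents[[k]], gs[[k]])
    }
  }
  invisible(loss)
}

# ---- primitive ops ----------------------------------------------------

agMatmul <- function(a, w) {
  A <- agVal(a); W <- agVal(w)
  agNode(A %*% W, list(a, w), function(g) {
    list(g %*% t(W), crossprod(A, g))
  })
}

# add a 1 x C bias row vector to every row
agAddBias <- function(a, b) {
  A <- agVal(a); B <- agVal(b)
  agNode(sweep(A, 2, as.numeric(B), `+`), list(a, b), function(g) {
    list(g, matrix(colSums(g), 1))
  })
}

agAdd <- function(a, b) {
  A <- agVal(a); B <- agVal(b)
  agNode(A + B, list(a, b), function(g) list(g, g))
}

agSub <- function(a, b) {
  A <- agVal(a); B <- agVal(b)
  agNode(A - B, list(a, b), function(g) list(g, -g))
}

agMul <- function(a, b) { # elementwise, same shape
  A <- agVal(a); B <- agVal(b)
  agNode(A * B, list(a, b), function(g) list(g * B, g * A))
}

# multiply each row of a (N x C) by row vector v (1 x C)
agMulRow <- function(a, v) {
  A <- agVal(a); V <- as.numeric(agVal(v))
  agNode(sweep(A, 2, V, `*`), list(a, v), function(g) {
    list(sweep(g, 2, V, `*`), matrix(colSums(g * A), 1))
  })
}

# multiply each column of a (N x C) by constant column vector w (length N)
agMulColConst <- function(a, w) {
  A <- agVal(a)
  agNode(A * w, list(a), function(g) list(g * w))
}

agScale <- function(a, s) { # constant scalar
  A <- agVal(a)
  agNode(A * s, list(a), function(g) list(g * s))
}

agRelu <- function(a) {
  A <- agVal(a)
  mask <- A > 0
  agNode(A * mask, list(a), function(g) list(g * mask))
}

agSigmoid <- function(a) {
  A <- agVal(a)
  S <- 1 / (1 + exp(-A))
  agNode(S, list(a), function(g) list(g * S * (1 - S)))
}

agLog <- function(a) {
  A <- agVal(a)
  agNode(log(A), list(a), function(g) list(g / A))
}

agSqrt <- function(a) {
  A <- agVal(a)
  S <- sqrt(A)
  agNode(S, list(a), function(g) list(g / (2 * S)))
}

agPow <- function(a, p) { # constant exponent, a >= 0
  A <- agVal(a)
  agNode(A^p, list(a), function(g) {
    list(g * p * ifelse(A > 0, A^(p - 1), 0))
  })
}

agAddScalar <- function(a, c) { # constant scalar offset
  A <- agVal(a)
  agNode(A + c, list(a), function(g) list(g))
}

agClamp <- function(a, lo, hi) { # gradient passes only inside the range
  A <- agVal(a)
  mask <- A >= lo & A <= hi
  agNode(pmin(pmax(A, lo), hi), list(a), function(g) list(g * mask))
}

agCbind <- function(a, b) {
  A <- agVal(a); B <- agVal(b)
  ca <- ncol(A)
  agNode(cbind(A, B), list(a, b), function(g) {
    list(g[, seq_len(ca), drop = FALSE], g[, -seq_len(ca), drop = FALSE])
  })
}

# gather rows: out[i, ] = a[idx[i], ]
agGather <- function(a, idx) {
  A <- agVal(a)
  n <- nrow(A)
  agNode(A[idx, , drop = FALSE], list(a), function(g) {
    dA <- matrix(0, n, ncol(g))
    agg <- rowsum(g, group = idx)
    dA[as.integer(rownames(agg)), ] <- agg
    list(dA)
  })
}

# max over strided groups of k rows: a is (m*k) x C with group i occupying
# rows i, i+m, ..., i+(k-1)m (column-major neighbour layout) -> m x C
agGroupMax <- function(a, k) {
  A <- agVal(a)
  m <- nrow(A) / k
  stopifnot(m == round(m))
  best <- A[seq_len(m), , drop = FALSE]
  arg <- matrix(seq_len(m), m, ncol(A))
  if (k > 1) for (j in 2:k) {
    off <- (j - 1L) * m
    cand <- A[(off + 1L):(off + m), , drop = FALSE]
    upd <- which(cand > best)
    if (length(upd)) {
      best[upd] <- cand[upd]
      arg[upd] <- off + ((upd - 1L) %% m) + 1L
    }
  }
  agNode(best, list(a), function(g) {
    dA <- matrix(0, nrow(A), ncol(A))
    li <- as.vector((col(arg) - 1L) * nrow(A) + arg)
    dA[li] <- dA[li] + as.vector(g)
    list(dA)
  })
}

# mean over strided groups of k rows (same layout as agGroupMax)
agGroupMean <- function(a, k) {
  A <- agVal(a)
  m <- nrow(A) / k
  stopifnot(m == round(m))
  s <- A[seq_len(m), , drop = FALSE]
  if (k > 1) for (j in 2:k) {
    off <- (j - 1L) * m
    s <- s + A[(off + 1L):(off + m), , drop = FALSE]
  }
  agNode(s / k, list(a), function(g) {
    list(g[rep(seq_len(m), k), , drop = FALSE] / k)
  })
}

# column means -> 1 x C
agColMeans <- function(a) {
  A <- agVal(a)
  n <- nrow(A)
  agNode(matrix(colMeans(A), 1), list(a), function(g) {
    list(matrix(rep(as.numeric(g), each = n), n) / n)
  })
}

# subtract a 1 x C row vector from every row
agSubRow <- function(a, v) {
  A <- agVal(a); V <- as.numeric(agVal(v))
  agNode(sweep(A, 2, V), list(a, v), function(g) {
    list(g, matrix(-colSums(g), 1))
  })
}

# mean of all elements -> 1 x 1
agMeanAll <- function(a) {
  A <- agVal(a)
  agNode(matrix(mean(A), 1, 1), list(a), function(g) {
    list(matrix(as.numeric(g) / length(A), nrow(A), ncol(A)))
  })
}

# sum of all elements -> 1 x 1
agSumAll <- function(a) {
  A <- agVal(a)
  agNode(matrix(sum(A), 1, 1), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(A), ncol(A)))
  })
}

# gated mix of two same-shape tensors: g*a + (1-g)*b with g = sigmoid(x),
# x a 1x1 learnable node
agGateMix <- function(a, b, x) {
  A <- agVal(a); B <- agVal(b); X <- as.numeric(agVal(x))
  s <- 1 / (1 + exp(-X))
  agNode(s * A + (1 - s) * B, list(a, b, x), function(g) {
    list(g * s, g * (1 - s),
         matrix(sum(g * (A - B)) * s * (1 - s), 1, 1))
  })
}
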