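#' @import methods
#' @useDynLib stemleaf3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Labelled point cloud
#'
#' The universal exchange container of the package: an `N x 3` matrix of
#' positions with optional per-point normals, colours and integer organ
#' labels.  Coordinates are interpreted z-up; trait extraction relies on this
#' convention.
#'
#' @slot positions numeric `N x 3` matrix of xyz coordinates.
#' @slot normals numeric `N x 3` matrix of unit normals, or a `0 x 3` matrix
#'   when absent.
#' @slot colors numeric `N x 3` matrix of rgb values, or a `0 x 3` matrix when
#'   absent.  The dialect (`"byte"` for 0-255, `"unit"` for 0-1) is recorded
#'   in `colorScale`.
#' @slot colorScale character scalar, `"byte"` or `"unit"`.
#' @slot labels integer vector of length `N` (non-negative), or length 0 when
#'   absent.  Convention: 0 = stem, 1 = leaf, 2 = branch/other.
#' @slot frame character axis-convention tag, always `"z-up"` here.
#'
#' @examples
#' pc <- PointCloud(matrix(rnorm(30), ncol = 3))
#' nPoints(pc)
#' @export
setClass("PointCloud",
  representation(
    positions = "matrix",
    normals = "matrix",
    colors = "matrix",
    colorScale = "character",
    labels = "integer",
    frame = "character"
  ),
  prototype(
    normals = matrix(numeric(0), ncol = 3),
    colors = matrix(numeric(0), ncol = 3),
    colorScale = "byte",
    labels = integer(0),
    frame = "z-up"
  )
)

setValidity("PointCloud", function(object) {
  n <- nrow(object@positions)
  msg <- character(0)
  if (n < 1L) msg <- c(msg, "positions must contain at least one point")
  if (ncol(object@positions) != 3L) msg <- c(msg, "positions must have 3 columns")
  if (!all(is.finite(object@positions))) msg <- c(msg, "positions must be finite")
  if (nrow(object@normals) > 0L) {
    if (nrow(object@normals) != n) msg <- c(msg, "normals must match point count")
    nrm <- sqrt(rowSums(object@normals^2))
    if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "normals must be unit length (1e-6)")
  }
  if (nrow(object@colors) > 0L && nrow(object@colors) != n) {
    msg <- c(msg, "colors must match point count")
  }
  if (!object@colorScale %in% c("byte", "unit")) {
    msg <- c(msg, "colorScale must be 'byte' or 'unit'")
  }
  if (length(object@labels) > 0L) {
    if (length(object@labels) != n) msg <- c(msg, "labels must match point count")
    if (any(object@labels < 0L)) msg <- c(msg, "labels must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PointCloud
#'
#' @param positions `N x 3` numeric matrix.
#' @param normals optional `N x 3` matrix of unit normals.
#' @param colors optional `N x 3` matrix of rgb values.
#' @param labels optional integer vector of per-point organ labels.
#' @param colorScale `"byte"` (0-255) or `"unit"` (0-1); auto-detected from
#'   the colour range when `NULL`.
#' @return a [PointCloud-class] object.
#' @export
PointCloud <- function(positions, normals = NULL, colors = NULL, labels = NULL,
                       colorScale = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (is.null(normals)) normals <- matrix(numeric(0), ncol = 3)
  if (is.null(colors)) colors <- matrix(numeric(0), ncol = 3)
  normals <- as.matrix(normals); storage.mode(normals) <- "double"
  colors <- as.matrix(colors); storage.mode(colors) <- "double"
  dimnames(positions) <- dimnames(normals) <- dimnames(colors) <- NULL
  if (is.null(colorScale)) {
    colorScale <- if (nrow(colors) > 0 && max(colors) <= 1) "unit" else "byte"
  }
  labels <- if (is.null(labels)) integer(0) else as.integer(labels)
  new("PointCloud",
    positions = positions, normals = normals, colors = colors,
    colorScale = colorScale, labels = labels, frame = "z-up")
}

#' @rdname PointCloud
#' @param x,object a `PointCloud`.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname PointCloud
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@positions))

#' @rdname PointCloud
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname PointCloud
#' @export
setMethod("positions", "PointCloud", function(x) x@positions)

#' @rdname PointCloud
#' @export
setGeneric("normals", function(x) standardGeneric("normals"))

#' @rdname PointCloud
#' @export
setMethod("normals", "PointCloud", function(x) {
  if (nrow(x@normals)) x@normals else NULL
})

#' @rdname PointCloud
#' @export
setGeneric("pointColors", function(x) standardGeneric("pointColors"))

#' @rdname PointCloud
#' @export
setMethod("pointColors", "PointCloud", function(x) {
  if (nrow(x@colors)) x@colors else NULL
})

#' @rdname PointCloud
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))

#' @rdname PointCloud
#' @export
setMethod("pointLabels", "PointCloud", function(x) {
  if (length(x@labels)) x@labels else NULL
})

#' @rdname PointCloud
#' @param value replacement labels (integer vector of length `nPoints(x)`).
#' @export
setGeneric("pointLabels<-", function(x, value) standardGeneric("pointLabels<-"))

#' @rdname PointCloud
#' @export
setMethod("pointLabels<-", "PointCloud", function(x, value) {
  x@labels <- if (is.null(value)) integer(0) else as.integer(value)
  validObject(x)
  x
})

#' Subset a point cloud
#'
#' All per-point channels (normals, colours, labels) follow their point.
#'
#' @param x a `PointCloud`.
#' @param i integer or logical index of points to keep.
#' @param j,...,drop ignored.
#' @return a `PointCloud` with the selected points.
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  new("PointCloud",
    positions = x@positions[i, , drop = FALSE],
    normals = if (nrow(x@normals)) x@normals[i, , drop = FALSE] else x@normals,
    colors = if (nrow(x@colors)) x@colors[i, , drop = FALSE] else x@colors,
    colorScale = x@colorScale,
    labels = if (length(x@labels)) x@labels[i] else x@labels,
    frame = x@frame)
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud with %d points (%s frame)\n", nPoints(object), object@frame))
  ch <- c(
    if (nrow(object@normals)) "normals",
    if (nrow(object@colors)) sprintf("colors[%s]", object@colorScale),
    if (length(object@labels)) sprintf("labels{%s}", paste(sort(unique(object@labels)), collapse = ","))
  )
  cat("  channels:", if (length(ch)) paste(ch, collapse = ", ") else "none", "\n")
  rng <- apply(object@positions, 2, range)
  cat(sprintf("  extent: x[%.3g, %.3g] y[%.3g, %.3g] z[%.3g, %.3g]\n",
    rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
})

# concatenate clouds in a common frame; channels kept only if present in all
combinePointClouds <- function(clouds) {
  clouds <- Filter(Negate(is.null), clouds)
  stopifnot(length(clouds) >= 1)
  pos <- do.call(rbind, lapply(clouds, positions))
  haveN <- all(vapply(clouds, function(c) !is.null(normals(c)), logical(1)))
  haveC <- all(vapply(clouds, function(c) !is.null(pointColors(c)), logical(1)))
  haveL <- all(vapply(clouds, function(c) !is.null(pointLabels(c)), logical(1)))
  PointCloud(pos,
    normals = if (haveN) do.call(rbind, lapply(clouds, normals)) else NULL,
    colors = if (haveC) do.call(rbind, lapply(clouds, pointColors)) else NULL,
    labels = if (haveL) unlist(lapply(clouds, pointLabels)) else NULL,
    colorScale = if (haveC) clouds[[1]]@colorScale else NULL)
}
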