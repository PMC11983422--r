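#' Read a point cloud from PLY or whitespace-delimited text
#'
#' PLY files may be ascii or binary little-endian.  Text files are
#' whitespace-delimited with one point per row; accepted column layouts are
#' 3 (`x y z`), 6 (`x y z nx ny nz`), 7 (`x y z r g b label`),
#' 9 (`x y z nx ny nz r g b`) and 10 (`x y z nx ny nz r g b label`).
#' The colour dialect is auto-detected: a maximum colour value of at most 1
#' is taken as unit scale, otherwise bytes.
#'
#' @param path file to read.
#' @param format `"ply"`, `"txt"`, or `"auto"` (from the file extension).
#' @return a [PointCloud-class].
#' @export
readPointCloud <- function(path, format = c("auto", "ply", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "txt"
  }
  if (format == "ply") readPly(path) else readTxtCloud(path)
}

#' Write a point cloud to PLY or text
#'
#' PLY output is binary little-endian with double-precision coordinates, so
#' positions round-trip bit-exactly.  Text output uses 6 significant digits.
#'
#' @param cloud a [PointCloud-class].
#' @param path output file.
#' @param format `"ply"`, `"txt"`, or `"auto"` (from the file extension).
#' @param binary write binary little-endian PLY (default) or ascii.
#' @return `path`, invisibly.
#' @export
writePointCloud <- function(cloud, path, format = c("auto", "ply", "txt"),
                            binary = TRUE) {
  format <- match.arg(format)
  stopifnot(is(cloud, "PointCloud"))
  validObject(cloud)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "txt"
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (format == "ply") writePly(cloud, path, binary = binary) else writeTxtCloud(cloud, path)
  invisible(path)
}

readTxtCloud <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty point cloud file: ", path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    stop("malformed row at line ", bad, ": expected ", ncols[1],
         " columns, found ", ncols[bad])
  }
  nc <- ncols[1]
  if (!nc %in% c(3L, 6L, 7L, 9L, 10L)) {
    stop("unsupported column count ", nc,
         "; accepted layouts: 3 (xyz), 6 (xyz+normals), 7 (xyz+rgb+label), ",
         "9 (xyz+normals+rgb), 10 (xyz+normals+rgb+label)")
  }
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    badrow <- ceiling(which(is.na(vals))[1] / nc)
    stop("malformed row at line ", badrow, ": non-numeric field")
  }
  m <- matrix(vals, ncol = nc, byrow = TRUE)
  pos <- m[, 1:3, drop = FALSE]
  nrm <- cols <- lab <- NULL
  if (nc == 6L) nrm <- m[, 4:6, drop = FALSE]
  if (nc == 7L) { cols <- m[, 4:6, drop = FALSE]; lab <- m[, 7] }
  if (nc >= 9L) { nrm <- m[, 4:6, drop = FALSE]; cols <- m[, 7:9, drop = FALSE] }
  if (nc == 10L) lab <- m[, 10]
  if (!is.null(nrm)) {
    nn <- sqrt(rowSums(nrm^2))
    nn[nn == 0] <- 1
    nrm <- nrm / nn
  }
  PointCloud(pos, normals = nrm, colors = cols, labels = lab)
}

writeTxtCloud <- function(cloud, path) {
  m <- positions(cloud)
  if (!is.null(normals(cloud))) m <- cbind(m, normals(cloud))
  if (!is.null(pointColors(cloud))) m <- cbind(m, pointColors(cloud))
  if (!is.null(pointLabels(cloud))) m <- cbind(m, pointLabels(cloud))
  txt <- apply(m, 1L, function(r) paste(signif(r, 6), collapse = " "))
  writeLines(txt, path)
}

# --- PLY ---------------------------------------------------------------
# Minimal PLY support tailored to point clouds: one "vertex" element with
# x/y/z (+ optional nx/ny/nz, red/green/blue, label) properties.

plyTypeInfo <- function(type) {
  switch(type,
    "char" = , "int8" = list(what = "integer", size = 1L, signed = TRUE),
    "uchar" = , "uint8" = list(what = "integer", size = 1L, signed = FALSE),
    "short" = , "int16" = list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "uint16" = list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "int32" = list(what = "integer", size = 4L, signed = TRUE),
    "uint" = , "uint32" = list(what = "integer", size = 4L, signed = FALSE),
    "float" = , "float32" = list(what = "double", size = 4L, signed = TRUE),
    "double" = , "float64" = list(what = "double", size = 8L, signed = TRUE),
    stop("unsupported PLY property type: ", type))
}

readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; elements <- list(); current <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated PLY header")
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(current)) elements[[current$name]] <- current
      current <- list(name = tok[2], count = as.integer(tok[3]),
                      props = character(0), types = character(0))
    } else if (tok[1] == "property") {
      if (tok[2] == "list") stop("PLY list properties are not supported")
      current$types <- c(current$types, tok[2])
      current$props <- c(current$props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (!is.null(current)) elements[[current$name]] <- current
  v <- elements[["vertex"]]
  if (is.null(v)) stop("PLY file has no vertex element")
  np <- length(v$props)
  if (identical(fmt, "ascii")) {
    dat <- scan(con, what = numeric(), n = v$count * np, quiet = TRUE)
    m <- matrix(dat, ncol = np, byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    m <- matrix(0, nrow = v$count, ncol = np)
    infos <- lapply(v$types, plyTypeInfo)
    rowsize <- sum(vapply(infos, `[[`, integer(1), "size"))
    raw <- readBin(con, "raw", n = rowsize * v$count)
    off <- 0L
    for (j in seq_len(np)) {
      info <- infos[[j]]
      starts <- (seq_len(v$count) - 1L) * rowsize + off
      idx <- as.vector(outer(seq_len(info$size), starts, `+`))
      bytes <- raw[idx]
      m[, j] <- readBin(bytes, what = info$what, n = v$count,
                        size = info$size, endian = "little",
                        signed = if (info$size >= 4L) TRUE else info$signed)
      off <- off + info$size
    }
  } else {
    stop("unsupported PLY format: ", fmt)
  }
  colnames(m) <- v$props
  need <- c("x", "y", "z")
  if (!all(need %in% v$props)) stop("PLY vertex element lacks x/y/z")
  pos <- m[, need, drop = FALSE]
  nrm <- if (all(c("nx", "ny", "nz") %in% v$props)) m[, c("nx", "ny", "nz"), drop = FALSE]
  cols <- if (all(c("red", "green", "blue") %in% v$props)) m[, c("red", "green", "blue"), drop = FALSE]
  lab <- if ("label" %in% v$props) m[, "label"]
  PointCloud(pos, normals = nrm, colors = cols, labels = lab)
}

writePly <- function(cloud, path, binary = TRUE) {
  pos <- positions(cloud)
  nrm <- normals(cloud)
  cols <- pointColors(cloud)
  lab <- pointLabels(cloud)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nrow(pos)),
    "property double x", "property double y", "property double z",
    if (!is.null(nrm)) c("property double nx", "property double ny", "property double nz"),
    if (!is.null(cols)) c("property uchar red", "property uchar green", "property uchar blue"),
    if (!is.null(lab)) "property int label",
    "end_header")
  colsByte <- NULL
  if (!is.null(cols)) {
    colsByte <- if (cloud@colorScale == "unit") round(cols * 255) else round(cols)
    colsByte[] <- pmin(pmax(colsByte, 0), 255)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  n <- nrow(pos)
  if (binary) {
    dmat <- t(cbind(pos, if (!is.null(nrm)) nrm))
    for (i in seq_len(n)) {
      writeBin(as.numeric(dmat[, i]), con, size = 8L, endian = "little")
      if (!is.null(colsByte)) {
        writeBin(as.raw(colsByte[i, ]), con)
      }
      if (!is.null(lab)) writeBin(as.integer(lab[i]), con, size = 4L, endian = "little")
    }
  } else {
    m <- cbind(pos, if (!is.null(nrm)) nrm)
    txt <- apply(m, 1L, function(r) paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " "))
    if (!is.null(colsByte)) {
      txt <- paste(txt, apply(colsByte, 1L, paste, collapse = " "))
    }
    if (!is.null(lab)) txt <- paste(txt, as.integer(lab))
    writeLines(txt, con)
  }
  invisible(path)
}
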