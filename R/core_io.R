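# readers/writers for PLY, ASCII XYZ and LAS, plus neighbourhood queries

.formatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, ply = "ply", xyz = "xyz", txt = "xyz", las = "las", laz = "las",
         stop("cannot infer point-cloud format from extension '", ext, "'"))
}

.plyTypeSize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                  float = 4L, float32 = 4L, double = 8L, float64 = 8L)
.plyIsFloat <- function(type) type %in% c("float", "float32", "double", "float64")

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  nvert <- NULL
  props <- list()        # vertex properties in order: list(name=, type=)
  inVertex <- FALSE
  elements <- list()     # name -> count for non-vertex elements (to skip)
  elemOrder <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of PLY header in ", path)
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      inVertex <- tok[2] == "vertex"
      if (inVertex) nvert <- as.integer(tok[3])
      elements[[tok[2]]] <- as.integer(tok[3])
      elemOrder <- c(elemOrder, tok[2])
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        if (inVertex) stop("list properties on vertices are not supported")
      } else if (inVertex) {
        props[[length(props) + 1L]] <- list(name = tok[3], type = tok[2])
      }
    } else if (tok[1] == "end_header") break
  }
  if (is.null(nvert)) stop("PLY file has no vertex element: ", path)
  if (length(elemOrder) && elemOrder[1] != "vertex")
    stop("PLY files with elements before 'vertex' are not supported")
  pnames <- vapply(props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames))
    stop("PLY vertex element must provide x, y and z properties")

  if (identical(fmt, "ascii")) {
    tab <- if (nvert > 0)
      read.table(text = readLines(con, n = nvert), colClasses = "numeric",
                 col.names = pnames, header = FALSE)
    else as.data.frame(matrix(numeric(0), 0, length(pnames),
                              dimnames = list(NULL, pnames)))
    vals <- as.list(tab)
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- .plyTypeSize[vapply(props, `[[`, "", "type")]
    if (anyNA(sizes)) stop("unsupported PLY property type")
    rowSize <- sum(sizes)
    raw <- readBin(con, "raw", n = rowSize * nvert)
    if (length(raw) < rowSize * nvert) stop("truncated PLY payload in ", path)
    vals <- vector("list", length(props))
    offset <- 0L
    for (j in seq_along(props)) {
      tp <- props[[j]]$type
      sz <- .plyTypeSize[[tp]]
      if (nvert > 0) {
        sel <- as.vector(outer(seq_len(sz), (seq_len(nvert) - 1L) * rowSize + offset, `+`))
        bytes <- raw[sel]
        vals[[j]] <- if (.plyIsFloat(tp))
          readBin(bytes, "double", n = nvert, size = sz, endian = "little")
        else
          readBin(bytes, "integer", n = nvert, size = sz, endian = "little",
                  signed = !startsWith(tp, "u") || sz >= 4L)
      } else vals[[j]] <- numeric(0)
      offset <- offset + sz
    }
    names(vals) <- pnames
  } else stop("unsupported PLY format '", fmt, "'")

  coords <- cbind(x = as.numeric(vals$x), y = as.numeric(vals$y),
                  z = as.numeric(vals$z))
  if (length(coords) && !all(is.finite(coords)))
    stop("PLY file contains non-finite coordinates: ", path)
  classLabel <- NULL
  if ("class_label" %in% pnames) {
    code <- as.integer(vals$class_label)
    classLabel <- c("leaf", "wood", "unassigned")[code + 1L]
  }
  lid <- if ("leaf_id" %in% pnames) as.integer(vals$leaf_id) else NULL
  pointCloud(coords, classLabel = classLabel, leafId = lid, sourcePath = path)
}

.writePLY <- function(cloud, path, binary = TRUE) {
  co <- coords(cloud)
  n <- nrow(co)
  hasLab <- length(cloud@classLabel) > 0
  hasId <- length(cloud@leafId) > 0
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           paste("element vertex", n),
           "property double x", "property double y", "property double z",
           if (hasLab) "property int class_label",
           if (hasId) "property int leaf_id",
           "end_header")
  lab <- if (hasLab) match(cloud@classLabel, c("leaf", "wood", "unassigned")) - 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0) return(invisible(path))
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(co[i, ]), con, size = 8L, endian = "little")
      if (hasLab) writeBin(as.integer(lab[i]), con, size = 4L, endian = "little")
      if (hasId) writeBin(as.integer(cloud@leafId[i]), con, size = 4L, endian = "little")
    }
  } else {
    txt <- sprintf("%.10g %.10g %.10g", co[, 1], co[, 2], co[, 3])
    if (hasLab) txt <- paste(txt, lab)
    if (hasId) txt <- paste(txt, cloud@leafId)
    writeLines(txt, con)
  }
  invisible(path)
}

.readXYZ <- function(path) {
  tab <- tryCatch(read.table(path, header = FALSE),
                  error = function(e) stop("cannot parse XYZ file ", path, ": ",
                                           conditionMessage(e)))
  if (nrow(tab) && ncol(tab) < 3) stop("XYZ file must have at least 3 columns: ", path)
  coords <- as.matrix(tab[, 1:3, drop = FALSE])
  storage.mode(coords) <- "double"
  if (length(coords) && !all(is.finite(coords)))
    stop("XYZ file contains non-finite coordinates: ", path)
  pointCloud(coords, sourcePath = path)
}

.writeXYZ <- function(cloud, path) {
  co <- coords(cloud)
  writeLines(sprintf("%.10g %.10g %.10g", co[, 1], co[, 2], co[, 3]), path)
  invisible(path)
}

# LAS 1.x reader, coordinates only (point formats 0-10)
.readLAS <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path)
  seek(con, 24L)
  verMajor <- as.integer(readBin(con, "raw", 1L))
  verMinor <- as.integer(readBin(con, "raw", 1L))
  seek(con, 96L)
  offsetToPoints <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 104L)
  fmt <- as.integer(readBin(con, "raw", 1L))
  recLen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  nPts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 131L)
  sc <- readBin(con, "double", 3L, size = 8L, endian = "little")
  off <- readBin(con, "double", 3L, size = 8L, endian = "little")
  if (verMajor == 1L && verMinor >= 4L && nPts == 0L) {
    seek(con, 247L)
    n64 <- readBin(con, "double", 1L, size = 8L, endian = "little")  # approx read
    nPts <- as.integer(n64)
  }
  seek(con, offsetToPoints)
  raw <- readBin(con, "raw", n = recLen * nPts)
  if (length(raw) < recLen * nPts) stop("truncated LAS payload in ", path)
  ints <- matrix(0L, nPts, 3)
  for (j in 1:3) {
    sel <- as.vector(outer(seq_len(4L), (seq_len(nPts) - 1L) * recLen + (j - 1L) * 4L, `+`))
    ints[, j] <- readBin(raw[sel], "integer", n = nPts, size = 4L, endian = "little")
  }
  coords <- sweep(sweep(ints, 2, sc, `*`), 2, off, `+`)
  pointCloud(coords, sourcePath = path)
}

#' Read a point cloud from PLY, ASCII XYZ or LAS
#'
#' PLY (ASCII or binary little-endian) per-vertex integer properties
#' `class_label` (0 = leaf, 1 = wood, 2 = unassigned) and `leaf_id`
#' (-1 = unassigned) are loaded when present. LAS is read coordinates-only.
#' Coordinates are returned unchanged (no recentring); they are expected in
#' metres.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"ply"`, `"xyz"` or `"las"`
#' @return a [PointCloud-class]
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("0 0 0", "1 0 0", "0 1 0"), f)
#' readPointCloud(f)
#' @export
readPointCloud <- function(path, format = c("auto", "ply", "xyz", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("point-cloud file does not exist: ", path)
  if (format == "auto") format <- .formatFromPath(path)
  switch(format,
         ply = .readPLY(path),
         xyz = .readXYZ(path),
         las = .readLAS(path))
}

#' Write a point cloud to PLY or ASCII XYZ
#'
#' PLY round-trips coordinates at double precision and labels exactly; XYZ
#' stores coordinates only.
#'
#' @param cloud a [PointCloud-class]
#' @param path output file
#' @param format `"auto"` (by extension), `"ply"` or `"xyz"`
#' @param binary write binary little-endian PLY (default) or ASCII
#' @return the path, invisibly
#' @export
writePointCloud <- function(cloud, path, format = c("auto", "ply", "xyz"),
                            binary = TRUE) {
  stopifnot(is(cloud, "PointCloud"))
  validObject(cloud)
  format <- match.arg(format)
  if (format == "auto") format <- .formatFromPath(path)
  if (format == "las") stop("LAS writing is not supported")
  switch(format,
         ply = .writePLY(cloud, path, binary = binary),
         xyz = .writeXYZ(cloud, path))
}

#' Indices of points within a spherical neighbourhood
#'
#' Returns exactly the indices \eqn{j \ne i} with
#' \eqn{\lVert p_j - p_i \rVert \le radius}, in ascending order. The query
#' point itself is excluded (its offset vector vanishes).
#'
#' @param cloud a [PointCloud-class]
#' @param index query point index (1-based)
#' @param radius neighbourhood radius in metres (> 0)
#' @return integer vector of neighbour indices
#' @export
radiusNeighbors <- function(cloud, index, radius) {
  stopifnot(is(cloud, "PointCloud"))
  n <- npoints(cloud)
  if (!(radius > 0)) stop("radius must be positive")
  if (index < 1 || index > n) stop("point index out of range")
  co <- coords(cloud)
  d2 <- (co[, 1] - co[index, 1])^2 + (co[, 2] - co[index, 2])^2 +
        (co[, 3] - co[index, 3])^2
  out <- unname(which(d2 <= radius^2))
  out[out != index]
}
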