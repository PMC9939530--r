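#' PointCloud: 3D points with optional wood/leaf labels and leaf instances
#'
#' Coordinates are in metres. `classLabel`, when present, holds one of
#' `"leaf"`, `"wood"`, `"unassigned"` per point; `leafId`, when present, holds
#' a non-negative instance id per leaf point and `-1L` elsewhere.
#'
#' @slot coords numeric matrix, N x 3 (x, y, z in metres)
#' @slot classLabel character of length 0 or N
#' @slot leafId integer of length 0 or N; -1 means unassigned
#' @slot sourcePath character of length 0 or 1
#' @export
setClass("PointCloud",
  representation(coords = "matrix", classLabel = "character",
                 leafId = "integer", sourcePath = "character"),
  prototype(coords = matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("x", "y", "z"))),
            classLabel = character(0), leafId = integer(0),
            sourcePath = character(0)))

.validPointCloud <- function(object) {
  msg <- character(0)
  co <- object@coords
  if (ncol(co) != 3) msg <- c(msg, "coords must have exactly 3 columns")
  if (length(co) && !all(is.finite(co))) msg <- c(msg, "all coordinates must be finite")
  n <- nrow(co)
  if (length(object@classLabel) && length(object@classLabel) != n)
    msg <- c(msg, "classLabel length must equal the number of points")
  if (length(object@classLabel) &&
      !all(object@classLabel %in% c("leaf", "wood", "unassigned")))
    msg <- c(msg, "classLabel values must be 'leaf', 'wood' or 'unassigned'")
  if (length(object@leafId) && length(object@leafId) != n)
    msg <- c(msg, "leafId length must equal the number of points")
  if (length(object@leafId) && length(object@classLabel)) {
    bad <- object@leafId >= 0L & object@classLabel != "leaf"
    if (any(bad)) msg <- c(msg, "leafId >= 0 is only allowed where classLabel == 'leaf'")
  }
  if (length(object@sourcePath) > 1) msg <- c(msg, "sourcePath must have length 0 or 1")
  if (length(msg)) msg else TRUE
}
setValidity("PointCloud", .validPointCloud)

#' Construct a PointCloud
#'
#' @param coords numeric matrix (or coercible) with 3 columns, metres
#' @param classLabel optional character per-point labels
#'   (`"leaf"`/`"wood"`/`"unassigned"`)
#' @param leafId optional integer per-point leaf instance ids (-1 = unassigned)
#' @param sourcePath optional path the cloud was read from
#' @return a [PointCloud-class] object
#' @examples
#' pc <- pointCloud(matrix(rnorm(30), ncol = 3))
#' npoints(pc)
#' @export
pointCloud <- function(coords, classLabel = NULL, leafId = NULL, sourcePath = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0) coords <- matrix(numeric(0), 0, 3)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  new("PointCloud", coords = coords,
      classLabel = if (is.null(classLabel)) character(0) else as.character(classLabel),
      leafId = if (is.null(leafId)) integer(0) else as.integer(leafId),
      sourcePath = if (is.null(sourcePath)) character(0) else as.character(sourcePath))
}

#' Plane in Hessian normal form
#'
#' The plane is \eqn{\{x : A x_1 + B x_2 + C x_3 = D\}} with unit normal
#' (A, B, C).
#'
#' @slot normal unit numeric of length 3
#' @slot offset numeric scalar D (metres)
#' @export
setClass("Plane", representation(normal = "numeric", offset = "numeric"))
setValidity("Plane", function(object) {
  if (length(object@normal) != 3) return("normal must have length 3")
  if (abs(sum(object@normal^2) - 1) > 1e-8) return("normal must be a unit vector")
  if (length(object@offset) != 1) return("offset must be a scalar")
  TRUE
})

#' @param normal numeric length-3 normal (normalised internally)
#' @param offset plane offset D
#' @rdname Plane-class
#' @export
plane <- function(normal, offset) {
  n <- sqrt(sum(normal^2))
  if (n == 0) stop("plane normal cannot be zero")
  new("Plane", normal = as.numeric(normal) / n, offset = as.numeric(offset) / n * n)
}

#' LeafModel: fitted geometry of one segmented leaf
#'
#' @slot fittedPoints MLS-smoothed leaf points (M x 3, metres)
#' @slot pe petiole-tip endpoint of the midrib axis
#' @slot ps blade-apex endpoint of the midrib axis
#' @slot leftEdges,rightEdges refined edge points per side ((n-1) x 3)
#' @slot hexagon six ordered vertices of the hexagonal base (6 x 3)
#' @slot normal unit leaf normal
#' @slot thickness equivalent leaf thickness (m): point extent along the normal
#' @slot volume hexagonal-prism volume (m^3)
#' @slot qualityFlag one of `"ok"`, `"fallback_bbox"`, `"rejected"`
#' @slot leafId instance id this model was fitted to
#' @export
setClass("LeafModel",
  representation(fittedPoints = "matrix", pe = "numeric", ps = "numeric",
                 leftEdges = "matrix", rightEdges = "matrix", hexagon = "matrix",
                 normal = "numeric", thickness = "numeric", volume = "numeric",
                 qualityFlag = "character", leafId = "integer"))
setValidity("LeafModel", function(object) {
  if (!object@qualityFlag %in% c("ok", "fallback_bbox", "rejected"))
    return("qualityFlag must be 'ok', 'fallback_bbox' or 'rejected'")
  if (length(object@thickness) && object@thickness < 0) return("thickness must be >= 0")
  if (length(object@volume) && object@volume < 0) return("volume must be >= 0")
  TRUE
})

#' CylinderModel: one fitted branch segment
#'
#' @slot axisStart,axisEnd axis endpoints (metres)
#' @slot radius fitted radius (m)
#' @slot volume pi r^2 L (m^3)
#' @slot rmsResidual root-mean-square point-to-surface residual (m)
#' @slot converged logical; FALSE when the nonlinear fit fell back to PCA
#' @slot circumCoverage fraction of 36 azimuth bins around the axis that
#'   contain points; a genuine tube has high coverage, a curved arc lying on
#'   a spuriously fat cylinder has low coverage
#' @export
setClass("CylinderModel",
  representation(axisStart = "numeric", axisEnd = "numeric", radius = "numeric",
                 volume = "numeric", rmsResidual = "numeric", converged = "logical",
                 circumCoverage = "numeric"))
setValidity("CylinderModel", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  L <- sqrt(sum((object@axisEnd - object@axisStart)^2))
  if (abs(object@volume - pi * object@radius^2 * L) >
      1e-9 * max(1e-12, object@volume))
    return("volume must equal pi r^2 L of the reported parameters")
  TRUE
})

#' CrownModel: crown point set and its alpha-shape volume
#'
#' @slot crownPoints points above the crown base used for the shape (M x 3)
#' @slot alpha alpha parameter in metres (`Inf` = convex hull)
#' @slot volume crown volume (m^3)
#' @slot crownBaseHeight height of the crown base (m)
#' @export
setClass("CrownModel",
  representation(crownPoints = "matrix", alpha = "numeric", volume = "numeric",
                 crownBaseHeight = "numeric"))

#' GapFractionReport: results of the volumetric gap-fraction pipeline
#'
#' @slot gfVol volume-based gap fraction
#' @slot totalLeafVolume summed hexagonal-prism leaf volumes (m^3)
#' @slot totalWoodVolume summed branch-cylinder volumes (m^3)
#' @slot crownVolume crown volume (m^3)
#' @slot nLeaves number of modelled leaf instances
#' @slot nCylinders number of fitted branch cylinders
#' @slot gfImgPerRing data.frame of hemispherical-photo gap fractions per
#'   zenith ring (columns zenithLo, zenithHi, gf)
#' @slot gfVoxel voxel-occupancy gap fraction
#' @slot gfLight data.frame of Beer-Lambert transmissions per zenith angle
#' @slot warnings character vector of pipeline warnings
#' @export
setClass("GapFractionReport",
  representation(gfVol = "numeric", totalLeafVolume = "numeric",
                 totalWoodVolume = "numeric", crownVolume = "numeric",
                 nLeaves = "integer", nCylinders = "integer",
                 gfImgPerRing = "data.frame", gfVoxel = "numeric",
                 gfLight = "data.frame", warnings = "character"))
setValidity("GapFractionReport", function(object) {
  if (length(object@gfVol) && length(object@crownVolume) && object@crownVolume > 0) {
    expect <- 1 - (object@totalLeafVolume + object@totalWoodVolume) / object@crownVolume
    if (abs(object@gfVol - expect) > 1e-12)
      return("gfVol must equal 1 - (leaf + wood volume)/crown volume")
  }
  if (length(object@gfVoxel) && !is.na(object@gfVoxel) &&
      (object@gfVoxel < 0 || object@gfVoxel > 1))
    return("gfVoxel must lie in [0, 1]")
  TRUE
})
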