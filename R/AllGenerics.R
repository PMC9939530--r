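# generics and accessors for the core data classes

#' Number of points in a cloud
#' @param x a [PointCloud-class]
#' @return integer point count
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' @rdname npoints
#' @export
setMethod("npoints", "PointCloud", function(x) nrow(x@coords))

#' Coordinate matrix of a cloud
#' @param x a [PointCloud-class]
#' @return N x 3 numeric matrix (metres)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' Per-point wood/leaf class labels
#' @param x a [PointCloud-class]
#' @param value character labels (`"leaf"`, `"wood"`, `"unassigned"`)
#' @return character vector (length 0 when absent)
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname classLabel
#' @export
setMethod("classLabel", "PointCloud", function(x) x@classLabel)

#' @rdname classLabel
#' @export
setGeneric("classLabel<-", function(x, value) standardGeneric("classLabel<-"))

#' @rdname classLabel
#' @export
setMethod("classLabel<-", "PointCloud", function(x, value) {
  x@classLabel <- if (is.null(value)) character(0) else as.character(value)
  validObject(x)
  x
})

#' Per-point leaf instance ids
#' @param x a [PointCloud-class]
#' @param value integer ids, -1 = unassigned
#' @return integer vector (length 0 when absent)
#' @export
setGeneric("leafId", function(x) standardGeneric("leafId"))

#' @rdname leafId
#' @export
setMethod("leafId", "PointCloud", function(x) x@leafId)

#' @rdname leafId
#' @export
setGeneric("leafId<-", function(x, value) standardGeneric("leafId<-"))

#' @rdname leafId
#' @export
setMethod("leafId<-", "PointCloud", function(x, value) {
  x@leafId <- if (is.null(value)) integer(0) else as.integer(value)
  validObject(x)
  x
})

#' Volume of a fitted model
#' @param x a [LeafModel-class], [CylinderModel-class] or [CrownModel-class]
#' @return volume in cubic metres
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))

#' @rdname volume
#' @export
setMethod("volume", "LeafModel", function(x) x@volume)

#' @rdname volume
#' @export
setMethod("volume", "CylinderModel", function(x) x@volume)

#' @rdname volume
#' @export
setMethod("volume", "CrownModel", function(x) x@volume)

#' Volume-based gap fraction stored in a report
#' @param x a [GapFractionReport-class]
#' @return numeric gap fraction
#' @export
setGeneric("gfVol", function(x) standardGeneric("gfVol"))

#' @rdname gfVol
#' @export
setMethod("gfVol", "GapFractionReport", function(x) x@gfVol)

# subsetting keeps labels aligned with coordinates
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  pointCloud(x@coords[i, , drop = FALSE],
             classLabel = if (length(x@classLabel)) x@classLabel[i] else NULL,
             leafId = if (length(x@leafId)) x@leafId[i] else NULL,
             sourcePath = if (length(x@sourcePath)) x@sourcePath else NULL)
})

setMethod("show", "PointCloud", function(object) {
  n <- npoints(object)
  cat("PointCloud with", n, "points\n")
  if (length(object@classLabel)) {
    tab <- table(object@classLabel)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (length(object@leafId)) {
    k <- length(unique(object@leafId[object@leafId >= 0L]))
    cat("  leaf instances:", k, "\n")
  }
  if (length(object@sourcePath)) cat("  source:", object@sourcePath, "\n")
  if (n) {
    rng <- apply(object@coords, 2, range)
    cat(sprintf("  extent: x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
})

setMethod("show", "LeafModel", function(object) {
  cat(sprintf("LeafModel (id %d, %s): thickness %.4f m, volume %.3e m^3\n",
              object@leafId, object@qualityFlag,
              if (length(object@thickness)) object@thickness else NA_real_,
              if (length(object@volume)) object@volume else NA_real_))
})

setMethod("show", "CylinderModel", function(object) {
  L <- sqrt(sum((object@axisEnd - object@axisStart)^2))
  cat(sprintf("CylinderModel: r %.4f m, L %.3f m, volume %.3e m^3 (rms %.4f m)\n",
              object@radius, L, object@volume, object@rmsResidual))
})

setMethod("show", "CrownModel", function(object) {
  cat(sprintf("CrownModel: %d points, alpha %s, base %.3f m, volume %.3f m^3\n",
              nrow(object@crownPoints),
              if (is.infinite(object@alpha)) "Inf (convex hull)"
              else sprintf("%.3f m", object@alpha),
              object@crownBaseHeight, object@volume))
})

setMethod("show", "GapFractionReport", function(object) {
  cat("Volume-based gap-fraction report\n")
  cat(sprintf("  GF_vol: %.4f\n", object@gfVol))
  cat(sprintf("  leaf volume: %.4e m^3 over %d leaves\n",
              object@totalLeafVolume, object@nLeaves))
  cat(sprintf("  wood volume: %.4e m^3 over %d cylinders\n",
              object@totalWoodVolume, object@nCylinders))
  cat(sprintf("  crown volume: %.4f m^3\n", object@crownVolume))
  if (nrow(object@gfImgPerRing))
    cat(sprintf("  HP GF (%g-%g deg): %.3f\n", object@gfImgPerRing$zenithLo[1],
                object@gfImgPerRing$zenithHi[1], object@gfImgPerRing$gf[1]))
  if (length(object@gfVoxel) && !is.na(object@gfVoxel))
    cat(sprintf("  voxel GF: %.3f\n", object@gfVoxel))
  for (w in object@warnings) cat("  warning:", w, "\n")
})
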