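# end-to-end orchestration: classify -> leaf instances -> hexagonal prisms
# -> branch cylinders -> crown volume -> GF_vol (+ optional baselines)

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full volume-based gap-fraction pipeline
#'
#' Orchestrates wood/leaf classification, leaf-centre detection, geodesic
#' instance segmentation, per-leaf hexagonal-prism modelling, branch
#' cylinder fitting, crown-volume estimation and the gap-fraction
#' computation, plus any baselines requested in `config$baselines`. If the
#' input cloud already carries class labels they are reused unless
#' `reclassify = TRUE`. Wood cylinders are clipped at the crown base so that
#' the numerator and denominator of the gap fraction refer to the same
#' region. Deterministic for fixed input, config and seed.
#'
#' @param x a [PointCloud-class] or a path readable by [readPointCloud()]
#' @param config a [pipelineConfig()]
#' @param reclassify ignore existing labels and re-run the classifier
#' @return a [GapFractionReport-class]
#' @export
runPipeline <- function(x, config = pipelineConfig(), reclassify = FALSE) {
  validatePipelineConfig(config)
  set.seed(config$seed)
  cloud <- if (is(x, "PointCloud")) x
           else .stageTry("read", readPointCloud(x))
  if (config$unitScale != 1)
    cloud <- pointCloud(coords(cloud) * config$unitScale,
                        classLabel = if (length(cloud@classLabel)) cloud@classLabel,
                        leafId = if (length(cloud@leafId)) cloud@leafId)
  warnings <- character(0)

  .stageLog("pipeline start: ", npoints(cloud), " points")
  if (!length(classLabel(cloud)) || reclassify) {
    cloud <- .stageTry("classify", classifyWoodLeaf(
      cloud, method = config$classifyMethod,
      params = list(tLin = config$linearityThreshold,
                    scales = config$classifyScales)))
  }
  lab <- classLabel(cloud)
  leafIdxAll <- which(lab == "leaf")
  woodIdxAll <- which(lab == "wood")
  .stageLog("classified: ", length(leafIdxAll), " leaf / ",
            length(woodIdxAll), " wood")

  # leaf instances
  leafCloud <- cloud[leafIdxAll]
  cp <- centreDetectionParams(radius = config$radius,
                              threshold1 = config$threshold1,
                              threshold2 = config$threshold2,
                              threshold3 = config$threshold3,
                              minNeighbors = config$minNeighbors,
                              suppressionRadius = config$suppressionRadius,
                              sqrtUniformity = config$sqrtUniformity)
  centres <- .stageTry("leaf-centres",
                       if (npoints(leafCloud)) detectLeafCentres(leafCloud, cp)
                       else integer(0))
  .stageLog("leaf centres: ", length(centres))
  sp <- segmentationParams(geodesicCap = config$geodesicCap,
                           knnK = config$knnK, eps = config$dbscanEps,
                           minPts = config$dbscanMinPts,
                           minLeafPoints = config$minLeafPoints)
  leafCloud <- .stageTry("leaf-instances", segmentLeaves(leafCloud, centres, sp))
  ids <- leafId(leafCloud)
  instances <- sort(unique(ids[ids >= 0L]))
  .stageLog("leaf instances: ", length(instances))

  # per-leaf hexagonal prisms
  lmCfg <- leafModelConfig(minLeafPoints = config$minLeafPoints,
                           nSlices = config$nSlices,
                           mlsSupportRadius = config$mlsSupportRadius,
                           mlsDegree = config$mlsDegree,
                           avgLeafWidth = config$avgLeafWidth)
  lco <- coords(leafCloud)
  leafModels <- .stageTry("model-leaves", lapply(instances, function(k)
    modelLeaf(lco[ids == k, , drop = FALSE], config = lmCfg, id = k)))
  leafVols <- vapply(leafModels, volume, 0)
  totalLeaf <- sum(leafVols)
  .stageLog("leaf volume: ", signif(totalLeaf, 4), " m^3 over ",
            length(leafModels), " leaves")

  # branch cylinders; fits whose residual greatly exceeds the scanner noise
  # floor (the median residual over all cylinders) are not single branches
  # and are excluded from the wood volume
  woodCloud <- cloud[woodIdxAll]
  cylinders <- .stageTry("cylinders", {
    groups <- segmentBranchPoints(woodCloud, segmentLength = config$segmentLength)
    wco <- coords(woodCloud)
    out <- list()
    for (g in groups) {
      if (length(g) < 6) next
      out <- c(out, .fitCylindersRecursive(wco[g, , drop = FALSE]))
    }
    if (length(out) > 1) {
      rms <- vapply(out, function(x) x@rmsResidual, 0)
      covr <- vapply(out, function(x) x@circumCoverage, 0)
      out <- out[rms <= config$cylinderRmsFactor * stats::median(rms) &
                 covr >= 0.4]
    }
    out
  })
  .stageLog("cylinders: ", length(cylinders))

  # crown volume over vegetative points above the crown base
  crownBase <- config$crownBaseHeight
  if (is.null(crownBase))
    crownBase <- .stageTry("crown-base", estimateCrownBase(cloud))
  veg <- cloud[lab %in% c("leaf", "wood")]
  crown <- .stageTry("crown-volume",
                     crownVolume(veg, crownBaseHeight = crownBase,
                                 alpha = config$alpha))
  .stageLog("crown volume: ", signif(volume(crown), 4), " m^3 (base ",
            signif(crownBase, 4), " m)")

  totalWood <- sum(vapply(cylinders, .clipCylinderVolume, 0, base = crownBase))
  gf <- withCallingHandlers(
    .stageTry("gap-fraction", computeGFvol(totalLeaf, totalWood, volume(crown))),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  gfImg <- data.frame(zenithLo = numeric(0), zenithHi = numeric(0),
                      gf = numeric(0))
  gfVoxel <- NA_real_
  gfLight <- data.frame(theta = numeric(0), transmission = numeric(0))
  if ("hp" %in% config$baselines) {
    obs <- c(mean(range(coords(veg)[, 1])), mean(range(coords(veg)[, 2])),
             min(coords(veg)[, 3]) - 0.1)
    gfImg <- .stageTry("hp-baseline", hemisphericalGF(
      veg, observer = obs, imageSize = config$hpImageSize,
      ringEdges = config$hpRingEdges, footprintDeg = config$hpFootprintDeg,
      projection = config$hpProjection))
  }
  if ("voxel" %in% config$baselines)
    gfVoxel <- .stageTry("voxel-baseline", voxelGapFraction(
      veg, voxelSize = config$voxelSize, crownVolume = volume(crown)))
  if ("beer" %in% config$baselines && !is.null(config$beerLAI)) {
    th <- seq(0, 85, by = 5) * pi / 180
    gfLight <- data.frame(theta = th,
                          transmission = beerLambertGF(config$beerG,
                                                       config$beerOmega,
                                                       config$beerLAI, th))
  }

  report <- new("GapFractionReport", gfVol = gf, totalLeafVolume = totalLeaf,
                totalWoodVolume = totalWood, crownVolume = volume(crown),
                nLeaves = length(leafModels), nCylinders = length(cylinders),
                gfImgPerRing = gfImg, gfVoxel = gfVoxel, gfLight = gfLight,
                warnings = warnings)
  validObject(report)
  attr(report, "leafModels") <- leafModels
  attr(report, "cylinders") <- cylinders
  attr(report, "crown") <- crown
  attr(report, "leafCloud") <- leafCloud
  report
}

#' Serialise a gap-fraction report to JSON
#'
#' Identical inputs, configuration and seed produce byte-identical JSON.
#'
#' @param report a [GapFractionReport-class]
#' @param path optional output file; when `NULL` the JSON string is returned
#' @return the JSON string, invisibly when written to a file
#' @export
reportToJSON <- function(report, path = NULL) {
  stopifnot(is(report, "GapFractionReport"))
  x <- list(gf_vol = report@gfVol,
            total_leaf_volume_m3 = report@totalLeafVolume,
            total_wood_volume_m3 = report@totalWoodVolume,
            crown_volume_m3 = report@crownVolume,
            n_leaves = report@nLeaves,
            n_cylinders = report@nCylinders,
            gf_img_per_ring = report@gfImgPerRing,
            gf_voxel = report@gfVoxel,
            gf_light = report@gfLight,
            warnings = report@warnings)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, na = "null",
                         always_decimal = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
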