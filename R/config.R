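# pipeline configuration: every constant the method needs, in one place,
# serialisable to YAML

#' Build a pipeline configuration
#'
#' Collects all tunable constants of the gap-fraction pipeline. Dimensionful
#' defaults derive from species priors (average leaf length/width), mirroring
#' the use of per-species field knowledge rather than per-scan estimation:
#' the centre-detection radius is three quarters of the average half leaf
#' width, the geodesic cap twice the average leaf length, the MLS support a
#' quarter of the average width.
#'
#' @param avgLeafLength,avgLeafWidth species-prior blade dimensions (m)
#' @param radius centre-detection neighbourhood radius (m); `NULL` = derived
#' @param threshold1 mean plane-distance bound (m); `NULL` = `0.2 * radius`
#' @param threshold2 mean normal-angle bound (radians)
#' @param threshold3 uniformity bound on sigma'
#' @param sqrtUniformity compare sqrt(sigma') instead of sigma'
#' @param minNeighbors minimum neighbourhood size for centre candidates
#' @param suppressionRadius centre suppression distance (m); `NULL` = half
#'   the average leaf length
#' @param knnK geodesic-graph neighbour count
#' @param geodesicCap geodesic growing cap (m); `NULL` = derived
#' @param dbscanEps DBSCAN radius (m); `NULL` = twice the mean point spacing
#' @param dbscanMinPts DBSCAN core threshold
#' @param minLeafPoints minimum points for hexagon modelling
#' @param nSlices edge-slicing bins
#' @param mlsSupportRadius MLS support (m); `NULL` = derived
#' @param mlsDegree MLS polynomial degree (1 or 2)
#' @param classifyMethod `"threshold"`, `"gaussian"` or `"svm"`
#' @param classifyScales physical feature scales for classification (m)
#' @param linearityThreshold wood/leaf linearity threshold
#' @param segmentLength branch segment length (m)
#' @param cylinderRmsFactor cylinders whose fit rms exceeds this multiple of
#'   the median rms (the scanner-noise floor) are excluded from the wood
#'   volume
#' @param alpha crown alpha parameter (m); `Inf` = convex hull
#' @param crownBaseHeight crown base override (m); `NULL` = estimated
#' @param voxelSize voxel edge for the voxel baseline (m)
#' @param hpImageSize,hpFootprintDeg,hpProjection,hpRingEdges
#'   hemispherical-photograph baseline settings
#' @param beerG,beerOmega,beerLAI Beer-Lambert baseline parameters
#' @param baselines character subset of `c("hp", "voxel", "beer")`
#' @param unitScale multiply input coordinates by this factor to get metres
#' @param seed integer seed for any stochastic stage
#' @return a validated list of class `PipelineConfig`
#' @export
pipelineConfig <- function(avgLeafLength = 0.05, avgLeafWidth = 0.035,
                           radius = NULL, threshold1 = NULL,
                           threshold2 = 0.2618, threshold3 = 2.0,
                           sqrtUniformity = FALSE, minNeighbors = 10L,
                           suppressionRadius = NULL,
                           knnK = 10L, geodesicCap = NULL, dbscanEps = NULL,
                           dbscanMinPts = 10L, minLeafPoints = 40L,
                           nSlices = 21L, mlsSupportRadius = NULL,
                           mlsDegree = 2L,
                           classifyMethod = "threshold",
                           classifyScales = c(0.01, 0.02, 0.03, 0.05, 0.08),
                           linearityThreshold = 0.6,
                           segmentLength = 0.2, cylinderRmsFactor = 3,
                           alpha = Inf,
                           crownBaseHeight = NULL, voxelSize = 0.1,
                           hpImageSize = 1024L, hpFootprintDeg = 0.15,
                           hpProjection = "equal-area",
                           hpRingEdges = c(52.3, 62.3),
                           beerG = 0.5, beerOmega = 1, beerLAI = NULL,
                           baselines = character(0),
                           unitScale = 1, seed = 1L) {
  if (is.null(radius)) radius <- 0.75 * avgLeafWidth / 2
  if (is.null(threshold1)) threshold1 <- 0.2 * radius
  if (is.null(suppressionRadius)) suppressionRadius <- 0.5 * avgLeafLength
  if (is.null(geodesicCap)) geodesicCap <- 2 * avgLeafLength
  if (is.null(mlsSupportRadius)) mlsSupportRadius <- avgLeafWidth / 4
  baselines <- as.character(unlist(baselines))
  cfg <- list(schemaVersion = 1L,
              avgLeafLength = avgLeafLength, avgLeafWidth = avgLeafWidth,
              radius = radius, threshold1 = threshold1, threshold2 = threshold2,
              threshold3 = threshold3, sqrtUniformity = isTRUE(sqrtUniformity),
              minNeighbors = as.integer(minNeighbors),
              suppressionRadius = suppressionRadius,
              knnK = as.integer(knnK), geodesicCap = geodesicCap,
              dbscanEps = dbscanEps, dbscanMinPts = as.integer(dbscanMinPts),
              minLeafPoints = as.integer(minLeafPoints),
              nSlices = as.integer(nSlices),
              mlsSupportRadius = mlsSupportRadius,
              mlsDegree = as.integer(mlsDegree),
              classifyMethod = classifyMethod,
              classifyScales = classifyScales,
              linearityThreshold = linearityThreshold,
              segmentLength = segmentLength,
              cylinderRmsFactor = cylinderRmsFactor, alpha = alpha,
              crownBaseHeight = crownBaseHeight, voxelSize = voxelSize,
              hpImageSize = as.integer(hpImageSize),
              hpFootprintDeg = hpFootprintDeg, hpProjection = hpProjection,
              hpRingEdges = hpRingEdges,
              beerG = beerG, beerOmega = beerOmega, beerLAI = beerLAI,
              baselines = baselines, unitScale = unitScale,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `PipelineConfig`
#' @return the config, invisibly; stops with a message on invalid values
#' @export
validatePipelineConfig <- function(cfg) {
  must_pos <- c("avgLeafLength", "avgLeafWidth", "radius", "threshold1",
                "threshold2", "threshold3", "suppressionRadius", "geodesicCap",
                "mlsSupportRadius", "segmentLength", "voxelSize",
                "hpFootprintDeg", "unitScale", "linearityThreshold", "beerG")
  for (f in must_pos) {
    v <- cfg[[f]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !(v > 0)))
      stop("config field '", f, "' must be a positive number")
  }
  if (!is.null(cfg$dbscanEps) && !(cfg$dbscanEps > 0))
    stop("config field 'dbscanEps' must be a positive number")
  if (!cfg$classifyMethod %in% c("threshold", "gaussian", "svm"))
    stop("classifyMethod must be 'threshold', 'gaussian' or 'svm'")
  if (!cfg$hpProjection %in% c("equal-area", "equal-angle"))
    stop("hpProjection must be 'equal-area' or 'equal-angle'")
  if (any(!cfg$baselines %in% c("hp", "voxel", "beer")))
    stop("baselines must be a subset of 'hp', 'voxel', 'beer'")
  if (!(cfg$alpha > 0)) stop("alpha must be positive (or Inf)")
  if (any(cfg$classifyScales <= 0)) stop("classifyScales must be positive")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file take their defaults; unknown fields are an
#' error. The configuration round-trips losslessly through
#' [writePipelineConfig()].
#'
#' @param path YAML file
#' @return a `PipelineConfig`
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- yaml::read_yaml(path)
  raw$schemaVersion <- NULL
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a `PipelineConfig`
#' @param path output YAML file
#' @return the path, invisibly
#' @export
writePipelineConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, TRUE)]
  yaml::write_yaml(out, path)
  invisible(path)
}
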