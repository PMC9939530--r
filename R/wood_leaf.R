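# wood-leaf classification from local covariance eigen-features

#' Covariance eigen-features of a point's k-NN neighbourhood
#'
#' The covariance is taken over the k nearest neighbours plus the point
#' itself. With eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0},
#' linearity \eqn{= (\lambda_1-\lambda_2)/\lambda_1}, planarity
#' \eqn{= (\lambda_2-\lambda_3)/\lambda_1} and scattering
#' \eqn{= \lambda_3/\lambda_1}; the triple sums to 1. When all points
#' coincide (\eqn{\lambda_1 = 0}) the convention (0, 0, 1) is returned.
#'
#' @param cloud a [PointCloud-class]
#' @param index query point (1-based)
#' @param k number of neighbours (>= 3)
#' @return list with `linearity`, `planarity`, `scattering`, `eigenvalues`
#'   (descending)
#' @export
localEigenFeatures <- function(cloud, index, k = 20L) {
  stopifnot(is(cloud, "PointCloud"))
  n <- npoints(cloud)
  if (k < 3) stop("k must be at least 3")
  if (n < k + 1) stop("cloud has fewer than k + 1 points")
  if (index < 1 || index > n) stop("point index out of range")
  co <- coords(cloud)
  nn <- RANN::nn2(co, co[index, , drop = FALSE], k = k + 1L)
  idx <- as.integer(nn$nn.idx[1, ])
  res <- .eigenFeaturesBatchCpp(co, idx, c(0L, length(idx)))
  list(linearity = res$linearity[1], planarity = res$planarity[1],
       scattering = res$scattering[1], eigenvalues = as.numeric(res$eigenvalues[1, ]))
}

# voxel-grid downsample: index of one representative point per occupied voxel
.voxelDownsample <- function(co, cell) {
  lo <- apply(co, 2, min)
  key <- floor(sweep(co, 2, lo, `-`) / cell + 1e-9)
  !duplicated(key)
}

# batch eigen-features at a physical neighbourhood radius; the neighbour
# source is voxel-downsampled so a k-cap cannot shrink the effective radius
# in dense clouds (the covariance shape is what matters, not the count)
.featuresAtRadius <- function(co, radius, maxK = 150L) {
  keep <- .voxelDownsample(co, radius / 6)
  ref <- co[keep, , drop = FALSE]
  k <- min(nrow(ref), maxK)
  nn <- RANN::nn2(ref, co, k = k, searchtype = "radius", radius = radius)
  idx <- nn$nn.idx
  n <- nrow(co)
  lists <- vector("list", n)
  for (i in seq_len(n)) {
    v <- idx[i, ]
    lists[[i]] <- v[v > 0L]
  }
  lens <- lengths(lists)
  .eigenFeaturesBatchCpp(ref, as.integer(unlist(lists, use.names = FALSE)),
                         c(0L, cumsum(lens)))
}

# dimensionality triples (linearity/planarity/scattering) at every
# classification scale, as three matrices (points x scales)
.multiScaleTriples <- function(co, scales, maxK = 150L) {
  n <- nrow(co)
  LIN <- PLA <- SCA <- matrix(0, n, length(scales))
  for (j in seq_along(scales)) {
    f <- .featuresAtRadius(co, scales[j], maxK = maxK)
    lin <- f$linearity; pla <- f$planarity; sca <- f$scattering
    lin[!is.finite(lin)] <- 0
    pla[!is.finite(pla)] <- 0
    sca[!is.finite(sca)] <- 1
    LIN[, j] <- lin; PLA[, j] <- pla; SCA[, j] <- sca
  }
  list(LIN = LIN, PLA = PLA, SCA = SCA)
}

# feature matrix used by the trainable classifiers
.classifierFeatures <- function(co, scales, maxK = 150L) {
  tr <- .multiScaleTriples(co, scales, maxK)
  X <- cbind(tr$LIN, tr$PLA, tr$SCA)
  colnames(X) <- paste0(rep(c("lin", "pla", "sca"), each = length(scales)), "_s",
                        rep(seq_along(scales), times = 3))
  X
}

# per-point linearity at the entropy-optimal scale: for each point, the scale
# whose dimensionality triple has minimal Shannon entropy (the standard
# optimal-neighbourhood selection), optionally smoothed over the kNN graph
.optimalScaleLinearity <- function(co, scales, maxK = 150L,
                                   smoothK = 16L, smoothIter = 3L) {
  tr <- .multiScaleTriples(co, scales, maxK)
  ent <- -(tr$LIN * log(pmax(tr$LIN, 1e-9)) + tr$PLA * log(pmax(tr$PLA, 1e-9)) +
           tr$SCA * log(pmax(tr$SCA, 1e-9)))
  best <- max.col(-ent, ties.method = "first")
  lin <- tr$LIN[cbind(seq_len(nrow(co)), best)]
  if (smoothIter > 0L && nrow(co) > 1L) {
    k <- min(smoothK, nrow(co))
    nn <- RANN::nn2(co, co, k = k)
    for (i in seq_len(smoothIter))
      lin <- rowMeans(matrix(lin[nn$nn.idx], nrow(co), k))
  }
  lin
}

#' Classify points as wood or leaf
#'
#' The `threshold` method labels a point wood when its neighbourhood
#' linearity exceeds `tLin`, with the neighbourhood evaluated at the
#' entropy-optimal physical scale for each point (the scale whose
#' linearity/planarity/scattering triple has minimal Shannon entropy — the
#' standard optimal-neighbourhood selection; a single fixed k-NN scale can
#' resolve thin twigs or trunk curvature, but not both) and the resulting
#' linearity field smoothed over the k-NN graph to suppress salt-and-pepper
#' errors at blade edges. Points whose features are undefined default to
#' leaf — conservative for leaf-volume totals, since wood volume comes from
#' cylinder fits that tolerate a few missing points. The `gaussian`
#' (quadratic discriminant) and `svm` methods train on a labelled cloud
#' supplied in `params$training` and predict with the same multi-scale
#' feature set.
#'
#' @param cloud a [PointCloud-class]
#' @param method `"threshold"`, `"gaussian"` or `"svm"`
#' @param params list of options: `tLin` (default 0.6), `scales` (default
#'   `c(0.01, 0.02, 0.03, 0.05, 0.08)` metres), `maxK` (neighbour cap,
#'   default 150), `smoothK`/`smoothIter` (linearity-field smoothing,
#'   defaults 16 and 3), `training` (labelled [PointCloud-class]; required
#'   for `gaussian`/`svm`)
#' @return the cloud with `classLabel` filled in
#' @export
classifyWoodLeaf <- function(cloud, method = c("threshold", "gaussian", "svm"),
                             params = list()) {
  stopifnot(is(cloud, "PointCloud"))
  method <- match.arg(method)
  n <- npoints(cloud)
  if (n == 0) {
    classLabel(cloud) <- character(0)
    return(cloud)
  }
  tLin <- params$tLin %||% 0.6
  scales <- params$scales %||% c(0.01, 0.02, 0.03, 0.05, 0.08)
  maxK <- params$maxK %||% 150L
  co <- coords(cloud)

  if (method == "threshold") {
    lin <- .optimalScaleLinearity(co, scales, maxK = maxK,
                                  smoothK = params$smoothK %||% 16L,
                                  smoothIter = params$smoothIter %||% 3L)
    lab <- ifelse(lin > tLin, "wood", "leaf")
  } else {
    training <- params$training
    if (is.null(training))
      stop(method, " classification requires a labelled training cloud in params$training")
    stopifnot(is(training, "PointCloud"))
    if (!length(classLabel(training)))
      stop("training cloud has no class labels")
    Xtr <- .classifierFeatures(coords(training), scales, maxK)
    ytr <- factor(classLabel(training), levels = c("leaf", "wood"))
    X <- .classifierFeatures(co, scales, maxK)
    if (method == "gaussian") {
      # degenerate fixtures (exactly planar training leaves) make some
      # feature columns constant within a class; a deterministic sub-noise
      # jitter keeps the class covariances full rank
      Xtr <- Xtr + .withSeed(1L, matrix(rnorm(length(Xtr), 0, 1e-7),
                                        nrow(Xtr)))
      fit <- MASS::qda(Xtr, grouping = ytr)
      lab <- as.character(predict(fit, X)$class)
    } else {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial")
      lab <- as.character(predict(fit, X))
    }
    lab[is.na(lab)] <- "leaf"
  }
  classLabel(cloud) <- lab
  if (length(cloud@leafId)) {
    lid <- cloud@leafId
    lid[lab != "leaf"] <- -1L
    cloud@leafId <- lid
  }
  cloud
}

`%||%` <- function(a, b) if (is.null(a)) b else a
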