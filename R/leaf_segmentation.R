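# Individual leaf segmentation: the centre of a leaf surface is a point whose
# spherical neighbourhood lies close to a plane through the point (the "great
# circle"), has consistently oriented normals, and covers the circle
# isotropically (40 equal-area cells); instances are then grown geodesically
# from the detected centres, with DBSCAN sweeping up unreached points.

#' Parameters for leaf-centre detection
#'
#' @param radius spherical neighbourhood radius (m); the working default is
#'   three quarters of the average half leaf width
#' @param threshold1 bound on the mean point-to-plane distance (m); default
#'   `0.2 * radius`
#' @param threshold2 bound on the mean normal angle to neighbours (radians)
#' @param threshold3 bound on the angular uniformity statistic sigma'
#' @param minNeighbors minimum neighbourhood size for a candidate centre
#' @param suppressionRadius non-maximum-suppression distance between accepted
#'   centres (m); defaults to `2 * radius`, about half a leaf length, so one
#'   centre survives per lamina
#' @param sqrtUniformity compare `sqrt(sigma')` to `threshold3` instead of
#'   sigma' itself
#' @return a validated list of class `CentreDetectionParams`
#' @export
centreDetectionParams <- function(radius, threshold1 = 0.2 * radius,
                                  threshold2 = 0.2618, threshold3 = 2.0,
                                  minNeighbors = 10L,
                                  suppressionRadius = 2 * radius,
                                  sqrtUniformity = FALSE) {
  vals <- c(radius = radius, threshold1 = threshold1, threshold2 = threshold2,
            threshold3 = threshold3, minNeighbors = minNeighbors,
            suppressionRadius = suppressionRadius)
  if (any(!(vals > 0))) stop("all centre-detection parameters must be positive")
  structure(list(radius = radius, threshold1 = threshold1,
                 threshold2 = threshold2, threshold3 = threshold3,
                 minNeighbors = as.integer(minNeighbors),
                 suppressionRadius = suppressionRadius,
                 sqrtUniformity = isTRUE(sqrtUniformity)),
            class = "CentreDetectionParams")
}

#' Least-squares plane through a point ("great circle" fit)
#'
#' Fits the plane constrained to pass through the query point: the normal is
#' the eigenvector of the smallest eigenvalue of
#' \eqn{\sum_j w_j w_j^T} with offsets \eqn{w_j = p_j - p_i}, and
#' \eqn{D = A x_i + B y_i + C z_i}. Also returns the mean absolute
#' point-to-plane distance of the neighbours.
#'
#' @param cloud a [PointCloud-class]
#' @param index query point (1-based)
#' @param neighbors integer indices of the neighbours
#' @return list with `plane` ([Plane-class]) and `meanDistance` (m)
#' @export
fitGreatCirclePlane <- function(cloud, index, neighbors) {
  stopifnot(is(cloud, "PointCloud"))
  co <- coords(cloud)
  if (length(neighbors) < 3) stop("plane fitting requires at least 3 neighbours")
  W <- sweep(co[neighbors, , drop = FALSE], 2, co[index, ], `-`)
  res <- .planeThroughPointCpp(W)
  if (!(res$lambda1 > 0) ||
      .collinearOffsets(W))
    stop("degenerate geometry: neighbours are collinear")
  nrm <- res$normal
  new_plane <- plane(nrm, sum(nrm * co[index, ]))
  list(plane = new_plane, meanDistance = res$meanDistance)
}

.collinearOffsets <- function(W) {
  S <- crossprod(W)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev[2] <= 1e-12 * max(ev[1], .Machine$double.eps)
}

#' Robust normal at a candidate leaf centre
#'
#' Minimises \eqn{\sum_j (w_j^T n)^2 e^{-(w_j^T n)^2}} in the
#' iteratively-reweighted form: starting from the unweighted plane normal,
#' the normal is repeatedly recomputed as the smallest eigenvector of
#' \eqn{\sum_j \omega_j w_j w_j^T} with Gaussian weights
#' \eqn{\omega_j = e^{-(w_j^T n)^2/h^2}}, bandwidth h = median initial
#' residual, until the angular change is below 1e-4 rad (max 20 iterations).
#' The sign is fixed so the z-component is non-negative (ties: y, then x).
#'
#' @param p centre point (3-vector)
#' @param neighbors neighbour coordinate matrix (N1 x 3)
#' @return unit normal (numeric length 3)
#' @export
estimateCentreNormal <- function(p, neighbors) {
  if (nrow(neighbors) < 3) stop("normal estimation requires at least 3 neighbours")
  W <- sweep(neighbors, 2, p, `-`)
  if (.collinearOffsets(W)) stop("degenerate geometry: neighbours are collinear")
  as.numeric(.irlsNormalCpp(W, 20L, 1e-4))
}

#' Mean angular deviation between a normal and its neighbours' normals
#'
#' Computes \eqn{(1/N_1)\sum_j \arccos(\mathrm{clamp}(|n_i \cdot n_j|, 0, 1))};
#' the absolute value makes the test independent of normal orientation.
#'
#' @param n unit normal of the centre point
#' @param neighborNormals matrix (N1 x 3) of unit neighbour normals
#' @return mean angle in radians
#' @export
normalConsistency <- function(n, neighborNormals) {
  if (!nrow(neighborNormals)) stop("empty neighbour set")
  ca <- abs(as.numeric(neighborNormals %*% n))
  mean(acos(pmin(ca, 1)))
}

#' Orthogonal projection of points onto a plane
#'
#' Each point maps to its orthogonal foot
#' \eqn{p' = p - (A x + B y + C z - D)(A, B, C)}; the projection is
#' idempotent and \eqn{\lVert p' - p \rVert} equals the absolute
#' point-to-plane distance.
#'
#' @param points numeric matrix (N x 3)
#' @param plane a [Plane-class]
#' @return projected points (N x 3)
#' @export
projectPointsToPlane <- function(points, plane) {
  stopifnot(is(plane, "Plane"))
  nrm <- plane@normal
  resid <- as.numeric(points %*% nrm) - plane@offset
  points - outer(resid, nrm)
}

#' Angular uniformity of projected neighbours (index of dispersion)
#'
#' The disc of radius R about the centre, in the plane, is divided into 40
#' equal-area cells (8 sectors of 45 degrees x 5 annuli with boundary radii
#' \eqn{R\sqrt{d/5}}). With per-cell counts \eqn{num_d} and mean \eqn{\mu},
#' \eqn{\sigma' = \left[\sum_d (num_d - \mu)^2 / 40\right] / \mu} — a
#' variance-to-mean ratio (about 1 for uniform random cover, 0 for exactly
#' equal counts). Points beyond R are discarded; an empty disc yields `Inf`.
#'
#' @param projectedPoints points already on the plane (N x 3)
#' @param centre centre point (3-vector, on the plane)
#' @param plane a [Plane-class]
#' @param R disc radius (m)
#' @return sigma' (dimensionless)
#' @export
angularUniformity <- function(projectedPoints, centre, plane, R) {
  stopifnot(is(plane, "Plane"))
  if (!(R > 0)) stop("R must be positive")
  .sigmaPrimeCpp(projectedPoints, as.numeric(centre), plane@normal, R)
}

#' Detect leaf-surface centre points
#'
#' A point is a centre candidate when (i) its neighbours lie close to the
#' plane through it (mean distance < threshold1), (ii) its robust normal
#' agrees with the neighbours' normals (mean angle < threshold2), and (iii)
#' the neighbours projected onto the plane cover the disc uniformly
#' (sigma' <= threshold3). Candidates within `suppressionRadius` of a
#' stronger (lower sigma') candidate are suppressed. Returns ascending point
#' indices.
#'
#' @param cloud leaf-labelled [PointCloud-class] (all points are treated as
#'   leaf points)
#' @param params a [centreDetectionParams()]
#' @return integer indices of centre points
#' @export
detectLeafCentres <- function(cloud, params) {
  stopifnot(is(cloud, "PointCloud"), inherits(params, "CentreDetectionParams"))
  n <- npoints(cloud)
  if (n == 0) return(integer(0))
  co <- coords(cloud)
  # the neighbour cap must exceed the expected disc population, otherwise
  # truncation empties the outer annuli and corrupts the uniformity test
  sp <- .meanSpacing(co)
  expected <- if (is.finite(sp) && sp > 0)
    pi * params$radius^2 * 0.25 / sp^2 else 150
  maxK <- as.integer(min(max(80, ceiling(2 * expected)), 800, n))
  nb <- .radiusLists(co, params$radius, maxK = maxK, includeSelf = FALSE)
  st <- .centreStatsCpp(co, nb$flat, nb$off, params$radius, params$threshold1,
                        params$threshold2, params$minNeighbors)
  sig <- st$sigma
  if (params$sqrtUniformity) sig <- sqrt(sig)
  cand <- which(!is.na(st$meanDistance) & st$meanDistance < params$threshold1 &
                !is.na(st$meanAngle) & st$meanAngle < params$threshold2 &
                !is.na(sig) & sig <= params$threshold3 &
                st$nNeighbors >= params$minNeighbors)
  if (!length(cand)) return(integer(0))
  # non-maximum suppression, strongest (lowest sigma') first
  ord <- cand[order(sig[cand], cand)]
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted)) {
      d2 <- (co[accepted, 1] - co[i, 1])^2 + (co[accepted, 2] - co[i, 2])^2 +
            (co[accepted, 3] - co[i, 3])^2
      if (any(d2 < params$suppressionRadius^2)) next
    }
    accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Parameters for leaf instance extraction
#'
#' @param geodesicCap maximum geodesic distance from a seed (m); the working
#'   default is twice the average leaf length
#' @param knnK neighbours per point in the geodesic graph
#' @param eps DBSCAN radius for unreached points (m); `NULL` = four times the
#'   mean nearest-neighbour spacing (so that a surface patch of radius eps is
#'   expected to contain about `minPts` points)
#' @param minPts DBSCAN core-point threshold
#' @param minLeafPoints minimum cluster size accepted as a new leaf instance
#' @param mergeRadius watershed basins whose divide path is shorter than this
#'   geodesic distance are merged (two seeds on one strongly curled or
#'   drooped lamina); `NULL` = `geodesicCap / 3`, about two thirds of a leaf
#'   length
#' @return a list of class `SegmentationParams`
#' @export
segmentationParams <- function(geodesicCap, knnK = 10L, eps = NULL,
                               minPts = 10L, minLeafPoints = 40L,
                               mergeRadius = NULL) {
  if (!(geodesicCap > 0)) stop("geodesicCap must be positive")
  if (is.null(mergeRadius)) mergeRadius <- geodesicCap / 3
  structure(list(geodesicCap = geodesicCap, knnK = as.integer(knnK), eps = eps,
                 minPts = as.integer(minPts),
                 minLeafPoints = as.integer(minLeafPoints),
                 mergeRadius = mergeRadius),
            class = "SegmentationParams")
}

# union-find
.ufFind <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

#' Extract individual leaf instances
#'
#' Multi-source geodesic region growing over the k-NN graph: every point is
#' assigned to the seed with the smallest geodesic (graph shortest-path)
#' distance, capped at `geodesicCap`. Points unreached by any seed are
#' clustered with DBSCAN; clusters with at least `minLeafPoints` points
#' become new instances, smaller clusters get id -1 (noise). Instance ids are
#' contiguous integers starting at 0.
#'
#' @param cloud leaf-point [PointCloud-class]
#' @param centres integer seed indices from [detectLeafCentres()] (may be
#'   empty, in which case instances are exactly the DBSCAN clusters)
#' @param params a [segmentationParams()]
#' @return the cloud with `leafId` filled in
#' @export
segmentLeaves <- function(cloud, centres, params) {
  stopifnot(is(cloud, "PointCloud"), inherits(params, "SegmentationParams"))
  n <- npoints(cloud)
  if (n == 0) {
    leafId(cloud) <- integer(0)
    return(cloud)
  }
  co <- coords(cloud)
  ids <- rep(-1L, n)
  nextId <- 0L
  if (length(centres)) {
    g <- .knnGraphCSR(co, k = params$knnK)
    res <- .multiSourceDijkstraCpp(n, g$off, g$to, g$w, as.integer(centres),
                                   params$geodesicCap)
    lab <- res$seed
    # merge watershed basins separated by a shallow divide: for an edge (u, v)
    # crossing two basins, the divide path length is d(u) + w + d(v); basins
    # closer than mergeRadius belong to one lamina (e.g. the two halves of a
    # strongly drooped leaf)
    if (length(centres) > 1L && params$mergeRadius > 0) {
      parent <- seq_len(length(centres))
      from <- rep(seq_len(n), diff(g$off))
      to <- g$to + 1L
      lu <- lab[from]; lv <- lab[to]
      crossing <- which(lu > 0L & lv > 0L & lu != lv)
      if (length(crossing)) {
        divide <- res$distance[from[crossing]] + g$w[crossing] +
                  res$distance[to[crossing]]
        for (e in crossing[divide <= params$mergeRadius]) {
          ra <- .ufFind(parent, lab[from[e]])
          rb <- .ufFind(parent, lab[to[e]])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
        lab[lab > 0L] <- vapply(lab[lab > 0L], function(x) .ufFind(parent, x), 0L)
      }
    }
    reached <- lab > 0L
    ids[reached] <- lab[reached] - 1L
    nextId <- max(lab) + 1L
  }
  un <- which(ids < 0L)
  if (length(un)) {
    eps <- params$eps
    if (is.null(eps)) {
      sp <- .meanSpacing(co)
      eps <- 4 * sp
    }
    cl <- .dbscan(co[un, , drop = FALSE], eps = eps, minPts = params$minPts)
    if (any(cl > 0L)) {
      sizes <- tabulate(cl)
      for (k in which(sizes >= params$minLeafPoints)) {
        ids[un[cl == k]] <- nextId
        nextId <- nextId + 1L
      }
    }
  }
  # compact ids to a contiguous range (seeds that captured no points drop out)
  used <- sort(unique(ids[ids >= 0L]))
  if (length(used)) ids[ids >= 0L] <- match(ids[ids >= 0L], used) - 1L
  if (!length(cloud@classLabel)) classLabel(cloud) <- rep("leaf", n)
  leafId(cloud) <- ids
  cloud
}
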