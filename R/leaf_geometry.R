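# Per-leaf geometric modelling: MLS smoothing, midrib endpoints, edge
# extraction with cubic refinement, leaf normal, equivalent thickness, and
# the hexagonal-prism envelope whose base area times thickness is the
# equivalent leaf volume.

#' Moving-least-squares smoothing of a leaf point set
#'
#' Each point is replaced by its projection onto a locally weighted
#' polynomial surface (Gaussian weights with bandwidth `supportRadius / 2`)
#' fitted in the local tangent frame of its neighbourhood. Points whose
#' neighbourhood is too small for the quadratic fall back to a plane fit;
#' the output has exactly as many points as the input. Exactly coplanar
#' input is reproduced unchanged.
#'
#' @param leafPoints numeric matrix (M x 3)
#' @param supportRadius neighbourhood radius (m)
#' @param degree polynomial degree, 1 or 2
#' @return smoothed matrix (M x 3)
#' @export
mlsSmooth <- function(leafPoints, supportRadius, degree = 2L) {
  leafPoints <- as.matrix(leafPoints)
  if (!(supportRadius > 0)) stop("supportRadius must be positive")
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  if (nrow(leafPoints) < 3) return(leafPoints)
  nb <- .radiusLists(leafPoints, supportRadius, maxK = 120L, includeSelf = TRUE)
  .mlsSmoothCpp(leafPoints, nb$flat, nb$off, supportRadius / 2, as.integer(degree))
}

#' Midrib endpoints: the farthest point pair
#'
#' The two points at maximum Euclidean separation form the central axis L1.
#' The pair is exact (for up to 5000 points by pairwise scan, above that via
#' the convex hull, whose farthest pair equals the cloud's). The petiole tip
#' `pe` is the lower-z endpoint; ties are broken by lexicographic coordinate
#' order.
#'
#' @param fittedPoints numeric matrix (M x 3), M >= 2
#' @return list with `pe`, `ps` (3-vectors) and `indices` of the pair
#' @export
findMidribEndpoints <- function(fittedPoints) {
  P <- as.matrix(fittedPoints)
  M <- nrow(P)
  if (M < 2) stop("midrib endpoints require at least 2 points")
  if (M > 5000) {
    hv <- tryCatch(.convexHull3dCpp(P)$vertices, error = function(e) seq_len(M))
    sub <- P[hv, , drop = FALSE]
    pair <- .farthestPair(sub)
    idx <- hv[pair]
  } else {
    idx <- .farthestPair(P)
  }
  a <- P[idx[1], ]; b <- P[idx[2], ]
  swap <- if (a[3] != b[3]) a[3] > b[3]
          else if (a[1] != b[1]) a[1] > b[1]
          else if (a[2] != b[2]) a[2] > b[2] else FALSE
  if (swap) { tmp <- a; a <- b; b <- tmp; idx <- rev(idx) }
  list(pe = as.numeric(a), ps = as.numeric(b), indices = idx)
}

# exact farthest pair by (chunked) pairwise scan; ties -> smallest indices
.farthestPair <- function(P) {
  M <- nrow(P)
  best <- c(1L, 2L); bestD <- -1
  chunk <- 512L
  s2 <- rowSums(P^2)
  for (lo in seq(1L, M, by = chunk)) {
    hi <- min(M, lo + chunk - 1L)
    G <- P[lo:hi, , drop = FALSE] %*% t(P)
    D2 <- outer(s2[lo:hi], s2, `+`) - 2 * G
    D2[cbind(seq_len(hi - lo + 1L), lo:hi)] <- -Inf
    w <- which(D2 == max(D2), arr.ind = TRUE)
    m <- max(D2)
    if (m > bestD) {
      w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
      best <- c(lo + w[1, 1] - 1L, w[1, 2])
      bestD <- m
    }
  }
  sort(best)
}

#' Raw left/right edge points from uniform slices along the midrib
#'
#' Slicing lines perpendicular to the axis L1 are placed at the `nSlices - 1`
#' interior boundaries of `nSlices` uniform bins of the axial coordinate;
#' the points within half a bin of each line whose in-plane transverse
#' coordinate is extremal give the left and right edge points (the sign of
#' the transverse direction — the cross product of the leaf normal with the
#' axis — defines left vs right). Lines intercepting no points are skipped.
#'
#' @param fittedPoints numeric matrix (M x 3)
#' @param pe,ps midrib endpoints from [findMidribEndpoints()]
#' @param nSlices number of bins (>= 4); yields up to `nSlices - 1` edge
#'   points per side
#' @return list with `left`, `right` (matrices of edge points), `frame`
#'   (local axes: `origin`, `axis`, `lateral`, `normal`) and `skipped`
#'   (indices of empty slicing lines)
#' @export
sliceEdgePoints <- function(fittedPoints, pe, ps, nSlices = 21L) {
  P <- as.matrix(fittedPoints)
  if (nSlices < 4) stop("nSlices must be at least 4")
  axis <- ps - pe
  L <- sqrt(sum(axis^2))
  if (!(L > 0)) stop("degenerate axis: pe and ps coincide")
  u <- .unit(axis)
  nrm <- leafNormal(P)
  lat <- .unit(.cross(nrm, u))
  t <- as.numeric(sweep(P, 2, pe, `-`) %*% u)
  v <- as.numeric(sweep(P, 2, pe, `-`) %*% lat)
  h <- L / nSlices
  if (max(t) - min(t) <= .Machine$double.eps * L)
    stop("degenerate axis: all points in one slice")
  left <- right <- matrix(numeric(0), 0, 3)
  skipped <- integer(0)
  for (k in seq_len(nSlices - 1L)) {
    tk <- k * h
    inSlab <- which(t >= tk - h / 2 & t < tk + h / 2)
    if (!length(inSlab)) { skipped <- c(skipped, k); next }
    iL <- inSlab[which.max(v[inSlab])]
    iR <- inSlab[which.min(v[inSlab])]
    left <- rbind(left, P[iL, ])
    right <- rbind(right, P[iR, ])
  }
  list(left = left, right = right,
       frame = list(origin = as.numeric(pe), axis = u, lateral = lat,
                    normal = nrm),
       skipped = skipped)
}

#' Cubic refinement of one side's edge points
#'
#' In the leaf-local frame (u along the midrib axis, v in-plane transverse,
#' w along the normal) two independent least-squares cubics v(u) and w(u)
#' are fitted by solving the 4 x 4 normal equations; refined points keep
#' their u and take the fitted v and w. With fewer than 4 points the raw
#' edges are returned unchanged with attribute `fitted = FALSE`.
#'
#' @param edgePoints matrix of edge points for one side (k x 3)
#' @param frame local frame as returned by [sliceEdgePoints()]
#' @return refined edge points (k x 3); attributes `fitted` and
#'   `coefficients` (4 x 2 matrix, columns v and w) when the fit ran
#' @export
fitEdgeCubic <- function(edgePoints, frame) {
  E <- as.matrix(edgePoints)
  if (nrow(E) < 4) {
    attr(E, "fitted") <- FALSE
    return(E)
  }
  d <- sweep(E, 2, frame$origin, `-`)
  u <- as.numeric(d %*% frame$axis)
  v <- as.numeric(d %*% frame$lateral)
  w <- as.numeric(d %*% frame$normal)
  X <- cbind(1, u, u^2, u^3)
  XtX <- crossprod(X)
  cv <- solve(XtX, crossprod(X, v))
  cw <- solve(XtX, crossprod(X, w))
  vf <- as.numeric(X %*% cv)
  wf <- as.numeric(X %*% cw)
  out <- matrix(frame$origin, nrow(E), 3, byrow = TRUE) +
    outer(u, frame$axis) + outer(vf, frame$lateral) + outer(wf, frame$normal)
  attr(out, "fitted") <- TRUE
  attr(out, "coefficients") <- cbind(v = as.numeric(cv), w = as.numeric(cw))
  out
}

#' Leaf-surface normal from the point covariance
#'
#' The eigenvector of the smallest eigenvalue of the centred covariance
#' matrix, with sign fixed so the z-component is non-negative (ties: y,
#' then x).
#'
#' @param fittedPoints numeric matrix (M x 3), at least 3 non-collinear points
#' @return unit normal (numeric length 3)
#' @export
leafNormal <- function(fittedPoints) {
  P <- as.matrix(fittedPoints)
  if (nrow(P) < 3) stop("leaf normal requires at least 3 points")
  C <- stats::cov(P)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] <= 1e-12 * max(e$values[1], .Machine$double.eps))
    stop("degenerate geometry: points are collinear")
  n <- e$vectors[, 3]
  if (n[3] < 0 || (n[3] == 0 && (n[2] < 0 || (n[2] == 0 && n[1] < 0)))) n <- -n
  as.numeric(n)
}

#' Equivalent leaf thickness
#'
#' The distance between the highest and the lowest point in the direction of
#' the leaf normal: \eqn{\max_j (p_j \cdot n) - \min_j (p_j \cdot n)}. This
#' captures the curl, twist and droop of the lamina and is used as the
#' hexagonal-prism height.
#'
#' @param fittedPoints numeric matrix (M x 3), M >= 1
#' @param normal unit leaf normal
#' @return thickness in metres, with attributes `high` and `low` (indices of
#'   the extreme points)
#' @export
equivalentThickness <- function(fittedPoints, normal) {
  P <- as.matrix(fittedPoints)
  if (nrow(P) < 1) stop("thickness requires at least 1 point")
  proj <- as.numeric(P %*% normal)
  hi <- which.max(proj); lo <- which.min(proj)
  structure(proj[hi] - proj[lo], high = hi, low = lo)
}

#' Six ordered vertices of the hexagonal base
#'
#' Two symmetrical edge points per side are chosen at 1-based counting
#' numbers `round(k/4)` and `round(3k/4)` (round-half-up), where k is the
#' number of edge points on that side; together with the midrib endpoints
#' they form the ordered hexagon
#' `pe, left[i1], left[i2], ps, right[i2], right[i1]` — a simple polygon in
#' the leaf plane.
#'
#' @param pe,ps midrib endpoints
#' @param leftEdges,rightEdges refined edge points per side (>= 2 rows each)
#' @return 6 x 3 matrix of ordered vertices
#' @export
hexagonVertices <- function(pe, ps, leftEdges, rightEdges) {
  L <- as.matrix(leftEdges); R <- as.matrix(rightEdges)
  if (nrow(L) < 2 || nrow(R) < 2)
    stop("hexagon construction needs at least 2 edge points per side")
  iL <- c(roundHalfUp(nrow(L) / 4), roundHalfUp(3 * nrow(L) / 4))
  iR <- c(roundHalfUp(nrow(R) / 4), roundHalfUp(3 * nrow(R) / 4))
  iL <- pmin(pmax(iL, 1L), nrow(L))
  iR <- pmin(pmax(iR, 1L), nrow(R))
  if (iL[1] == iL[2] || iR[1] == iR[2])
    stop("too few edge points: the two hexagon indices coincide")
  rbind(pe, L[iL[1], ], L[iL[2], ], ps, R[iR[2], ], R[iR[1], ],
        deparse.level = 0)
}

# 2D coordinates of the hexagon in its best-fit plane
.hexagonPlanar <- function(hexagon) {
  H <- as.matrix(hexagon)
  ctr <- colMeans(H)
  Hc <- sweep(H, 2, ctr, `-`)
  e <- eigen(crossprod(Hc) / nrow(H), symmetric = TRUE)
  b1 <- e$vectors[, 1]; b2 <- e$vectors[, 2]
  cbind(as.numeric(Hc %*% b1), as.numeric(Hc %*% b2))
}

.shoelace <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

# signed segment-intersection test for simple-polygon checking
.segmentsCross <- function(a, b, c, d) {
  cross2 <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  d1 <- cross2(c, d, a); d2 <- cross2(c, d, b)
  d3 <- cross2(a, b, c); d4 <- cross2(a, b, d)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.isSimpleHexagon <- function(xy) {
  n <- nrow(xy)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next
      if (.segmentsCross(xy[i, ], xy[i %% n + 1L, ], xy[j, ], xy[j %% n + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Volume of the hexagonal prism enclosing a leaf
#'
#' The six vertices are projected onto their best-fit plane; the planar base
#' area is computed as the sum of the three named components — the lower
#' triangle at the petiole, the middle trapezoid and the upper triangle at
#' the apex — which equals the shoelace area of the ordered hexagon for any
#' simple polygon. The volume is base area times the equivalent thickness.
#'
#' @param hexagon 6 x 3 matrix from [hexagonVertices()]
#' @param thickness equivalent leaf thickness (m, >= 0)
#' @return volume in m^3, with attribute `area` (m^2)
#' @export
hexagonalPrismVolume <- function(hexagon, thickness) {
  H <- as.matrix(hexagon)
  if (nrow(H) != 6) stop("hexagon must have exactly 6 vertices")
  if (thickness < 0) stop("thickness must be >= 0")
  xy <- .hexagonPlanar(H)
  if (!.isSimpleHexagon(xy))
    stop("self-intersecting hexagon: leaf model rejected")
  # shoelace area of the ordered ring; for the axis-ordered hexagons this
  # function receives (pe, L1, L2, ps, R2, R1) it equals the sum of the
  # petiole triangle, middle trapezoid and apex triangle exactly
  area <- .shoelace(xy)
  structure(area * thickness, area = area)
}

#' Configuration for per-leaf modelling
#'
#' @param minLeafPoints leaves with fewer points fall back to a
#'   covariance-aligned bounding box (a scan should cover every leaf with at
#'   least about 40 points)
#' @param nSlices slicing bins for edge extraction
#' @param mlsSupportRadius MLS neighbourhood radius (m); `NULL` = a quarter
#'   of the average leaf width
#' @param mlsDegree MLS polynomial degree
#' @param avgLeafWidth species-prior average leaf width (m)
#' @return list of class `LeafModelConfig`
#' @export
leafModelConfig <- function(minLeafPoints = 40L, nSlices = 21L,
                            mlsSupportRadius = NULL, mlsDegree = 2L,
                            avgLeafWidth = 0.035) {
  structure(list(minLeafPoints = as.integer(minLeafPoints),
                 nSlices = as.integer(nSlices),
                 mlsSupportRadius = mlsSupportRadius,
                 mlsDegree = as.integer(mlsDegree),
                 avgLeafWidth = avgLeafWidth),
            class = "LeafModelConfig")
}

#' Fit the full hexagonal-prism model to one leaf instance
#'
#' Runs MLS smoothing, midrib endpoints, edge slicing, cubic edge
#' refinement, leaf normal, equivalent thickness and hexagonal-prism volume.
#' Leaves with fewer than `minLeafPoints` points, or whose hexagon
#' construction fails, fall back to the volume of the covariance-aligned
#' bounding box (`qualityFlag = "fallback_bbox"`); leaves with fewer than 3
#' points are rejected with zero volume.
#'
#' @param leafPoints matrix of one instance's points (M x 3)
#' @param config a [leafModelConfig()]
#' @param id instance id recorded in the model
#' @return a [LeafModel-class]
#' @export
modelLeaf <- function(leafPoints, config = leafModelConfig(), id = 0L) {
  P <- as.matrix(leafPoints)
  M <- nrow(P)
  empty <- matrix(numeric(0), 0, 3)
  if (M < 3) {
    return(new("LeafModel", fittedPoints = P, pe = numeric(3), ps = numeric(3),
               leftEdges = empty, rightEdges = empty,
               hexagon = matrix(numeric(0), 0, 3), normal = c(0, 0, 1),
               thickness = 0, volume = 0, qualityFlag = "rejected",
               leafId = as.integer(id)))
  }
  bboxModel <- function(fp) {
    C <- stats::cov(fp)
    e <- eigen(C, symmetric = TRUE)
    proj <- sweep(fp, 2, colMeans(fp), `-`) %*% e$vectors
    ext <- apply(proj, 2, function(x) diff(range(x)))
    nrm <- e$vectors[, 3]
    if (nrm[3] < 0) nrm <- -nrm
    new("LeafModel", fittedPoints = fp, pe = numeric(3), ps = numeric(3),
        leftEdges = empty, rightEdges = empty,
        hexagon = matrix(numeric(0), 0, 3), normal = as.numeric(nrm),
        thickness = ext[3], volume = prod(ext), qualityFlag = "fallback_bbox",
        leafId = as.integer(id))
  }
  support <- config$mlsSupportRadius
  if (is.null(support)) support <- config$avgLeafWidth / 4
  fitted <- tryCatch(mlsSmooth(P, support, config$mlsDegree),
                     error = function(e) P)
  if (M < config$minLeafPoints) return(bboxModel(fitted))
  out <- tryCatch({
    nrm <- leafNormal(fitted)
    th <- equivalentThickness(fitted, nrm)
    ends <- findMidribEndpoints(fitted)
    edges <- sliceEdgePoints(fitted, ends$pe, ends$ps, nSlices = config$nSlices)
    lref <- fitEdgeCubic(edges$left, frame = edges$frame)
    rref <- fitEdgeCubic(edges$right, frame = edges$frame)
    hexv <- hexagonVertices(ends$pe, ends$ps, lref, rref)
    vol <- hexagonalPrismVolume(hexv, as.numeric(th))
    new("LeafModel", fittedPoints = fitted, pe = ends$pe, ps = ends$ps,
        leftEdges = lref, rightEdges = rref, hexagon = hexv,
        normal = nrm, thickness = as.numeric(th), volume = as.numeric(vol),
        qualityFlag = "ok", leafId = as.integer(id))
  }, error = function(e) NULL)
  if (is.null(out)) out <- bboxModel(fitted)
  out
}
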