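# branch cylinder fitting (wood volume) and alpha-shape crown volume

#' Group wood points into branch segments
#'
#' Connected components of the k-NN graph (edges capped at five times the
#' mean nearest-neighbour spacing) are recursively bisected along their
#' widest principal axis until each group is at most `segmentLength` long
#' and tube-like (transverse spread compatible with a single branch), so
#' that one least-squares cylinder is a sensible model for each group.
#' Deterministic for a fixed cloud.
#'
#' @param woodCloud wood-point [PointCloud-class]
#' @param segmentLength maximum segment extent along the branch axis (m)
#' @param maxTransverse transverse RMS spread (m) below which a group always
#'   counts as a single branch; wider groups are still accepted when their
#'   cross-section is isotropic (one fat cylinder) rather than multi-modal
#'   (several parallel branches)
#' @return list of integer index vectors, one per segment
#' @export
segmentBranchPoints <- function(woodCloud, segmentLength = 0.2,
                                maxTransverse = 0.015) {
  stopifnot(is(woodCloud, "PointCloud"))
  n <- npoints(woodCloud)
  if (n == 0) return(list())
  co <- coords(woodCloud)
  if (n == 1) return(list(1L))
  sp <- .meanSpacing(co)
  cap <- 5 * sp
  g <- .knnGraphCSR(co, k = 10L, edgeCap = cap)
  from <- rep(seq_len(n), diff(g$off))
  to <- g$to + 1L
  components <- function(f, t) {
    if (!length(f)) return(seq_len(n))
    gr <- igraph::graph_from_edgelist(cbind(f, t), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
    igraph::components(gr)$membership
  }
  comp <- components(from, to)

  # local principal directions, for refining runs that mix several branches
  dirRadius <- max(0.012, 4 * sp)
  nbd <- .radiusLists(co, dirRadius, maxK = 60L, includeSelf = TRUE)
  dirs <- .principalDirectionsCpp(co, nbd$flat, nbd$off)
  agree <- abs(rowSums(dirs[from, , drop = FALSE] * dirs[to, , drop = FALSE]))
  dirOK <- agree >= cos(25 * pi / 180)

  out <- list()
  # strict = transverse spread alone decides; the isotropic-cross-section
  # escape (one fat cylinder) is only trusted at the top level, because a
  # star-shaped junction blob is also isotropic in cross-section
  tubeStats <- function(idx, strict = FALSE) {
    sub <- co[idx, , drop = FALSE]
    e <- eigen(stats::cov(sub), symmetric = TRUE)
    t <- as.numeric(sweep(sub, 2, colMeans(sub), `-`) %*% e$vectors[, 1])
    transverse <- sqrt(max(e$values[2], 0))
    tube <- transverse <= maxTransverse ||
      (!strict && transverse <= 0.05 &&
       transverse <= 2 * sqrt(max(e$values[3], 0)))
    list(t = t, len = diff(range(t)), tube = tube)
  }
  emitRuns <- function(idx, t, len) {
    # cut a tube-like group into equal runs of at most segmentLength
    nSeg <- max(1L, ceiling(len / segmentLength))
    br <- seq(min(t), max(t), length.out = nSeg + 1L)
    bin <- pmin(pmax(findInterval(t, br, rightmost.closed = TRUE), 1L), nSeg)
    for (b in sort(unique(bin)))
      out[[length(out) + 1L]] <<- sort(idx[bin == b])
  }
  # recursive median bisection for groups mixing several branches
  bisect <- function(idx) {
    if (length(idx) < 12L) { out[[length(out) + 1L]] <<- sort(idx); return() }
    st <- tubeStats(idx)
    if (st$tube) { emitRuns(idx, st$t, st$len); return() }
    cutAt <- stats::median(st$t)
    lo <- idx[st$t <= cutAt]; hi <- idx[st$t > cutAt]
    if (!length(lo) || !length(hi)) { out[[length(out) + 1L]] <<- sort(idx); return() }
    bisect(lo); bisect(hi)
  }
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    if (length(idx) < 12L) { out[[length(out) + 1L]] <- sort(idx); next }
    st <- tubeStats(idx)
    if (st$tube) {
      # a clean single branch (however fat): equal runs, no direction field
      emitRuns(idx, st$t, st$len)
    } else {
      # a whole-crown component: cut direction-disagreeing edges, then
      # bisect each resulting branch-wise sub-component
      inC <- logical(n); inC[idx] <- TRUE
      sel <- inC[from] & inC[to] & dirOK
      sub <- components(from[sel], to[sel])[idx]
      for (scid in sort(unique(sub))) bisect(idx[sub == scid])
    }
  }
  out
}

#' Least-squares cylinder fit to a branch segment
#'
#' The axis direction is initialised from the principal component; the axis
#' offset and direction are then refined by nonlinear least squares on the
#' point-to-axis distances (Levenberg-Marquardt). The radius is recovered
#' from the radial-distance moments under a Rician error model
#' (\eqn{r^2 = m_2 - b}, \eqn{b = m_2 - \sqrt{2 m_2^2 - m_4}}), which
#' removes the upward noise bias that a plain mean distance suffers on
#' branches whose radius is comparable to the scanner noise. On
#' non-convergence the PCA axis with the median distance as radius is
#' returned (`converged = FALSE`). Axis endpoints are the extreme
#' projections of the points onto the fitted axis.
#'
#' @param segmentPoints matrix (>= 6 points, not all collinear)
#' @return a [CylinderModel-class]
#' @export
fitCylinder <- function(segmentPoints) {
  P <- as.matrix(segmentPoints)
  if (nrow(P) < 6) stop("cylinder fitting requires at least 6 points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr, `-`)
  e <- eigen(crossprod(Pc) / nrow(P), symmetric = TRUE)
  if (e$values[2] <= 1e-12 * max(e$values[1], .Machine$double.eps))
    stop("degenerate geometry: collinear points cannot define a cylinder")
  d0 <- e$vectors[, 1]
  b1 <- e$vectors[, 2]; b2 <- e$vectors[, 3]

  axisDist <- function(par) {
    # par = (a, b, th1, th2): axis through ctr + a b1 + b b2 with direction
    # d0 tilted by (th1, th2) towards b1/b2
    d <- .unit(d0 + par[3] * b1 + par[4] * b2)
    o <- ctr + par[1] * b1 + par[2] * b2
    rel <- sweep(P, 2, o, `-`)
    proj <- as.numeric(rel %*% d)
    sqrt(pmax(rowSums(rel^2) - proj^2, 0))
  }
  resFun <- function(par) {
    dd <- axisDist(par)
    dd - mean(dd)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(0, 0, 0, 0), fn = resFun,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  par <- if (converged) fit$par else c(0, 0, 0, 0)
  dd <- axisDist(par)
  # Rician moment-matched radius: unbiased for thick and noise-dominated
  # thin branches alike
  ricianRadius <- function(dd) {
    m2 <- mean(dd^2); m4 <- mean(dd^4)
    disc <- 2 * m2^2 - m4
    if (disc <= 0) return(mean(dd))
    b <- min(max(m2 - sqrt(disc), 0), m2)
    sqrt(m2 - b)
  }
  r <- if (converged) ricianRadius(dd) else stats::median(dd)
  # a thin or incomplete arc of points also lies on an arbitrarily fat
  # cylinder; the radial spread about the principal axis bounds the credible
  # radius (for a fully sampled tube, lambda2 + lambda3 equals r^2)
  rObs <- sqrt(max(e$values[2], 0) + max(e$values[3], 0))
  if (!is.finite(r) || r > 1.5 * rObs) {
    par <- c(0, 0, 0, 0)
    dd <- axisDist(par)
    r <- max(min(rObs, ricianRadius(dd)), .Machine$double.eps)
    converged <- FALSE
  }
  if (!(r > 0)) r <- max(dd, .Machine$double.eps)
  d <- .unit(d0 + par[3] * b1 + par[4] * b2)
  o <- ctr + par[1] * b1 + par[2] * b2
  rel <- sweep(P, 2, o, `-`)
  proj <- as.numeric(rel %*% d)
  a0 <- o + min(proj) * d
  a1 <- o + max(proj) * d
  L <- max(proj) - min(proj)
  # circumferential coverage around the fitted axis
  u1 <- .unit(.cross(d, if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  u2 <- .cross(d, u1)
  az <- atan2(as.numeric(rel %*% u2), as.numeric(rel %*% u1))
  cov36 <- length(unique(pmin(floor((az + pi) / (2 * pi) * 36), 35))) / 36
  new("CylinderModel", axisStart = as.numeric(a0), axisEnd = as.numeric(a1),
      radius = r, volume = pi * r^2 * L,
      rmsResidual = sqrt(mean((dd - r)^2)), converged = converged,
      circumCoverage = cov36)
}

# fit one group; when the cylinder wraps only a narrow azimuthal arc (a
# curved branch chain lying on a spuriously fat cylinder), bisect the group
# along its axis and refit the straighter halves
.fitCylindersRecursive <- function(P, minCoverage = 0.4, depth = 0L) {
  cyl <- tryCatch(suppressWarnings(fitCylinder(P)), error = function(e) NULL)
  if (is.null(cyl)) return(list())
  if (cyl@circumCoverage >= minCoverage || nrow(P) < 24L || depth >= 4L)
    return(list(cyl))
  e <- eigen(stats::cov(P), symmetric = TRUE)
  t <- as.numeric(sweep(P, 2, colMeans(P), `-`) %*% e$vectors[, 1])
  cutAt <- stats::median(t)
  lo <- which(t <= cutAt); hi <- which(t > cutAt)
  if (length(lo) < 6L || length(hi) < 6L) return(list(cyl))
  c(.fitCylindersRecursive(P[lo, , drop = FALSE], minCoverage, depth + 1L),
    .fitCylindersRecursive(P[hi, , drop = FALSE], minCoverage, depth + 1L))
}

#' Total wood volume of a set of cylinders
#'
#' @param cylinders list of [CylinderModel-class] objects (may be empty)
#' @return summed volume (m^3)
#' @export
woodVolume <- function(cylinders) {
  if (!length(cylinders)) return(0)
  sum(vapply(cylinders, volume, 0))
}

#' Crown volume from the 3D alpha shape
#'
#' Points at or above `crownBaseHeight` are retained; `alpha = Inf` gives
#' the convex hull volume, a finite alpha gives the volume of the basic
#' alpha complex (Delaunay tetrahedra with circumradius at most alpha) —
#' non-decreasing in alpha and equal to the hull at infinity.
#'
#' @param cloud a [PointCloud-class] (vegetative points)
#' @param crownBaseHeight crown base (m); points below are dropped
#' @param alpha alpha parameter in metres, or `Inf` for the convex hull
#' @return a [CrownModel-class]
#' @export
crownVolume <- function(cloud, crownBaseHeight = -Inf, alpha = Inf) {
  stopifnot(is(cloud, "PointCloud"))
  co <- coords(cloud)
  keep <- co[, 3] >= crownBaseHeight
  P <- co[keep, , drop = FALSE]
  if (nrow(P) < 4) stop("crown volume requires at least 4 points above the base")
  vol <- if (is.infinite(alpha)) {
    .convexHull3dCpp(P)$volume
  } else {
    if (!(alpha > 0)) stop("alpha must be positive (or Inf)")
    d <- .delaunay3dCpp(P)
    sum(d$volume[is.finite(d$circumradius) & d$circumradius <= alpha])
  }
  new("CrownModel", crownPoints = P, alpha = alpha, volume = vol,
      crownBaseHeight = if (is.finite(crownBaseHeight)) crownBaseHeight
                        else min(P[, 3]))
}

#' Estimate the crown base height
#'
#' The crown base is taken as the height of the lowest wood point lying
#' farther than twice the trunk radius from the (vertical) trunk axis; the
#' trunk axis and radius are estimated from the lowest decile of wood
#' points. Falls back to the lowest leaf point when no such wood point
#' exists.
#'
#' @param cloud labelled [PointCloud-class]
#' @return crown base height (m)
#' @export
estimateCrownBase <- function(cloud) {
  stopifnot(is(cloud, "PointCloud"))
  lab <- classLabel(cloud)
  if (!length(lab)) stop("crown base estimation requires class labels")
  co <- coords(cloud)
  wood <- co[lab == "wood", , drop = FALSE]
  leaf <- co[lab == "leaf", , drop = FALSE]
  if (!nrow(wood)) {
    if (!nrow(leaf)) stop("no labelled points")
    return(min(leaf[, 3]))
  }
  zq <- quantile(wood[, 3], 0.1)
  base <- wood[wood[, 3] <= zq, , drop = FALSE]
  axis <- c(median(base[, 1]), median(base[, 2]))
  rTrunk <- median(sqrt((base[, 1] - axis[1])^2 + (base[, 2] - axis[2])^2))
  rad <- sqrt((wood[, 1] - axis[1])^2 + (wood[, 2] - axis[2])^2)
  off <- wood[rad > 2 * rTrunk, , drop = FALSE]
  if (nrow(off)) min(off[, 3]) else if (nrow(leaf)) min(leaf[, 3]) else min(wood[, 3])
}

# cylinder volume clipped to z >= base (used for the crown-restricted total)
.clipCylinderVolume <- function(cyl, base) {
  z0 <- min(cyl@axisStart[3], cyl@axisEnd[3])
  z1 <- max(cyl@axisStart[3], cyl@axisEnd[3])
  if (z1 <= base) return(0)
  frac <- if (z1 > z0) min(1, (z1 - base) / (z1 - z0)) else 1
  cyl@volume * frac
}
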