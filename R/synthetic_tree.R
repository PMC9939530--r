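# Parametric synthetic trees with TLS-like surface sampling and analytic
# ground truth. The lamina is an elliptic (or fan-shaped) planform with a
# quadratic out-of-plane curl and a rotation of the distal half (droop); the
# same hexagonal-prism definitions used by the fitting pipeline, evaluated on
# a dense noiseless surface, give the per-leaf true volume, so that
# pipeline-vs-truth comparisons isolate segmentation and fitting error.

#' Specification of one synthetic leaf
#'
#' @param length blade length along the midrib (m)
#' @param width maximum blade width (m)
#' @param curlAmplitude out-of-plane bowing amplitude (m); the lamina offset is
#'   `curlAmplitude * (2u - 1)^2` for relative midrib position u in `[0, 1]`
#' @param droopAngle rotation of the distal half about the mid-width axis
#'   (radians, in `[0, pi/2)`)
#' @param attachment petiole-tip position (3-vector, m)
#' @param zenith,azimuth orientation of the leaf normal (radians)
#' @param shape `"elliptic"` or `"fan"` (annular sector, ginkgo-like)
#' @return a validated list of class `SyntheticLeafSpec`
#' @export
syntheticLeafSpec <- function(length = 0.05, width = 0.035, curlAmplitude = 0.005,
                              droopAngle = 0.2, attachment = c(0, 0, 0),
                              zenith = 0, azimuth = 0,
                              shape = c("elliptic", "fan")) {
  shape <- match.arg(shape)
  if (!(length > 0) || !(width > 0)) stop("leaf length and width must be positive")
  if (curlAmplitude < 0) stop("curlAmplitude must be >= 0")
  if (droopAngle < 0 || droopAngle >= pi / 2) stop("droopAngle must lie in [0, pi/2)")
  structure(list(length = length, width = width, curlAmplitude = curlAmplitude,
                 droopAngle = droopAngle, attachment = attachment,
                 zenith = zenith, azimuth = azimuth, shape = shape),
            class = "SyntheticLeafSpec")
}

# local lamina surface: x along the midrib in [-L/2, L/2] (petiole at -L/2),
# y transverse, z out of plane; returns points for given (x, y) planform pairs
.laminaLift <- function(xy, spec) {
  L <- spec$length
  u <- (xy[, 1] + L / 2) / L
  z <- spec$curlAmplitude * (2 * u - 1)^2
  pts <- cbind(xy, z)
  distal <- xy[, 1] > 0
  if (any(distal) && spec$droopAngle > 0) {
    a <- spec$droopAngle
    x <- pts[distal, 1]; zz <- pts[distal, 3]
    pts[distal, 1] <- x * cos(a) + zz * sin(a)
    pts[distal, 3] <- -x * sin(a) + zz * cos(a)
  }
  pts
}

# uniform planform samples in the local frame (deterministic given RNG state)
.laminaPlanform <- function(spec, n) {
  L <- spec$length; W <- spec$width
  if (spec$shape == "elliptic") {
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < n) {
      m <- max(16L, ceiling((n - nrow(out)) * 4 / pi * 1.2))
      x <- runif(m, -L / 2, L / 2)
      y <- runif(m, -W / 2, W / 2)
      keep <- (x / (L / 2))^2 + (y / (W / 2))^2 <= 1
      out <- rbind(out, cbind(x, y)[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  } else {
    # annular sector with apex towards the petiole; outer radius r0 + L
    r0 <- L / 3
    r1 <- r0 + L
    halfAng <- asin(min(0.999, (W / 2) / r1))
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < n) {
      m <- max(16L, 2L * (n - nrow(out)))
      r <- sqrt(runif(m, r0^2, r1^2))
      th <- runif(m, -halfAng, halfAng)
      out <- rbind(out, cbind(r * cos(th) - (r0 + L / 2), r * sin(th)))
    }
    out[seq_len(n), , drop = FALSE]
  }
}

.planformArea <- function(spec) {
  if (spec$shape == "elliptic") pi * spec$length * spec$width / 4
  else {
    r0 <- spec$length / 3; r1 <- r0 + spec$length
    halfAng <- asin(min(0.999, (spec$width / 2) / r1))
    halfAng * (r1^2 - r0^2)
  }
}

# dense deterministic grid on the noiseless lamina (for ground truth)
.laminaTruthGrid <- function(spec, nGrid = 91L) {
  # odd nGrid keeps the exact apex (y = 0) and midline (x = 0) grid lines,
  # so the analytic extremes of the lamina are present in the truth sample
  L <- spec$length; W <- spec$width
  g <- seq(-0.5, 0.5, length.out = nGrid)
  xy <- as.matrix(expand.grid(x = g * L, y = g * W))
  if (spec$shape == "elliptic") {
    keep <- (xy[, 1] / (L / 2))^2 + (xy[, 2] / (W / 2))^2 <= 1
  } else {
    r0 <- L / 3; r1 <- r0 + L
    halfAng <- asin(min(0.999, (W / 2) / r1))
    cx <- xy[, 1] + (r0 + L / 2)
    r <- sqrt(cx^2 + xy[, 2]^2)
    th <- atan2(xy[, 2], cx)
    keep <- r >= r0 & r <= r1 & abs(th) <= halfAng
  }
  .laminaLift(xy[keep, , drop = FALSE], spec)
}

# orientation + attachment: rotate the local frame so +z maps to the
# (zenith, azimuth) direction, then pin the petiole tip to the attachment
.placeLeaf <- function(localPts, spec) {
  R <- rotZ(spec$azimuth) %*% rotY(spec$zenith)
  petiole <- .laminaLift(matrix(c(-spec$length / 2, 0), 1, 2), spec)
  world <- localPts %*% t(R)
  shift <- spec$attachment - as.numeric(petiole %*% t(R))
  sweep(world, 2, shift, `+`)
}

# ground-truth geometry of one leaf: the same hexagonal-prism definitions as
# the fitting pipeline, evaluated on the dense noiseless surface
.leafTruthGeometry <- function(spec, nSlices = 21L) {
  pts <- .placeLeaf(.laminaTruthGrid(spec), spec)
  nrm <- leafNormal(pts)
  th <- equivalentThickness(pts, nrm)
  ends <- findMidribEndpoints(pts)
  edges <- sliceEdgePoints(pts, ends$pe, ends$ps, nSlices = nSlices)
  lref <- fitEdgeCubic(edges$left, frame = edges$frame)
  rref <- fitEdgeCubic(edges$right, frame = edges$frame)
  hexv <- hexagonVertices(ends$pe, ends$ps, lref, rref)
  hv <- hexagonalPrismVolume(hexv, as.numeric(th))
  list(thickness = as.numeric(th), normal = nrm, hexagon = hexv,
       area = attr(hv, "area"), volume = as.numeric(hv))
}

#' Generate a TLS-like sample of one synthetic leaf
#'
#' Samples the parametric lamina uniformly by area at `density` points per
#' square metre, adds isotropic Gaussian noise, and returns the cloud together
#' with the noiseless ground-truth geometry (equivalent thickness and
#' hexagonal-prism volume computed on a dense noiseless surface by the same
#' definitions the fitting pipeline uses).
#'
#' @param spec a [syntheticLeafSpec()]
#' @param density sampling density (points per m^2 of planform)
#' @param noiseSd per-coordinate Gaussian noise standard deviation (m)
#' @param seed integer seed; the same seed reproduces the same cloud
#' @param leafIdValue instance id stored in the emitted cloud
#' @return list with elements `cloud` ([PointCloud-class]) and `truth`
#'   (list: `thickness`, `normal`, `hexagon`, `area`, `volume`)
#' @examples
#' leaf <- generateLeaf(syntheticLeafSpec(curlAmplitude = 0.01, droopAngle = 0),
#'                      density = 2e5, noiseSd = 0, seed = 7)
#' leaf$truth$thickness   # equals the curl amplitude for a flat-droop leaf
#' @export
generateLeaf <- function(spec, density = 1.5e5, noiseSd = 0.001, seed = 1,
                         leafIdValue = 0L) {
  stopifnot(inherits(spec, "SyntheticLeafSpec"))
  if (!(density > 0)) stop("density must be positive")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  n <- round(density * .planformArea(spec))
  if (n < 3) stop("sampling density too low: fewer than 3 points on the leaf")
  cloud <- .withSeed(seed, {
    xy <- .laminaPlanform(spec, n)
    pts <- .placeLeaf(.laminaLift(xy, spec), spec)
    if (noiseSd > 0) pts <- pts + matrix(rnorm(3 * n, sd = noiseSd), n, 3)
    pts
  })
  truth <- .leafTruthGeometry(spec)
  list(cloud = pointCloud(cloud, classLabel = rep("leaf", n),
                          leafId = rep(as.integer(leafIdValue), n)),
       truth = truth)
}

#' Specification of a synthetic tree
#'
#' Defaults emulate a small ornamental tree of the crepe-myrtle type: a short
#' trunk, a recursively branched crown inside a spheroidal envelope, and a few
#' hundred small (about 5 x 3.5 cm) curled, drooping leaves scanned at
#' TLS-like density with millimetre noise.
#'
#' @param nLeaves number of leaves
#' @param leafLength,leafWidth ranges (min, max) of blade dimensions (m)
#' @param curlAmplitude,droopAngle ranges of lamina distortion (m, radians)
#' @param petioleLength range of petiole lengths (m); the blade is offset
#'   from its twig by the petiole, which is too thin to register returns
#' @param leafShape `"elliptic"` or `"fan"`
#' @param branchDepth recursion depth of the branch network
#' @param branchAngle range of branching angles from the parent axis (radians)
#' @param radiusTaper,lengthTaper child/parent ratios of radius and length
#' @param trunkHeight,trunkRadius trunk dimensions (m)
#' @param crownShape `"spheroid"`, `"cone"` or `"cylinder"`
#' @param crownRadius semi-axis lengths (x, y, z) of the crown envelope (m)
#' @param samplingDensity surface sampling density (points per m^2)
#' @param noiseSd Gaussian noise standard deviation (m)
#' @param seed integer seed
#' @return a validated list of class `SyntheticTreeSpec`
#' @export
syntheticTreeSpec <- function(nLeaves = 150L,
                              leafLength = c(0.04, 0.06),
                              leafWidth = c(0.028, 0.042),
                              curlAmplitude = c(0.004, 0.016),
                              droopAngle = c(0.1, 0.5),
                              petioleLength = c(0.01, 0.025),
                              leafShape = "elliptic",
                              branchDepth = 7L,
                              branchAngle = c(0.35, 0.8),
                              radiusTaper = 0.7,
                              lengthTaper = 0.8,
                              trunkHeight = 0.8,
                              trunkRadius = 0.015,
                              crownShape = c("spheroid", "cone", "cylinder"),
                              crownRadius = c(0.45, 0.45, 0.5),
                              samplingDensity = 1.5e5,
                              noiseSd = 0.001,
                              seed = 1L) {
  crownShape <- match.arg(crownShape)
  if (nLeaves < 0) stop("nLeaves must be >= 0")
  if (!(samplingDensity > 0)) stop("samplingDensity must be positive")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!(trunkHeight > 0) || !(trunkRadius > 0)) stop("trunk dimensions must be positive")
  if (mean(leafLength) > 2 * max(crownRadius) || mean(leafWidth) > 2 * max(crownRadius))
    stop("infeasible geometry: leaves larger than the crown envelope")
  structure(list(nLeaves = as.integer(nLeaves), leafLength = leafLength,
                 leafWidth = leafWidth, curlAmplitude = curlAmplitude,
                 droopAngle = droopAngle, petioleLength = petioleLength,
                 leafShape = leafShape,
                 branchDepth = as.integer(branchDepth), branchAngle = branchAngle,
                 radiusTaper = radiusTaper, lengthTaper = lengthTaper,
                 trunkHeight = trunkHeight, trunkRadius = trunkRadius,
                 crownShape = crownShape, crownRadius = crownRadius,
                 samplingDensity = samplingDensity, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "SyntheticTreeSpec")
}

.insideCrown <- function(p, spec, centre) {
  d <- (p - centre) / spec$crownRadius
  switch(spec$crownShape,
         spheroid = sum(d^2) <= 1,
         cone = d[3] >= -1 && d[3] <= 1 &&
                sqrt(d[1]^2 + d[2]^2) <= (1 - d[3]) / 2 + 0.5,
         cylinder = abs(d[3]) <= 1 && sqrt(d[1]^2 + d[2]^2) <= 1)
}

# recursive branch skeleton: list of segments (start, end, radius, depth)
.growBranches <- function(spec, centre) {
  segs <- list()
  firstLen <- 0.55 * spec$crownRadius[3]
  recurse <- function(base, dir, radius, len, depth) {
    tip <- base + dir * len
    tries <- 0
    while (!.insideCrown(tip, spec, centre) && tries < 8) {
      # steer back towards the crown centre and shorten
      dir <- .unit(0.6 * dir + 0.4 * .unit(centre - base))
      len <- len * 0.8
      tip <- base + dir * len
      tries <- tries + 1
    }
    segs[[length(segs) + 1L]] <<- list(start = base, end = tip, radius = radius,
                                       depth = depth)
    if (depth < spec$branchDepth) {
      for (child in 1:2) {
        ang <- runif(1, spec$branchAngle[1], spec$branchAngle[2])
        roll <- runif(1, 0, 2 * pi)
        # rotate dir by ang about a random perpendicular axis
        perp <- .unit(.perpVector(dir, roll))
        newDir <- .unit(dir * cos(ang) + perp * sin(ang))
        recurse(tip, newDir, radius * spec$radiusTaper, len * spec$lengthTaper,
                depth + 1L)
      }
    }
  }
  trunkTop <- c(0, 0, spec$trunkHeight)
  # several first-order branches diverge laterally at the trunk top (the
  # crown base), rather than a single vertical leader
  for (j in 1:3) {
    ang <- runif(1, spec$branchAngle[1], spec$branchAngle[2])
    roll <- 2 * pi * j / 3 + runif(1, -0.5, 0.5)
    dir <- .unit(c(0, 0, 1) * cos(ang) + .perpVector(c(0, 0, 1), roll) * sin(ang))
    recurse(trunkTop, dir, spec$trunkRadius * spec$radiusTaper, firstLen, 1L)
  }
  segs
}

# a unit vector perpendicular to v, rotated by `roll` about v
.perpVector <- function(v, roll) {
  e <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- .unit(.cross(v, e))
  u2 <- .cross(v, u1)
  u1 * cos(roll) + u2 * sin(roll)
}

# surface sample of one cylinder at `density` points per m^2
.sampleCylinder <- function(start, end, radius, density) {
  axis <- end - start
  L <- sqrt(sum(axis^2))
  if (L == 0) return(matrix(numeric(0), 0, 3))
  n <- max(1L, round(density * 2 * pi * radius * L))
  d <- .unit(axis)
  e <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- .unit(.cross(d, e))
  u2 <- .cross(d, u1)
  t <- runif(n, 0, L)
  th <- runif(n, 0, 2 * pi)
  sweep(outer(t, d) + radius * (outer(cos(th), u1) + outer(sin(th), u2)),
        2, start, `+`)
}

#' Generate a TLS-like synthetic tree with ground truth
#'
#' Builds a recursive cylinder branch network inside the crown envelope,
#' attaches leaves along terminal twigs with a minimum internode spacing,
#' samples all surfaces at the requested density, adds Gaussian noise, and
#' returns per-point ground-truth labels plus analytic volumes: per-leaf
#' hexagonal-prism volumes on the noiseless surfaces, the exact summed
#' cylinder wood volume, the crown volume (convex hull of noiseless
#' vegetative points above the lowest branch), and the true volume-based gap
#' fraction. Ground truth depends on the generating geometry only, not on the
#' sampling density.
#'
#' @param spec a [syntheticTreeSpec()]
#' @return list with elements `cloud` (labelled [PointCloud-class]) and
#'   `truth` (list: `leafVolumes`, `leafThicknesses`, `woodVolume`,
#'   `woodVolumeInCrown`, `crownVolume`, `crownBaseHeight`, `gfVol`,
#'   `nLeaves`, `noiseless` coordinates)
#' @export
generateTree <- function(spec) {
  stopifnot(inherits(spec, "SyntheticTreeSpec"))
  centre <- c(0, 0, spec$trunkHeight + 0.85 * spec$crownRadius[3])
  res <- .withSeed(spec$seed, {
    segs <- .growBranches(spec, centre)
    depths <- vapply(segs, `[[`, 0, "depth")
    # leaves attach along the deepest branch orders (the leafy twigs)
    terminal <- which(depths >= max(depths) - 2L)

    # leaf attachment points along terminal twigs with internode spacing
    attach <- matrix(numeric(0), 0, 3)
    # internode spacing between petioles: a soft target that relaxes when the
    # twig supply is short (crowded twigs carry leaves at shorter internodes)
    minSep <- 0.5 * mean(spec$leafLength)
    tries <- 0L
    maxTries <- 60L * max(1L, spec$nLeaves)
    while (nrow(attach) < spec$nLeaves) {
      tries <- tries + 1L
      if (tries > maxTries) {
        minSep <- 0.8 * minSep
        tries <- 0L
        if (minSep < 0.05 * mean(spec$leafLength))
          stop("could not place ", spec$nLeaves, " leaves on the branch ",
               "network; reduce nLeaves or enlarge the crown envelope")
      }
      s <- segs[[sample(terminal, 1L)]]
      t <- runif(1, 0.1, 1)
      p <- s$start + t * (s$end - s$start)
      if (!.insideCrown(p, spec, centre)) next
      if (nrow(attach) &&
          min(sqrt(rowSums(sweep(attach, 2, p, `-`)^2))) < minSep) next
      attach <- rbind(attach, p)
    }

    leafSpecs <- vector("list", spec$nLeaves)
    if (spec$nLeaves > 0) for (i in seq_len(spec$nLeaves)) {
      pet <- runif(1, spec$petioleLength[1], spec$petioleLength[2])
      petDir <- .unit(c(rnorm(2), abs(rnorm(1, 0.3, 0.5))))
      # the blade extends outward along its petiole (with some jitter); blade
      # width follows length allometrically (aspect ratio about 0.7)
      len <- runif(1, spec$leafLength[1], spec$leafLength[2])
      wid <- min(max(len * runif(1, 0.65, 0.75), spec$leafWidth[1]),
                 spec$leafWidth[2])
      leafSpecs[[i]] <- syntheticLeafSpec(
        length = len,
        width = wid,
        curlAmplitude = runif(1, spec$curlAmplitude[1], spec$curlAmplitude[2]),
        droopAngle = runif(1, spec$droopAngle[1], spec$droopAngle[2]),
        attachment = attach[i, ] + pet * petDir,
        zenith = runif(1, 0, pi / 3),
        azimuth = atan2(petDir[2], petDir[1]) + runif(1, -0.6, 0.6),
        shape = spec$leafShape)
    }

    # sample surfaces (noiseless first; noise added afterwards)
    woodPts <- do.call(rbind, lapply(segs, function(s)
      .sampleCylinder(s$start, s$end, s$radius, spec$samplingDensity)))
    trunkPts <- .sampleCylinder(c(0, 0, 0), c(0, 0, spec$trunkHeight),
                                spec$trunkRadius, spec$samplingDensity)
    woodPts <- rbind(trunkPts, woodPts)

    leafPts <- matrix(numeric(0), 0, 3)
    leafIds <- integer(0)
    if (spec$nLeaves > 0) for (i in seq_len(spec$nLeaves)) {
      sp <- leafSpecs[[i]]
      n <- max(3L, round(spec$samplingDensity * .planformArea(sp)))
      xy <- .laminaPlanform(sp, n)
      pts <- .placeLeaf(.laminaLift(xy, sp), sp)
      leafPts <- rbind(leafPts, pts)
      leafIds <- c(leafIds, rep(i - 1L, n))
    }

    noiseless <- rbind(woodPts, leafPts)
    nW <- nrow(woodPts); nL <- nrow(leafPts)
    noisy <- noiseless
    if (spec$noiseSd > 0)
      noisy <- noisy + matrix(rnorm(3 * nrow(noisy), sd = spec$noiseSd),
                              nrow(noisy), 3)
    list(segs = segs, leafSpecs = leafSpecs, noiseless = noiseless,
         noisy = noisy, nW = nW, nL = nL, leafIds = leafIds)
  })

  labels <- c(rep("wood", res$nW), rep("leaf", res$nL))
  lid <- c(rep(-1L, res$nW), res$leafIds)
  cloud <- pointCloud(res$noisy, classLabel = labels, leafId = lid)

  # ground truth (geometry only; independent of sampling density)
  segs <- res$segs
  segLen <- vapply(segs, function(s) sqrt(sum((s$end - s$start)^2)), 0)
  segVol <- vapply(segs, function(s)
    pi * s$radius^2 * sqrt(sum((s$end - s$start)^2)), 0)
  trunkVol <- pi * spec$trunkRadius^2 * spec$trunkHeight
  woodVolume <- trunkVol + sum(segVol)

  crownBase <- min(vapply(segs, function(s) min(s$start[3], s$end[3]), 0))

  leafTruth <- lapply(res$leafSpecs, .leafTruthGeometry)
  leafVolumes <- vapply(leafTruth, `[[`, 0, "volume")
  leafThicknesses <- vapply(leafTruth, `[[`, 0, "thickness")

  # wood volume restricted to the crown (trunk clipped at the crown base)
  clip <- function(s) {
    z0 <- min(s$start[3], s$end[3]); z1 <- max(s$start[3], s$end[3])
    L <- sqrt(sum((s$end - s$start)^2))
    if (z1 <= crownBase) return(0)
    frac <- if (z1 > z0) min(1, (z1 - crownBase) / (z1 - z0)) else 1
    pi * s$radius^2 * L * frac
  }
  woodInCrown <- sum(vapply(segs, clip, 0)) +
    pi * spec$trunkRadius^2 * max(0, spec$trunkHeight - crownBase)

  # crown volume: convex hull of a fixed-resolution noiseless surface sample
  truthDensity <- 2e4
  hullPts <- .withSeed(spec$seed + 1L, {
    w <- do.call(rbind, lapply(segs, function(s)
      .sampleCylinder(s$start, s$end, s$radius, truthDensity)))
    l <- if (spec$nLeaves > 0)
      do.call(rbind, lapply(res$leafSpecs, function(sp)
        .placeLeaf(.laminaTruthGrid(sp, nGrid = 15L), sp)))  # hull needs no fine grid
    else matrix(numeric(0), 0, 3)
    rbind(w, l)
  })
  hullPts <- hullPts[hullPts[, 3] >= crownBase, , drop = FALSE]
  crownVolume <- .convexHull3dCpp(hullPts)$volume

  gf <- 1 - (sum(leafVolumes) + woodInCrown) / crownVolume

  list(cloud = cloud,
       truth = list(leafVolumes = leafVolumes, leafThicknesses = leafThicknesses,
                    woodVolume = woodVolume, woodVolumeInCrown = woodInCrown,
                    crownVolume = crownVolume, crownBaseHeight = crownBase,
                    gfVol = gf, nLeaves = spec$nLeaves,
                    noiseless = res$noiseless))
}
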