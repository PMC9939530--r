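test_that("great-circle plane fit is exact on planar neighbourhoods", {
  # neighbours exactly on the plane z = 0 through the centre at the origin
  P <- rbind(c(0, 0, 0), diskPoints(60, 0.02, seed = 1))
  cl <- pointCloud(P)
  fit <- fitGreatCirclePlane(cl, 1L, 2:61)
  expect_equal(fit$meanDistance, 0, tolerance = 1e-12)
  expect_equal(abs(fit$plane@normal[3]), 1, tolerance = 1e-9)
  expect_equal(fit$plane@offset, 0, tolerance = 1e-12)
})

test_that("mean plane distance matches the direct formula", {
  set.seed(12)
  P <- cbind(matrix(runif(80, -0.02, 0.02), ncol = 2), rnorm(40, sd = 1e-3))
  P <- rbind(c(0, 0, 0), P)
  cl <- pointCloud(P)
  fit <- fitGreatCirclePlane(cl, 1L, 2:41)
  n <- fit$plane@normal
  oracle <- mean(abs(P[2:41, ] %*% n - fit$plane@offset))
  expect_equal(fit$meanDistance, oracle, tolerance = 1e-12)

  line <- pointCloud(cbind(seq_len(5) / 100, 0, 0))
  expect_error(fitGreatCirclePlane(line, 1L, 2:5), "collinear")
})

test_that("robust centre normal honours the contract", {
  nb <- diskPoints(80, 0.02, seed = 2)
  n <- estimateCentreNormal(c(0, 0, 0), nb)
  expect_equal(sqrt(sum(n^2)), 1, tolerance = 1e-12)
  expect_gte(n[3], 0)
  expect_equal(abs(n[3]), 1, tolerance = 1e-9)   # exact plane normal

  # one gross outlier: the robust normal must beat the unweighted fit
  nbO <- rbind(nb, c(0.002, 0.001, 0.05))
  nRob <- estimateCentreNormal(c(0, 0, 0), nbO)
  W <- nbO
  nUnw <- eigen(crossprod(W), symmetric = TRUE)$vectors[, 3]
  angle <- function(v) acos(min(1, abs(v[3])))
  expect_lt(angle(nRob), angle(nUnw))
})

test_that("normal consistency averages the unsigned angles", {
  n <- c(0, 0, 1)
  expect_equal(normalConsistency(n, rbind(c(0, 0, 1), c(0, 0, -1))), 0,
               tolerance = 1e-12)
  expect_equal(normalConsistency(n, rbind(c(1, 0, 0), c(0, 1, 0))), pi / 2,
               tolerance = 1e-12)
  set.seed(13)
  M <- t(apply(matrix(rnorm(60), ncol = 3), 1, function(v) v / sqrt(sum(v^2))))
  oracle <- mean(acos(pmin(abs(M %*% n), 1)))
  expect_equal(normalConsistency(n, M), oracle, tolerance = 1e-12)
  expect_error(normalConsistency(n, M[0, , drop = FALSE]), "empty")
})

test_that("plane projection is idempotent, residual-free and distance-reducing", {
  pl <- plane(c(0, 0, 1), 0)
  expect_equal(projectPointsToPlane(matrix(c(1, 2, 5), 1), pl),
               matrix(c(1, 2, 0), 1), tolerance = 1e-12)
  set.seed(14)
  for (rep in 1:5) {
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    pl <- plane(nrm, rnorm(1))
    P <- matrix(rnorm(60), ncol = 3)
    Q <- projectPointsToPlane(P, pl)
    expect_lt(max(abs(Q %*% pl@normal - pl@offset)), 1e-9)
    expect_lt(max(abs(projectPointsToPlane(Q, pl) - Q)), 1e-9)
    # ||p' - p|| equals the absolute point-to-plane distance
    expect_equal(sqrt(rowSums((Q - P)^2)),
                 abs(as.numeric(P %*% pl@normal) - pl@offset),
                 tolerance = 1e-12)
  }
})

test_that("sigma' reproduces hand-computed dispersion values", {
  pl <- plane(c(0, 0, 1), 0)
  R <- 1
  # 40 points, one per cell: radii at annulus mid-areas, one sector each
  rad <- sqrt((rep(1:5, each = 8) - 0.5) / 5)
  ang <- (rep(0:7, times = 5) + 0.5) * pi / 4
  P <- cbind(rad * cos(ang), rad * sin(ang), 0)
  expect_equal(angularUniformity(P, c(0, 0, 0), pl, R), 0, tolerance = 1e-12)

  # 40 points in one cell: sigma' = 39 exactly
  P1 <- cbind(rep(0.2, 40), rep(0.1, 40), 0)
  expect_equal(angularUniformity(P1, c(0, 0, 0), pl, R), 39, tolerance = 1e-12)

  # empty disc yields the +Inf sentinel
  expect_identical(angularUniformity(P1, c(5, 5, 0), pl, R), Inf)
})

test_that("sigma' of a large uniform disc is near 1 (Poisson dispersion)", {
  set.seed(15)
  P <- diskPoints(4000, R = 1, seed = 15)
  pl <- plane(c(0, 0, 1), 0)
  s <- angularUniformity(P, c(0, 0, 0), pl, 1)
  expect_gt(s, 0.6)
  expect_lt(s, 1.6)
})

test_that("sigma' is invariant under 45-degree in-plane rotations", {
  set.seed(16)
  P <- diskPoints(500, R = 1, seed = 16)
  pl <- plane(c(0, 0, 1), 0)
  s0 <- angularUniformity(P, c(0, 0, 0), pl, 1)
  for (k in 1:3) {
    a <- k * pi / 4
    Q <- cbind(P[, 1] * cos(a) - P[, 2] * sin(a),
               P[, 1] * sin(a) + P[, 2] * cos(a), 0)
    expect_equal(angularUniformity(Q, c(0, 0, 0), pl, 1), s0,
                 tolerance = 1e-12)
  }
})

test_that("leaf centres are found near the centroid of a round dense leaf", {
  # round leaf so that the full neighbourhood disc only fits near the centre
  leaf <- generateLeaf(syntheticLeafSpec(length = 0.04, width = 0.038,
                                         curlAmplitude = 0.002,
                                         droopAngle = 0),
                       density = 4e5, noiseSd = 2e-4, seed = 17)
  cl <- pointCloud(coords(leaf$cloud))
  radius <- 0.75 * 0.038 / 2
  cp <- centreDetectionParams(radius = radius)
  cen <- detectLeafCentres(cl, cp)
  expect_gte(length(cen), 1)
  centroid <- colMeans(coords(cl))
  d <- sqrt(rowSums(sweep(coords(cl)[cen, , drop = FALSE], 2, centroid, `-`)^2))
  expect_true(all(d <= radius / 2 + 1e-9))

  expect_identical(detectLeafCentres(pointCloud(matrix(numeric(0), 0, 3)), cp),
                   integer(0))
})

test_that("a rim point fails the angular uniformity test", {
  # half-disc neighbourhood: only one side of the great circle is covered
  half <- diskPoints(400, 0.02, seed = 18)
  half <- half[half[, 1] >= 0, ]
  pl <- plane(c(0, 0, 1), 0)
  s <- angularUniformity(half, c(0, 0, 0), pl, 0.02)
  expect_gt(s, 2)     # far above the default threshold3 = 2
})

test_that("two separated leaves segment into two instances", {
  a <- generateLeaf(syntheticLeafSpec(curlAmplitude = 0.004, droopAngle = 0.1),
                    density = 2e5, noiseSd = 3e-4, seed = 19, leafIdValue = 0L)
  sp2 <- syntheticLeafSpec(curlAmplitude = 0.004, droopAngle = 0.1,
                           attachment = c(0.11, 0, 0))
  b <- generateLeaf(sp2, density = 2e5, noiseSd = 3e-4, seed = 20,
                    leafIdValue = 1L)
  P <- rbind(coords(a$cloud), coords(b$cloud))
  truth <- c(leafId(a$cloud), leafId(b$cloud))
  cl <- pointCloud(P)
  cp <- centreDetectionParams(radius = 0.75 * 0.035 / 2,
                              suppressionRadius = 0.025)
  cen <- detectLeafCentres(cl, cp)
  seg <- segmentLeaves(cl, cen, segmentationParams(geodesicCap = 0.1))
  ids <- leafId(seg)
  expect_identical(length(unique(ids[ids >= 0])), 2L)
  tab <- table(ids[ids >= 0], truth[ids >= 0])
  expect_gte(sum(apply(tab, 1, max)) / length(truth), 0.95)

  # partition property: every point gets exactly one id or -1
  expect_identical(length(ids), npoints(cl))
  expect_true(all(ids >= -1L))

  # DBSCAN-only fallback with no centres still recovers both leaves
  seg0 <- segmentLeaves(cl, integer(0), segmentationParams(geodesicCap = 0.1))
  ids0 <- leafId(seg0)
  expect_identical(length(unique(ids0[ids0 >= 0])), 2L)
})

test_that("a single leaf with one centre forms one instance", {
  leaf <- generateLeaf(syntheticLeafSpec(curlAmplitude = 0.003,
                                         droopAngle = 0),
                       density = 2e5, noiseSd = 3e-4, seed = 21)
  cl <- pointCloud(coords(leaf$cloud))
  centre <- which.min(rowSums(sweep(coords(cl), 2, colMeans(coords(cl)), `-`)^2))
  seg <- segmentLeaves(cl, centre, segmentationParams(geodesicCap = 0.1))
  ids <- leafId(seg)
  expect_identical(sort(unique(ids[ids >= 0])), 0L)
  expect_gte(mean(ids == 0L), 0.99)
})

test_that("detected instance count tracks the true leaf count on a tree", {
  tr <- generateTree(syntheticTreeSpec(nLeaves = 60L, seed = 7L,
                                       samplingDensity = 1.2e5))
  cl <- tr$cloud
  leafCloud <- cl[classLabel(cl) == "leaf"]
  cfg <- pipelineConfig()
  cen <- detectLeafCentres(leafCloud,
                           centreDetectionParams(radius = cfg$radius,
                                                 suppressionRadius = cfg$suppressionRadius))
  seg <- segmentLeaves(leafCloud, cen,
                       segmentationParams(geodesicCap = cfg$geodesicCap))
  ids <- leafId(seg)
  found <- length(unique(ids[ids >= 0]))
  expect_gte(found, 0.9 * 60)
  expect_lte(found, 1.1 * 60)
})
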