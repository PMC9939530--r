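test_that("a straight cylinder splits into the expected segment count", {
  P <- cylinderPoints(6000, radius = 0.05, length = 1, seed = 37)
  groups <- segmentBranchPoints(pointCloud(P), segmentLength = 0.25)
  expect_identical(length(groups), 4L)
  expect_identical(sort(unlist(groups)), seq_len(6000))

  expect_identical(segmentBranchPoints(pointCloud(matrix(numeric(0), 0, 3))),
                   list())
})

test_that("disconnected branches are never merged", {
  a <- cylinderPoints(800, radius = 0.01, length = 0.5, seed = 38)
  b <- cylinderPoints(800, radius = 0.01, length = 0.5, seed = 39)
  b[, 1] <- b[, 1] + 0.1    # 10 cm apart
  groups <- segmentBranchPoints(pointCloud(rbind(a, b)), segmentLength = 1)
  fromA <- vapply(groups, function(g) any(g <= 800), TRUE)
  fromB <- vapply(groups, function(g) any(g > 800), TRUE)
  expect_false(any(fromA & fromB))
})

test_that("cylinder fitting recovers exact and noisy radii", {
  P <- cylinderPoints(2000, radius = 0.05, length = 1, seed = 40)
  cy <- fitCylinder(P)
  expect_equal(cy@radius, 0.05, tolerance = 1e-6)
  L <- sqrt(sum((cy@axisEnd - cy@axisStart)^2))
  expect_equal(cy@volume, pi * 0.05^2 * L, tolerance = 1e-9)
  expect_equal(L, 1, tolerance = 1e-3)

  Pn <- cylinderPoints(3000, radius = 0.05, length = 1, noiseSd = 0.002,
                       seed = 41)
  cyn <- fitCylinder(Pn)
  expect_lt(abs(cyn@radius - 0.05) / 0.05, 0.04)

  expect_error(fitCylinder(cbind(seq_len(50), 0, 0)), "collinear")
  expect_error(fitCylinder(P[1:5, ]), "at least 6")
})

test_that("reported cylinder volume always equals pi r^2 L", {
  set.seed(42)
  for (rep in 1:5) {
    P <- cylinderPoints(500, radius = runif(1, 0.01, 0.08),
                        length = runif(1, 0.2, 1), noiseSd = 1e-3,
                        seed = 42 + rep)
    cy <- fitCylinder(P)
    L <- sqrt(sum((cy@axisEnd - cy@axisStart)^2))
    expect_equal(cy@volume, pi * cy@radius^2 * L, tolerance = 1e-9)
  }
})

test_that("wood volume sums cylinder volumes", {
  expect_identical(woodVolume(list()), 0)
  mk <- function(r, L) new("CylinderModel", axisStart = c(0, 0, 0),
                           axisEnd = c(0, 0, L), radius = r,
                           volume = pi * r^2 * L, rmsResidual = 0,
                           converged = TRUE, circumCoverage = 1)
  expect_equal(woodVolume(list(mk(0.1, 1), mk(0.1, 1))), 2 * pi * 0.01,
               tolerance = 1e-12)
})

test_that("pipeline wood volume tracks generator truth on a synthetic tree", {
  tr <- generateTree(syntheticTreeSpec(seed = 11L))
  cl <- tr$cloud
  wc <- cl[classLabel(cl) == "wood"]
  groups <- segmentBranchPoints(wc, 0.2)
  wco <- coords(wc)
  cyls <- list()
  for (g in groups) {
    if (length(g) < 6) next
    cyls <- c(cyls, crowngf3d:::.fitCylindersRecursive(wco[g, , drop = FALSE]))
  }
  rms <- vapply(cyls, function(x) x@rmsResidual, 0)
  covr <- vapply(cyls, function(x) x@circumCoverage, 0)
  keep <- rms <= 3 * median(rms) & covr >= 0.4
  est <- woodVolume(cyls[keep])
  expect_lt(abs(est - tr$truth$woodVolume) / tr$truth$woodVolume, 0.25)
})

test_that("convex hull crown volume is exact on a cube and a sampled ball", {
  cube <- pointCloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  cm <- crownVolume(cube, crownBaseHeight = -Inf, alpha = Inf)
  expect_equal(volume(cm), 1, tolerance = 1e-12)

  set.seed(43)
  n <- 1e5
  u <- matrix(rnorm(3 * n), ncol = 3)
  ball <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3)
  bm <- crownVolume(pointCloud(ball), crownBaseHeight = -Inf, alpha = Inf)
  expect_lt(abs(volume(bm) - 4 * pi / 3) / (4 * pi / 3), 0.02)

  expect_error(crownVolume(cube, crownBaseHeight = 2), "at least 4")
})

test_that("alpha-complex volume is monotone in alpha and meets the hull", {
  set.seed(44)
  P <- matrix(runif(900), ncol = 3)
  cl <- pointCloud(P)
  hull <- volume(crownVolume(cl, alpha = Inf))
  # near-coplanar boundary slivers can have arbitrarily large circumradii but
  # negligible volume, so a huge finite alpha recovers the hull volume
  alphas <- c(1e6, 0.6, 0.3, 0.15, 0.08)
  vols <- vapply(alphas, function(a) volume(crownVolume(cl, alpha = a)), 0)
  expect_true(all(diff(vols) <= 1e-12))     # decreasing alpha, non-increasing
  expect_equal(vols[1], hull, tolerance = 1e-6)
})

test_that("Delaunay tetrahedra exactly tile the convex hull", {
  set.seed(45)
  for (rep in 1:5) {
    P <- matrix(rnorm(3 * 80), ncol = 3)
    d <- crowngf3d:::.delaunay3dCpp(P)
    h <- crowngf3d:::.convexHull3dCpp(P)
    expect_equal(sum(d$volume), h$volume, tolerance = 1e-9)
  }
})

test_that("crown volume is invariant under rigid motion", {
  set.seed(46)
  P <- matrix(rnorm(600), ncol = 3)
  mot <- randomRigidMotion(5)
  v1 <- volume(crownVolume(pointCloud(P), alpha = Inf))
  v2 <- volume(crownVolume(pointCloud(applyMotion(P, mot)), alpha = Inf))
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("crown base estimation needs labels and returns a height", {
  tr <- generateTree(syntheticTreeSpec(nLeaves = 40L, seed = 12L,
                                       samplingDensity = 5e4))
  base <- estimateCrownBase(tr$cloud)
  expect_gt(base, 0.5 * tr$truth$crownBaseHeight)
  expect_lt(base, tr$truth$crownBaseHeight + 0.3)
  expect_error(estimateCrownBase(pointCloud(matrix(rnorm(30), 10, 3))),
               "labels")
})
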