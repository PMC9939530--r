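test_that("the gap-fraction formula handles limits and bad crowns", {
  expect_identical(computeGFvol(0, 0, 5), 1)
  expect_identical(computeGFvol(2, 3, 5), 0)
  expect_error(computeGFvol(1, 1, 0), "positive")
  expect_error(computeGFvol(-1, 0, 1), "non-negative")
  expect_warning(gf <- computeGFvol(3, 3, 5), "outside")
  expect_equal(gf, -0.2, tolerance = 1e-12)
})

test_that("published-style component volumes reproduce the reported gap fractions", {
  ex <- exampleCrownComponents()
  gf <- mapply(computeGFvol, ex$total_leaf_volume_m3, ex$total_wood_volume_m3,
               ex$crown_volume_m3)
  expect_true(all(abs(gf - ex$gf_vol_reported) <= 0.001))
})

test_that("hemispherical GF is 1 for empty and 0 for fully covered skies", {
  empty <- pointCloud(matrix(numeric(0), 0, 3))
  gf <- hemisphericalGF(empty, observer = c(0, 0, 0), imageSize = 512L,
                        ringEdges = c(0, 30, 60, 90))
  expect_true(all(gf$gf == 1))

  # dense hemisphere of points above the observer
  set.seed(47)
  n <- 2e5
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v[, 3] <- abs(v[, 3])
  full <- pointCloud(v * 5)
  gfF <- hemisphericalGF(full, observer = c(0, 0, 0), imageSize = 512L,
                         ringEdges = c(10, 40, 70))
  expect_true(all(gfF$gf < 0.02))
})

test_that("half-azimuth coverage yields GF near one half per ring", {
  set.seed(48)
  n <- 2e5
  th <- acos(runif(n))            # hemisphere zeniths
  ph <- runif(n, 0, pi)           # azimuth half-space only
  P <- 5 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  gf <- hemisphericalGF(pointCloud(P), observer = c(0, 0, 0),
                        imageSize = 512L, ringEdges = c(20, 40, 60, 80))
  expect_true(all(abs(gf$gf - 0.5) <= 0.02))
})

test_that("hemispherical GF is invariant under azimuthal rotation", {
  tr <- generateTree(syntheticTreeSpec(nLeaves = 40L, seed = 13L,
                                       samplingDensity = 5e4))
  P <- coords(tr$cloud)
  ctr <- c(mean(range(P[, 1])), mean(range(P[, 2])), 0)
  P0 <- sweep(P, 2, ctr, `-`)
  g1 <- hemisphericalGF(pointCloud(P0), observer = c(0, 0, 0),
                        imageSize = 512L, ringEdges = c(40, 70))
  a <- 2.1
  Prot <- P0 %*% t(rotZ(2.1))
  g2 <- hemisphericalGF(pointCloud(Prot), observer = c(0, 0, 0),
                        imageSize = 512L, ringEdges = c(40, 70))
  expect_lt(abs(g1$gf - g2$gf), 0.01)
})

test_that("the 57.3-degree convention ring is the default", {
  empty <- pointCloud(matrix(numeric(0), 0, 3))
  gf <- hemisphericalGF(empty, imageSize = 512L)
  expect_equal(gf$zenithLo, 52.3)
  expect_equal(gf$zenithHi, 62.3)
})

test_that("voxel gap fraction matches constructed occupancy", {
  expect_identical(voxelGapFraction(pointCloud(matrix(numeric(0), 0, 3)),
                                    0.1, 1), 1)
  # points at the centres of all voxels tiling a 10x10x10 grid (1 m^3)
  g <- (0:9) / 10 + 0.05
  centres <- as.matrix(expand.grid(g, g, g))
  cl <- pointCloud(centres)
  expect_equal(voxelGapFraction(cl, 0.1, 1), 0, tolerance = 1e-12)

  # half the voxels occupied
  half <- centres[centres[, 1] < 0.5, ]
  expect_equal(voxelGapFraction(pointCloud(half), 0.1, 1), 0.5,
               tolerance = 1e-12)

  expect_warning(voxelGapFraction(cl, 0.5, 0.01), "clamping")
})

test_that("occupied voxel volume grows with voxel size until saturation", {
  set.seed(49)
  P <- matrix(runif(3000), ncol = 3)
  cl <- pointCloud(P)
  sizes <- c(0.05, 0.1, 0.2, 0.5)
  gfs <- vapply(sizes, function(s)
    suppressWarnings(voxelGapFraction(cl, s, 2)), 0)
  expect_true(all(diff(gfs) <= 1e-9))
})

test_that("Beer-Lambert transmission matches closed forms", {
  expect_identical(beerLambertGF(G = 0.5, Omega = 1, LAI = 0, theta = 0), 1)
  expect_equal(beerLambertGF(G = 0.5, Omega = 1, LAI = 2, theta = 0),
               exp(-1), tolerance = 1e-12)
  th <- seq(0, 1.4, by = 0.2)
  p <- beerLambertGF(G = 0.5, Omega = 0.8, LAI = 3, theta = th)
  expect_true(all(diff(p) < 0))
  expect_error(beerLambertGF(G = 0.5, Omega = 1, LAI = 1, theta = pi / 2),
               "theta")
  expect_error(beerLambertGF(G = -1, Omega = 1, LAI = 1), "G")
  expect_error(beerLambertGF(G = 0.5, Omega = 1.4, LAI = 1), "Omega")
})

test_that("gf_vol decreases when leaf volume grows at fixed crown volume", {
  g1 <- computeGFvol(0.01, 0.01, 2)
  g2 <- computeGFvol(0.02, 0.01, 2)
  expect_lt(g2, g1)
})
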