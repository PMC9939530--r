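test_that("eigen-features recover degenerate geometries", {
  # straight segment: pure linearity
  line <- pointCloud(cbind(seq(0, 1, length.out = 50), 0, 0))
  f <- localEigenFeatures(line, 25L, k = 20L)
  expect_equal(f$linearity, 1, tolerance = 1e-9)
  expect_equal(f$planarity, 0, tolerance = 1e-9)

  # planar disk with lambda1 = lambda2: pure planarity
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  disk <- pointCloud(rbind(cbind(cos(th), sin(th), 0),
                           0.5 * cbind(cos(th), sin(th), 0)))
  f <- localEigenFeatures(disk, 1L, k = 79L)
  expect_equal(f$planarity, 1, tolerance = 1e-6)
  expect_equal(f$linearity, 0, tolerance = 1e-6)
})

test_that("features match an independent eigen-decomposition oracle", {
  set.seed(6)
  P <- matrix(rnorm(900), ncol = 3)
  cl <- pointCloud(P)
  i <- 17L; k <- 30L
  f <- localEigenFeatures(cl, i, k = k)
  d <- sqrt(colSums((t(P) - P[i, ])^2))
  nb <- order(d)[seq_len(k + 1)]        # the point itself plus k nearest
  ev <- sort(eigen(cov(P[nb, ]) * (length(nb) - 1) / length(nb),
                   symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(f$linearity, (ev[1] - ev[2]) / ev[1], tolerance = 1e-9)
  expect_equal(f$planarity, (ev[2] - ev[3]) / ev[1], tolerance = 1e-9)
  expect_equal(f$scattering, ev[3] / ev[1], tolerance = 1e-9)
})

test_that("the feature triple sums to one and is rigid-motion invariant", {
  set.seed(7)
  P <- matrix(rnorm(600, sd = 0.05), ncol = 3)
  cl <- pointCloud(P)
  mot <- randomRigidMotion(2)
  cl2 <- pointCloud(applyMotion(P, mot))
  for (i in c(1L, 50L, 137L)) {
    f <- localEigenFeatures(cl, i, k = 15L)
    expect_equal(f$linearity + f$planarity + f$scattering, 1, tolerance = 1e-9)
    g <- localEigenFeatures(cl2, i, k = 15L)
    expect_equal(f$linearity, g$linearity, tolerance = 1e-9)
    expect_equal(f$planarity, g$planarity, tolerance = 1e-9)
  }
  expect_error(localEigenFeatures(cl, 1L, k = 2L), "at least 3")
})

test_that("coincident points fall back to the (0, 0, 1) convention", {
  cl <- pointCloud(matrix(0, 10, 3))
  f <- localEigenFeatures(cl, 1L, k = 5L)
  expect_identical(c(f$linearity, f$planarity, f$scattering), c(0, 0, 1))
})

test_that("threshold classification separates pure fixtures", {
  cyl <- pointCloud(cylinderPoints(4000, radius = 0.008, length = 1,
                                   noiseSd = 5e-4, seed = 8))
  out <- classifyWoodLeaf(cyl, method = "threshold")
  expect_gte(mean(classLabel(out) == "wood"), 0.95)

  leaf <- generateLeaf(syntheticLeafSpec(length = 0.06, width = 0.042,
                                         curlAmplitude = 0.002,
                                         droopAngle = 0),
                       density = 2e5, noiseSd = 5e-4, seed = 9)
  out <- classifyWoodLeaf(pointCloud(coords(leaf$cloud)), method = "threshold")
  expect_gte(mean(classLabel(out) == "leaf"), 0.95)

  empty <- classifyWoodLeaf(pointCloud(matrix(numeric(0), 0, 3)))
  expect_identical(npoints(empty), 0L)
  expect_length(classLabel(empty), 0L)
})

test_that("trainable classifiers require training data and learn the fixtures", {
  cyl <- cylinderPoints(1500, radius = 0.008, length = 0.8, noiseSd = 5e-4,
                        seed = 10)
  leaf <- coords(generateLeaf(syntheticLeafSpec(curlAmplitude = 0.002,
                                                droopAngle = 0),
                              density = 2e5, noiseSd = 5e-4, seed = 11)$cloud)
  train <- pointCloud(rbind(cyl, leaf),
                      classLabel = c(rep("wood", nrow(cyl)),
                                     rep("leaf", nrow(leaf))))
  target <- pointCloud(rbind(cylinderPoints(800, radius = 0.008, length = 0.8,
                                            noiseSd = 5e-4, seed = 12),
                             coords(generateLeaf(syntheticLeafSpec(
                               curlAmplitude = 0.002, droopAngle = 0),
                               density = 1e5, noiseSd = 5e-4, seed = 13)$cloud)))
  truth <- c(rep("wood", 800), rep("leaf", npoints(target) - 800))
  for (m in c("gaussian", "svm")) {
    expect_error(classifyWoodLeaf(target, method = m), "training")
    out <- classifyWoodLeaf(target, method = m, params = list(training = train))
    expect_gte(mean(classLabel(out) == truth), 0.9)
  }
})
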