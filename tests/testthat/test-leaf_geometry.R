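test_that("MLS smoothing reproduces planes and reduces planar noise", {
  P <- cbind(diskPoints(200, 0.03, seed = 22)[, 1:2], 0)
  out <- mlsSmooth(P, supportRadius = 0.01)
  expect_equal(out, P, tolerance = 1e-9)
  expect_identical(nrow(out), nrow(P))

  set.seed(23)
  noisy <- P + cbind(0, 0, rnorm(nrow(P), sd = 0.002))
  sm <- mlsSmooth(noisy, supportRadius = 0.01)
  expect_lt(sqrt(mean(sm[, 3]^2)), sqrt(mean(noisy[, 3]^2)))
  expect_identical(nrow(sm), nrow(P))
})

test_that("midrib endpoints equal the brute-force farthest pair", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  E <- cbind(0.05 * cos(th), 0.02 * sin(th), 0)
  ends <- findMidribEndpoints(E)
  expect_equal(abs(ends$pe[1]), 0.05, tolerance = 1e-9)
  expect_equal(abs(ends$ps[1]), 0.05, tolerance = 1e-9)

  set.seed(24)
  for (rep in 1:20) {
    P <- matrix(rnorm(3 * sample(5:200, 1)), ncol = 3)
    ends <- findMidribEndpoints(P)
    D <- as.matrix(dist(P))
    expect_equal(sqrt(sum((ends$pe - ends$ps)^2)), max(D), tolerance = 1e-12)
  }

  two <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)
  ends <- findMidribEndpoints(two)
  expect_equal(ends$pe, c(0, 0, 0))
  expect_error(findMidribEndpoints(two[1, , drop = FALSE]), "at least 2")
})

test_that("farthest pair via the convex hull matches brute force at large M", {
  set.seed(25)
  P <- matrix(rnorm(3 * 6000), ncol = 3)
  ends <- findMidribEndpoints(P)
  sub <- P[sample(nrow(P), 2000), ]
  # hull-based pair must be at least as far apart as any sampled pair
  expect_gte(sqrt(sum((ends$pe - ends$ps)^2)) + 1e-12, max(dist(sub)))
})

test_that("edge slicing finds per-slab extremes on a rectangle", {
  set.seed(26)
  P <- cbind(runif(3000, -0.01, 0.01), runif(3000, -0.05, 0.05), 0)
  P <- rbind(P, c(0, -0.055, 0), c(0, 0.055, 0))   # axis endpoints on y
  ends <- findMidribEndpoints(P)
  sl <- sliceEdgePoints(P, ends$pe, ends$ps, nSlices = 10L)
  expect_lte(nrow(sl$left), 9)
  expect_gte(nrow(sl$left), 7)
  # rectangle edges: |x| of edge points near 0.01
  expect_gt(mean(abs(sl$left[, 1])), 0.008)
  expect_gt(mean(abs(sl$right[, 1])), 0.008)

  # elliptic leaf: edge offsets follow the analytic half-width profile
  leaf <- generateLeaf(syntheticLeafSpec(curlAmplitude = 0, droopAngle = 0),
                       density = 4e5, noiseSd = 0, seed = 27)
  Q <- coords(leaf$cloud)
  ends <- findMidribEndpoints(Q)
  sl <- sliceEdgePoints(Q, ends$pe, ends$ps, nSlices = 21L)
  L <- 0.05; W <- 0.035
  u <- (sl$left %*% c(1, 0, 0) - ends$pe[1]) / L
  predicted <- (W / 2) * sqrt(pmax(1 - (2 * u - 1)^2, 0))
  expect_lt(median(abs(abs(sl$left[, 2]) - predicted)), 0.003)

  expect_error(sliceEdgePoints(P, ends$pe, ends$ps, nSlices = 3L), "at least 4")
})

test_that("cubic edge refinement solves the normal equations exactly", {
  frame <- list(origin = c(0, 0, 0), axis = c(0, 1, 0),
                lateral = c(1, 0, 0), normal = c(0, 0, 1))
  u <- seq(0.01, 0.2, length.out = 12)
  v <- 1 + 2 * u^3
  w <- 0.5 - u + 0.3 * u^2
  E <- cbind(v, u, w)       # x = lateral = v(u), y = axis = u, z = normal
  out <- fitEdgeCubic(E, frame)
  cf <- attr(out, "coefficients")
  expect_equal(cf[, "v"], c(1, 0, 0, 2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(cf[, "w"], c(0.5, -1, 0.3, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(out, E, tolerance = 1e-8, ignore_attr = TRUE)

  # arbitrary edges: coefficients equal an independent lm() solve
  set.seed(28)
  vv <- rnorm(12); ww <- rnorm(12)
  E2 <- cbind(vv, u, ww)
  out2 <- fitEdgeCubic(E2, frame)
  cf2 <- attr(out2, "coefficients")
  expect_equal(cf2[, "v"], unname(coef(lm(vv ~ poly(u, 3, raw = TRUE)))),
               tolerance = 1e-8, ignore_attr = TRUE)

  raw <- E2[1:3, ]
  out3 <- fitEdgeCubic(raw, frame)
  expect_false(attr(out3, "fitted"))
  expect_equal(unclass(out3), unclass(raw), ignore_attr = TRUE)
})

test_that("leaf normal follows the covariance and its sign convention", {
  expect_equal(leafNormal(diskPoints(100, 0.02, seed = 29)), c(0, 0, 1),
               tolerance = 1e-9)
  mot <- randomRigidMotion(3)
  P <- diskPoints(100, 0.02, seed = 29)
  n2 <- leafNormal(applyMotion(P, mot))
  expected <- mot$R %*% c(0, 0, 1)
  if (expected[3] < 0) expected <- -expected
  expect_equal(n2, as.numeric(expected), tolerance = 1e-9)
  expect_error(leafNormal(cbind(1:5, 0, 0)), "collinear")

  set.seed(30)
  noisy <- P + matrix(rnorm(300, sd = 0.001), ncol = 3)
  ang <- acos(min(1, abs(leafNormal(noisy)[3])))
  expect_lt(ang, 2 * pi / 180)
})

test_that("equivalent thickness is the extreme projection span", {
  P <- diskPoints(50, 0.02, seed = 31)
  expect_equal(as.numeric(equivalentThickness(P, c(0, 0, 1))), 0,
               tolerance = 1e-12)
  Q <- rbind(P, c(0, 0, 0.005), c(0, 0, -0.005))
  th <- equivalentThickness(Q, c(0, 0, 1))
  expect_equal(as.numeric(th), 0.01, tolerance = 1e-12)
  expect_identical(attr(th, "high"), nrow(Q) - 1L)

  leaf <- generateLeaf(syntheticLeafSpec(curlAmplitude = 0.01, droopAngle = 0),
                       density = 2e5, noiseSd = 0, seed = 32)
  R <- coords(leaf$cloud)
  nrm <- leafNormal(R)
  proj <- as.numeric(R %*% nrm)
  expect_equal(as.numeric(equivalentThickness(R, nrm)),
               max(proj) - min(proj), tolerance = 1e-12)
})

test_that("hexagon vertex indices follow round-half-up counting", {
  mk <- function(k) cbind(seq_len(k), 0, 0)
  pe <- c(0, -1, 0); ps <- c(0, 1, 0)
  hx <- hexagonVertices(pe, ps, mk(20), mk(20))
  expect_equal(hx[2, 1], 5)    # round(20/4)
  expect_equal(hx[3, 1], 15)   # round(3*20/4)
  hx <- hexagonVertices(pe, ps, mk(10), mk(10))
  expect_equal(hx[2, 1], 3)    # round(2.5) half-up
  expect_equal(hx[3, 1], 8)    # round(7.5) half-up
  expect_error(hexagonVertices(pe, ps, mk(1), mk(1)), "at least 2")
})

test_that("hexagonal prism volume matches closed forms and Monte Carlo", {
  # regular hexagon, side 1, thickness 2
  th <- (0:5) * pi / 3
  hexR <- cbind(cos(th), sin(th), 0)
  v <- hexagonalPrismVolume(hexR, 2)
  expect_equal(as.numeric(v), 3 * sqrt(3) / 2 * 2, tolerance = 1e-9)
  expect_equal(as.numeric(hexagonalPrismVolume(hexR, 0)), 0)

  # random simple hexagons: area vs point-in-polygon Monte Carlo
  set.seed(33)
  for (rep in 1:3) {
    ang <- sort(runif(6, 0, 2 * pi))
    rad <- runif(6, 0.5, 1)
    H <- cbind(rad * cos(ang), rad * sin(ang), 0)
    a <- attr(hexagonalPrismVolume(H, 1), "area")
    n <- 1e6
    x <- runif(n, -1, 1); y <- runif(n, -1, 1)
    inside <- rep(FALSE, n)
    # ray-casting point-in-polygon
    j <- 6
    for (i in 1:6) {
      cond <- (H[i, 2] > y) != (H[j, 2] > y)
      slope <- (H[j, 1] - H[i, 1]) * (y - H[i, 2]) /
               (H[j, 2] - H[i, 2]) + H[i, 1]
      inside <- xor(inside, cond & (x < slope))
      j <- i
    }
    mc <- mean(inside) * 4
    expect_equal(a, mc, tolerance = 0.005)
  }

  # self-intersecting ordering is rejected
  bad <- hexR[c(1, 3, 5, 2, 4, 6), ]
  expect_error(hexagonalPrismVolume(bad, 1), "self-intersecting")
})

test_that("the 3-part decomposition equals the shoelace area for leaf hexagons", {
  set.seed(34)
  tri <- function(a, b, c) abs((b[1] - a[1]) * (c[2] - a[2]) -
                               (c[1] - a[1]) * (b[2] - a[2])) / 2
  for (rep in 1:10) {
    # hexagons with the structure hexagonVertices() emits: axis endpoints
    # plus two ordered edge points per side
    u <- sort(runif(2, 0.15, 0.85))
    H <- rbind(c(0, 0, 0),
               c(runif(1, 0.2, 0.6), u[1], 0),
               c(runif(1, 0.2, 0.6), u[2], 0),
               c(0, 1, 0),
               c(-runif(1, 0.2, 0.6), u[2], 0),
               c(-runif(1, 0.2, 0.6), u[1], 0))
    xy <- H[, 1:2]
    lower <- tri(xy[1, ], xy[2, ], xy[6, ])
    upper <- tri(xy[3, ], xy[4, ], xy[5, ])
    middle <- tri(xy[2, ], xy[3, ], xy[5, ]) + tri(xy[2, ], xy[5, ], xy[6, ])
    expect_equal(attr(hexagonalPrismVolume(H, 1), "area"),
                 lower + middle + upper, tolerance = 1e-12)
  }
})

test_that("modelLeaf recovers flat-leaf volume and applies quality flags", {
  leaf <- generateLeaf(syntheticLeafSpec(curlAmplitude = 0.008,
                                         droopAngle = 0),
                       density = 4e5, noiseSd = 0, seed = 35)
  m <- modelLeaf(coords(leaf$cloud), leafModelConfig())
  expect_identical(m@qualityFlag, "ok")
  expect_lt(abs(m@volume - leaf$truth$volume) / leaf$truth$volume, 0.15)

  few <- coords(leaf$cloud)[1:10, ]
  m10 <- modelLeaf(few, leafModelConfig())
  expect_identical(m10@qualityFlag, "fallback_bbox")

  m2 <- modelLeaf(coords(leaf$cloud)[1:2, ], leafModelConfig())
  expect_identical(m2@qualityFlag, "rejected")
  expect_identical(m2@volume, 0)
})

test_that("thickness and volume transform correctly under rigid motion and scaling", {
  leaf <- generateLeaf(syntheticLeafSpec(curlAmplitude = 0.01,
                                         droopAngle = 0.2),
                       density = 2e5, noiseSd = 0, seed = 36)
  P <- coords(leaf$cloud)
  m0 <- modelLeaf(P, leafModelConfig())
  # the motion must preserve the lower-z petiole convention, so rotate about
  # the vertical axis and translate
  mot <- zRotationMotion(4)
  m1 <- modelLeaf(applyMotion(P, mot), leafModelConfig())
  expect_equal(m1@thickness, m0@thickness, tolerance = 1e-6)
  expect_equal(m1@volume, m0@volume, tolerance = 1e-6)

  s <- 2.5
  cfgS <- leafModelConfig(mlsSupportRadius = s * 0.035 / 4)
  mS <- modelLeaf(P * s, cfgS)
  expect_equal(mS@thickness, s * m0@thickness, tolerance = 1e-6)
  expect_equal(mS@volume, s^3 * m0@volume, tolerance = 1e-6)
})

test_that("pipeline leaf volume tracks truth across the curl/droop grid", {
  errs <- c()
  for (curl in c(0.005, 0.01, 0.02)) {
    for (droop in c(0, 15, 30) * pi / 180) {
      sp <- syntheticLeafSpec(curlAmplitude = curl, droopAngle = droop)
      g <- generateLeaf(sp, density = 1.2e5, noiseSd = 0.001,
                        seed = round(1e4 * curl + 100 * droop))
      m <- modelLeaf(coords(g$cloud), leafModelConfig())
      errs <- c(errs, abs(m@volume - g$truth$volume) / g$truth$volume)
    }
  }
  expect_lte(median(errs), 0.20)
})
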