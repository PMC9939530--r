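test_that("PointCloud validity enforces the data model", {
  expect_s4_class(pointCloud(matrix(rnorm(9), 3, 3)), "PointCloud")
  expect_error(pointCloud(matrix(c(1, 2, NaN), 1, 3)), "finite")
  expect_error(pointCloud(matrix(1, 2, 3), classLabel = "leaf"), "length")
  expect_error(pointCloud(matrix(1, 1, 3), classLabel = "wood", leafId = 3L),
               "leafId")
  empty <- pointCloud(matrix(numeric(0), 0, 3))
  expect_identical(npoints(empty), 0L)
})

test_that("XYZ read/write round-trips coordinates", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0", "0 1 0"), f)
  pc <- readPointCloud(f)
  expect_identical(npoints(pc), 3L)
  expect_length(classLabel(pc), 0L)

  set.seed(3)
  cl <- pointCloud(matrix(runif(300, -50, 50), ncol = 3))
  g <- tempfile(fileext = ".xyz")
  writePointCloud(cl, g)
  back <- readPointCloud(g)
  expect_lt(max(abs(coords(back) - coords(cl))), 1e-6)
})

test_that("PLY round-trips coordinates and labels (ascii and binary)", {
  set.seed(4)
  n <- 10000L
  cl <- pointCloud(matrix(runif(3 * n, -10, 10), ncol = 3),
                   classLabel = sample(c("leaf", "wood", "unassigned"), n, TRUE),
                   leafId = NULL)
  lid <- ifelse(classLabel(cl) == "leaf", sample(0:50, n, TRUE), -1L)
  leafId(cl) <- lid
  for (bin in c(TRUE, FALSE)) {
    f <- tempfile(fileext = ".ply")
    writePointCloud(cl, f, binary = bin)
    back <- readPointCloud(f)
    expect_lt(max(abs(coords(back) - coords(cl))), 1e-6)
    expect_identical(classLabel(back), classLabel(cl))
    expect_identical(leafId(back), leafId(cl))
  }
})

test_that("empty clouds and NaN coordinates are handled per contract", {
  f <- tempfile(fileext = ".ply")
  writePointCloud(pointCloud(matrix(numeric(0), 0, 3)), f)
  expect_identical(npoints(readPointCloud(f)), 0L)

  g <- tempfile(fileext = ".xyz")
  writeLines("1 2 NaN", g)
  expect_error(readPointCloud(g), "finite|non-finite")

  expect_error(readPointCloud(tempfile(fileext = ".ply")), "exist")
  expect_error(readPointCloud(f, format = "las"), "not a LAS")
})

test_that("LAS coordinates are read back from a hand-built LAS 1.2 file", {
  # minimal LAS 1.2, point format 0, written byte by byte
  pts <- matrix(c(1.25, 2.5, 3.75, -1.5, 0.5, 10), 2, 3, byrow = TRUE)
  scale <- c(0.001, 0.001, 0.001)
  off <- c(0, 0, 0)
  f <- tempfile(fileext = ".las")
  con <- file(f, "wb")
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(raw(20), con)                                   # up to byte 24
  writeBin(as.raw(c(1, 2)), con)                           # version 1.2
  writeBin(raw(70), con)                                   # to byte 96
  writeBin(227L, con, size = 4, endian = "little")         # offset to points
  writeBin(0L, con, size = 4, endian = "little")           # no VLRs
  writeBin(as.raw(0), con)                                 # point format 0
  writeBin(20L, con, size = 2, endian = "little")          # record length
  writeBin(2L, con, size = 4, endian = "little")           # n points
  writeBin(raw(20), con)                                   # by-return counts
  writeBin(scale, con, size = 8, endian = "little")
  writeBin(off, con, size = 8, endian = "little")
  writeBin(rep(0, 6), con, size = 8, endian = "little")    # bbox
  for (i in 1:2) {
    writeBin(as.integer(round(pts[i, ] / scale)), con, size = 4,
             endian = "little")
    writeBin(raw(8), con)
  }
  close(con)
  pc <- readPointCloud(f)
  expect_equal(coords(pc), pts, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("radiusNeighbors matches the brute-force oracle", {
  # regular 1 cm grid at 1.5 cm radius
  g <- gridCloud(5L, 0.01)
  P <- coords(g)
  for (i in c(1L, 32L, 125L))
    expect_identical(radiusNeighbors(g, i, 0.015), bruteRadiusNeighbors(P, i, 0.015))

  # random clouds at the leaf-scale radius used for centre detection
  set.seed(11)
  for (rep in 1:5) {
    P <- matrix(runif(600, 0, 0.2), ncol = 3)
    cl <- pointCloud(P)
    i <- sample(nrow(P), 1)
    r <- 0.75 * 0.0175
    expect_identical(radiusNeighbors(cl, i, r), bruteRadiusNeighbors(P, i, r))
  }

  one <- pointCloud(matrix(0, 1, 3))
  expect_identical(radiusNeighbors(one, 1L, 1), integer(0))
  expect_error(radiusNeighbors(one, 1L, 0), "positive")
})

test_that("subsetting keeps labels aligned", {
  cl <- pointCloud(matrix(rnorm(30), 10, 3),
                   classLabel = rep(c("leaf", "wood"), 5),
                   leafId = c(0L, -1L, 1L, -1L, 2L, -1L, 3L, -1L, 4L, -1L))
  sub <- cl[c(1, 3, 5)]
  expect_identical(npoints(sub), 3L)
  expect_identical(classLabel(sub), rep("leaf", 3))
  expect_identical(leafId(sub), c(0L, 1L, 2L))
})
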