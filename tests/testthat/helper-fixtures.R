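# fixtures built in code: simple geometric clouds used across test files

# regular 3D grid with given spacing
gridCloud <- function(nPerSide = 5L, spacing = 0.01) {
  g <- (seq_len(nPerSide) - 1L) * spacing
  pointCloud(as.matrix(expand.grid(x = g, y = g, z = g)))
}

# points sampled on a cylinder surface (axis +z from origin)
cylinderPoints <- function(n = 2000L, radius = 0.05, length = 1, noiseSd = 0,
                           seed = 1) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  z <- runif(n, 0, length)
  P <- cbind(radius * cos(th), radius * sin(th), z)
  if (noiseSd > 0) P <- P + matrix(rnorm(3 * n, sd = noiseSd), n, 3)
  P
}

# uniform points on a planar disk in the z = 0 plane
diskPoints <- function(n = 500L, R = 0.05, seed = 1) {
  set.seed(seed)
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), 0)
}

# a random rigid motion (rotation + translation)
randomRigidMotion <- function(seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3))
}

applyMotion <- function(P, mot) sweep(P %*% t(mot$R), 2, mot$t, `+`)

# rigid motion that preserves the vertical axis (and therefore the lower-z
# petiole-endpoint convention of the midrib)
zRotationMotion <- function(seed = 1) {
  set.seed(seed)
  a <- runif(1, 0, 2 * pi)
  list(R = matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3),
       t = rnorm(3))
}

# brute-force O(N^2) neighbour oracle
bruteRadiusNeighbors <- function(P, i, radius) {
  d <- sqrt(colSums((t(P) - P[i, ])^2))
  j <- which(d <= radius)
  j[j != i]
}
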