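# small shared helpers

# round-half-up (base round() uses banker's rounding)
roundHalfUp <- function(x) floor(x + 0.5)

# evaluate code under a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rotation matrices about coordinate axes (right-handed, radians)
rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# fixed-radius neighbour lists for all points (flattened 1-based CSR layout)
# includeSelf = FALSE drops the query point from its own list
.radiusLists <- function(coords, radius, maxK = 150L, includeSelf = FALSE) {
  n <- nrow(coords)
  if (n == 0) return(list(flat = integer(0), off = 0L))
  k <- min(n, maxK)
  nn <- RANN::nn2(coords, coords, k = k, searchtype = "radius", radius = radius)
  idx <- nn$nn.idx
  lists <- vector("list", n)
  for (i in seq_len(n)) {
    v <- idx[i, ]
    v <- v[v > 0L]
    if (!includeSelf) v <- v[v != i]
    lists[[i]] <- v
  }
  lens <- lengths(lists)
  list(flat = as.integer(unlist(lists, use.names = FALSE)),
       off = c(0L, cumsum(lens)))
}

# symmetric kNN graph in CSR form for Dijkstra
.knnGraphCSR <- function(coords, k = 10L, edgeCap = Inf) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  if (n < 2L || k < 1L) return(list(off = integer(n + 1L), to = integer(0), w = numeric(0)))
  nn <- RANN::nn2(coords, coords, k = k + 1L)
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(nn$nn.idx[, -1L, drop = FALSE]))
  w <- as.numeric(t(nn$nn.dists[, -1L, drop = FALSE]))
  keep <- w <= edgeCap
  from <- from[keep]; to <- to[keep]; w <- w[keep]
  # symmetrise
  f2 <- c(from, to); t2 <- c(to, from); w2 <- c(w, w)
  o <- order(f2, t2)
  f2 <- f2[o]; t2 <- t2[o]; w2 <- w2[o]
  off <- c(0L, cumsum(tabulate(f2, nbins = n)))
  list(off = as.integer(off), to = as.integer(t2 - 1L), w = w2)
}

# plain DBSCAN on Euclidean coordinates (labels: 0 = noise, 1..K clusters)
.dbscan <- function(coords, eps, minPts) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  nb <- .radiusLists(coords, eps, maxK = min(n, 512L), includeSelf = TRUE)
  deg <- diff(nb$off)
  core <- deg >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      if (core[v]) {
        nbr <- nb$flat[(nb$off[v] + 1L):nb$off[v + 1L]]
        fresh <- nbr[labels[nbr] == 0L]
        labels[fresh] <- cl
        queue <- c(queue, fresh[core[fresh]])
      }
    }
  }
  labels
}

# mean nearest-neighbour spacing of a cloud
.meanSpacing <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(NA_real_)
  nn <- RANN::nn2(coords, coords, k = 2L)
  mean(nn$nn.dists[, 2L])
}

# stage logging with ISO timestamps
.stageLog <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
}
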