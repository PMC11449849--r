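# Shared fixtures and independent brute-force oracles.

dice_overlap <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

# straight tube fixture: horizontal tube of given radius in a small field
make_tube_fixture <- function(radius, extents = c(12 + 6 * radius, 100)) {
  x0 <- extents[1] / 2
  cl <- make_centerline("straight",
                        list(p0 = c(x0, 5), p1 = c(x0, extents[2] - 5)))
  rasterize_tube(cl, radius, extents)
}

# brute-force local mean with edge replication (independent of box_mean)
oracle_local_mean <- function(mat, window) {
  h <- window %/% 2
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      acc <- acc + mat[ii, jj]
    }
    out[i, j] <- acc / window^2
  }
  out
}

# exhaustive 256-bin Otsu search written independently of the implementation
oracle_otsu <- function(img) {
  mn <- min(img); mx <- max(img)
  bins <- pmin(floor((img - mn) / (mx - mn) * 256), 255)
  best_k <- NA; best_v <- -Inf
  for (k in 0:254) {
    lo <- bins <= k
    w0 <- mean(lo); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- mean(bins[lo] + 0.5)
    mu1 <- mean(bins[!lo] + 0.5)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_k <- k }
  }
  mn + (best_k + 1) / 256 * (mx - mn)
}

# direct per-voxel eigen-decomposition clutter filter (single whole-volume
# window), written with explicit loops as the oracle for reconstruct()
oracle_ed <- function(vol4, n_static) {
  d <- dim(vol4)
  n <- d[4]
  x <- matrix(0, prod(d[1:3]), n)
  for (f in seq_len(n)) x[, f] <- as.vector(vol4[, , , f])
  for (f in seq_len(n)) x[, f] <- x[, f] - mean(x[, f])
  cmat <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n))
    cmat[a, b] <- sum(x[, a] * x[, b]) / nrow(x)
  v <- eigen(cmat, symmetric = TRUE)$vectors[, seq_len(n_static), drop = FALSE]
  proj <- diag(n) - v %*% t(v)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    r <- proj %*% x[i, ]
    out[i] <- sqrt(sum(r^2) / n)
  }
  array(out, d[1:3])
}

small_phantom_spec <- function(seed, ...) {
  phantom_spec(extents = c(96L, 96L, 96L), n_vessels_range = c(4L, 6L),
               radius_range = c(2, 4), seed = seed, ...)
}
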