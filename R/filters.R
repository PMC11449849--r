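# Low-level 2D filters shared by the masking and heatmap operations.

# Local mean over a window x window neighborhood with edge replication,
# computed with an integral image on the padded matrix.
box_mean <- function(mat, window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window %% 2L == 0L) stop("window must be odd")
  if (window == 1L) return(mat)
  h <- window %/% 2L
  p <- pad_replicate(mat, h)
  s <- apply(p, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  s <- rbind(0, cbind(0, s))  # integral image with zero border
  nr <- nrow(mat); nc <- ncol(mat)
  i1 <- seq_len(nr); i2 <- i1 + 2L * h
  j1 <- seq_len(nc); j2 <- j1 + 2L * h
  tot <- s[i2 + 1L, j2 + 1L, drop = FALSE] - s[i1, j2 + 1L, drop = FALSE] -
    s[i2 + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
  tot / (window * window)
}

pad_replicate <- function(mat, h) {
  if (h == 0L) return(mat)
  ri <- c(rep(1L, h), seq_len(nrow(mat)), rep(nrow(mat), h))
  ci <- c(rep(1L, h), seq_len(ncol(mat)), rep(ncol(mat), h))
  mat[ri, ci, drop = FALSE]
}

# Separable Gaussian smoothing with a truncated, renormalized kernel
# (radius 3*sigma). Unlike a fixed-size brush convolution this remains
# well-defined when the kernel exceeds the image extent.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  gr <- band_kernel_matrix(nrow(mat), k)
  gc <- band_kernel_matrix(ncol(mat), k)
  gr %*% mat %*% t(gc)
}

# n x n row-stochastic band matrix applying a 1D kernel with edge
# renormalization
band_kernel_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (d in -r:r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    m[cbind(i[ok], j[ok])] <- k[d + r + 1L]
  }
  m / rowSums(m)
}

#' Global Otsu threshold
#'
#' The threshold maximizing the between-class variance of a 256-bin
#' histogram of the image intensities. Candidate thresholds are the 255 cut
#' points between adjacent bins; ties break toward the lower cut. The
#' returned value is the intensity at the winning cut point, so pixels are
#' classified by `intensity > threshold`.
#'
#' @param img An [enface_image()] or numeric matrix with at least two
#'   distinct values.
#' @return The threshold intensity.
#' @export
global_otsu <- function(img) {
  x <- if (inherits(img, "enface_image")) img$data else img
  mn <- min(x); mx <- max(x)
  if (mx == mn) stop("constant image: Otsu threshold undefined")
  bins <- pmin(floor((x - mn) / (mx - mn) * 256), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  p <- counts / sum(counts)
  mids <- (0:255) + 0.5
  w0 <- cumsum(p)[1:255]
  mu0 <- cumsum(p * mids)[1:255]
  mu_t <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)  # cut between bins k-1 and k (0-based)
  mn + k / 256 * (mx - mn)
}

#' Adaptive (local-mean) threshold mask
#'
#' A pixel is set when its intensity exceeds the local mean over a
#' `window x window` neighborhood (edge-replicated) plus `offset`.
#'
#' @param img An [enface_image()] or numeric matrix.
#' @param window Odd window width >= 3.
#' @param offset Additive offset on the local mean.
#' @return A [binary_angio_mask()].
#' @export
adaptive_mask <- function(img, window = 51L, offset = 0) {
  x <- if (inherits(img, "enface_image")) img$data else img
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (window > 2L * max(dim(x)))
    stop("window larger than twice the image extent")
  binary_angio_mask((x > box_mean(x, window) + offset) * 1)
}

#' Multi-scale Hessian vesselness (tubular-structure enhancement)
#'
#' For each scale s the image is Gaussian-smoothed with sigma = s and the
#' eigenvalues of the scale-normalized Hessian are computed per pixel
#' (|lambda1| <= |lambda2|). Bright tubes give lambda2 << 0; the ridge
#' response combines the anisotropy ratio lambda1/lambda2 with the
#' second-order structure magnitude (Frangi-type response, beta = 0.5,
#' structure scale set to half the per-scale maximum). The output is the
#' maximum response over scales, normalized to [0, 1].
#'
#' @param img An [enface_image()] or numeric matrix.
#' @param scales Gaussian scales in pixels, roughly matched to vessel radii;
#'   the default spans capillaries to large vessels at 13.125 um/px.
#' @return An [enface_image()] with values in [0, 1].
#' @export
vesselness <- function(img, scales = c(2, 4, 6, 8)) {
  geom <- pixel_geometry()
  if (inherits(img, "enface_image")) { geom <- img$pixel_geometry; img <- img$data }
  if (length(scales) == 0L || any(scales <= 0))
    stop("scales must be positive and non-empty")
  best <- matrix(0, nrow(img), ncol(img))
  # second-derivative magnitudes below this are numerical noise, not
  # structure (guards near-constant images against response normalization)
  floor_s2 <- (1e-6 * max(abs(img)))^2
  for (s in scales) {
    g <- gaussian_smooth(img, s)
    hxx <- deriv2_rows(g) * s^2
    hyy <- t(deriv2_rows(t(g))) * s^2
    hxy <- deriv1_rows(t(deriv1_rows(g)))
    hxy <- t(hxy) * s^2
    tr <- hxx + hyy
    disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    e1 <- (tr - disc) / 2
    e2 <- (tr + disc) / 2
    # order by magnitude: lam2 is the larger-|.| eigenvalue
    swap <- abs(e1) > abs(e2)
    lam1 <- ifelse(swap, e2, e1)
    lam2 <- ifelse(swap, e1, e2)
    rb2 <- (lam1 / ifelse(lam2 == 0, 1, lam2))^2
    s2 <- lam1^2 + lam2^2
    if (max(s2) <= floor_s2) next
    c2 <- max(s2) / 4  # (half max magnitude)^2
    resp <- exp(-rb2 / 0.5) * (1 - exp(-s2 / (2 * c2)))
    resp[lam2 >= 0] <- 0
    best <- pmax(best, resp)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  enface_image(best, geom)
}

# central second difference along rows (replicated edges)
deriv2_rows <- function(m) {
  n <- nrow(m)
  up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  up + dn - 2 * m
}

# central first difference along rows (replicated edges)
deriv1_rows <- function(m) {
  n <- nrow(m)
  up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  (dn - up) / 2
}
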