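# Separable Gaussian filtering on 3D grids via banded convolution matrices.
# Boundary handling is replicate padding, implemented by accumulating
# out-of-range kernel taps onto the edge sample. Derivative kernels of
# order >= 1 are forced to zero DC response so constant images map to
# exactly zero.

gauss_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(order + 1L,
              g,
              -x / sigma^2 * g,
              (x^2 / sigma^2 - 1) / sigma^2 * g)
  if (order >= 1L) k <- k - mean(k)
  k
}

# n x n banded operator applying kernel k along a line of n samples
band_operator <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (o in (-r):r) {
    j <- pmin(pmax(seq_len(n) + o, 1L), n)
    idx <- cbind(seq_len(n), j)
    B[idx] <- B[idx] + k[o + r + 1L]
  }
  B
}

# apply a 1D kernel along one axis of a 3D array
apply_kernel_axis <- function(a, k, axis) {
  d <- dim(a)
  if (axis == 1L) {
    B <- band_operator(d[1], k)
    array(B %*% matrix(a, d[1], d[2] * d[3]), dim = d)
  } else if (axis == 2L) {
    B <- band_operator(d[2], k)
    ap <- aperm(a, c(2, 1, 3))
    out <- array(B %*% matrix(ap, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    aperm(out, c(2, 1, 3))
  } else {
    B <- band_operator(d[3], k)
    array(matrix(a, d[1] * d[2], d[3]) %*% t(B), dim = d)
  }
}

# isotropic-in-mm Gaussian smoothing; sigma_mm scalar, spacing per-axis mm
gauss_smooth_3d <- function(a, sigma_mm, spacing) {
  out <- a
  for (ax in 1:3) {
    s_vox <- sigma_mm / spacing[ax]
    if (s_vox > 1e-8)
      out <- apply_kernel_axis(out, gauss_kernel(s_vox), ax)
  }
  out
}

# Hessian components of a 3D image at Gaussian scale sigma_mm, derivatives
# in 1/mm^2 using spacing-aware kernels. Returns list xx, yy, zz, xy, xz, yz.
hessian_3d <- function(a, sigma_mm, spacing) {
  orders <- list(xx = c(2, 0, 0), yy = c(0, 2, 0), zz = c(0, 0, 2),
                 xy = c(1, 1, 0), xz = c(1, 0, 1), yz = c(0, 1, 1))
  lapply(orders, function(o) {
    out <- a
    scale <- 1
    for (ax in 1:3) {
      s_vox <- sigma_mm / spacing[ax]
      out <- apply_kernel_axis(out, gauss_kernel(s_vox, order = o[ax]), ax)
      scale <- scale / spacing[ax]^o[ax]
    }
    out * scale
  })
}
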