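# Separable Gaussian smoothing of a 3-D array, sigma in mm, reflect boundary.
# Implemented as a banded-matrix multiply along each axis in turn.

gaussian_kernel_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- i + o
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    idx <- cbind(i, j)
    K[idx] <- K[idx] + w[o + r + 1L]
  }
  K
}

gaussian_smooth_3d <- function(a, sigma_mm, spacing) {
  d <- dim(a)
  sigma_mm <- rep(sigma_mm, length.out = 3)
  for (ax in 1:3) {
    if (sigma_mm[ax] <= 0 || d[ax] < 2L) next
    sv <- sigma_mm[ax] / spacing[ax]
    K <- gaussian_kernel_matrix(d[ax], sv)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- K %*% matrix(ap, nrow = d[ax])
    dim(m) <- d[perm]
    a <- aperm(m, order(perm))
  }
  a
}

# Block-average downsampling by an integer factor per axis (truncating any
# remainder rows/columns/slices).
block_average <- function(a, f) {
  f <- as.integer(rep(f, length.out = 3))
  d <- dim(a)
  nd <- d %/% f
  a <- a[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]), seq_len(nd[3] * f[3]),
         drop = FALSE]
  dim(a) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dim = nd)
}
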