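# Trilinear interpolation of a 3D array at continuous zero-based voxel
# coordinates. Outside the grid the array is either clamped to the border
# (border = "clamp") or treated as `fill` (border = "zero").
interpTrilinear <- function(arr, idx0, border = c("clamp", "zero"),
                            fill = 0) {
  border <- match.arg(border)
  d <- dim(arr)
  n <- nrow(idx0)
  out <- numeric(n)
  inside <- rep(TRUE, n)
  if (border == "zero") {
    inside <- idx0[, 1] > -1 & idx0[, 1] < d[1] &
              idx0[, 2] > -1 & idx0[, 2] < d[2] &
              idx0[, 3] > -1 & idx0[, 3] < d[3]
    out[!inside] <- fill
    if (!any(inside)) return(out)
    idx0 <- idx0[inside, , drop = FALSE]
  }
  x <- pmin(pmax(idx0[, 1], 0), d[1] - 1)
  y <- pmin(pmax(idx0[, 2], 0), d[2] - 1)
  z <- pmin(pmax(idx0[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  if (d[1] < 2) x0 <- rep(0, length(x))
  if (d[2] < 2) y0 <- rep(0, length(y))
  if (d[3] < 2) z0 <- rep(0, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  lin <- function(i, j, k) arr[1L + i + d[1] * (j + d[2] * k)]
  val <-
    lin(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    lin(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    lin(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    lin(x1, y1, z0) * fx       * fy       * (1 - fz) +
    lin(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    lin(x1, y0, z1) * fx       * (1 - fy) * fz +
    lin(x0, y1, z1) * (1 - fx) * fy       * fz +
    lin(x1, y1, z1) * fx       * fy       * fz
  out[inside] <- val
  out
}

# Full (zero-padded) 3D convolution via FFT. Returns array of dim
# dim(a) + dim(k) - 1. Used for morphological dilation on cropped boxes.
fftConvolve3 <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  dn <- da + dk - 1L
  ap <- array(0, dn); ap[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  kp <- array(0, dn); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  Re(fft(fft(ap) * fft(kp), inverse = TRUE)) / prod(dn)
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels per axis.
# Reflective borders via kernel renormalisation through convolution of a
# ones-array would be costly; simple zero-padding with weight correction is
# adequate for registration preprocessing.
gaussianSmooth3 <- function(arr, sigmaVox) {
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    out <- convolveAlong(out, k, ax)
  }
  out
}

# Convolve along one axis with a 1D kernel, replicate-padding the borders.
convolveAlong <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(k) - 1L) / 2L
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(nrow(m), r), , drop = FALSE])
  out <- matrix(0, nrow = da[1], ncol = ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * pad[t:(t + da[1] - 1L), , drop = FALSE]
  res <- array(out, da)
  aperm(res, order(perm))
}

# Block-average downsampling by integer factors (used by the
# multi-resolution registration pyramid).
downsampleMean3 <- function(arr, f) {
  d <- dim(arr)
  nd <- d %/% f
  cr <- arr[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]),
            seq_len(nd[3] * f[3]), drop = FALSE]
  dim(cr) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  apply(cr, c(2, 4, 6), mean)
}
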