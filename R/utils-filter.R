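# Separable 3D Gaussian smoothing and a 6-neighbour Laplacian with
# replicate-edge handling. Written directly on R arrays: each 1D pass is a
# weighted sum of index-shifted slabs, which keeps everything vectorised.

gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-h):h)^2 / (2 * sigma^2))
  w / sum(w)
}

shift_axis <- function(x, k, axis) {
  # shift x by k voxels along axis with replicate-edge padding
  d <- dim(x)
  idx <- pmin(pmax(seq_len(d[axis]) + k, 1L), d[axis])
  switch(axis,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

conv_axis <- function(x, w, axis) {
  h <- (length(w) - 1L) %/% 2L
  out <- array(0, dim = dim(x))
  for (k in -h:h) out <- out + w[k + h + 1L] * shift_axis(x, k, axis)
  out
}

gauss_smooth3d <- function(x, sigma) {
  w <- gauss_kernel(sigma)
  for (axis in 1:3) x <- conv_axis(x, w, axis)
  x
}

laplacian3d <- function(x) {
  out <- -6 * x
  for (axis in 1:3)
    out <- out + shift_axis(x, -1L, axis) + shift_axis(x, 1L, axis)
  out
}
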