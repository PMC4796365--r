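# Separable Gaussian filtering used by both the renderer (PSF) and the
# segmentation front end. Implemented as two banded-matrix products with
# row-normalized kernels, so borders are renormalized rather than padded.
# Kernel matrices are memoised per (n, sigma).

.blur_cache <- new.env(parent = emptyenv())

gauss_kernel_matrix <- function(n, sigma, transpose = FALSE) {
  key <- sprintf("%d_%g_%d", n, sigma, transpose)
  k <- .blur_cache[[key]]
  if (is.null(k)) {
    i <- seq_len(n)
    k <- outer(i, i, function(a, b) stats::dnorm(a - b, sd = sigma))
    k[abs(row(k) - col(k)) > ceiling(4 * sigma)] <- 0
    k <- k / rowSums(k)
    if (transpose) k <- t(k)
    .blur_cache[[key]] <- k
  }
  k
}

# Gaussian blur of a matrix, sigma in pixels. sigma <= 0 returns the input.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  ky <- gauss_kernel_matrix(nrow(m), sigma)
  # the x pass uses the transposed kernel so each output column is a
  # unit-weight average of source columns
  kxT <- gauss_kernel_matrix(ncol(m), sigma, transpose = TRUE)
  ky %*% m %*% kxT
}
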