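## Separable Gaussian smoothing of 3D arrays.
##
## Each axis is filtered with a normalized discrete Gaussian kernel
## truncated at 3 sigma; edges are handled by replicate-padding so that
## flat regions stay exactly flat.  stats::filter runs the convolution in
## C column-wise, so each pass reshapes the volume to put the filtered
## axis first.

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## sigma: length-3 vector in voxel units; sigma <= 0 skips the axis.
gauss_smooth3 <- function(a, sigma) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(sigma) == 3L)
  out <- a
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gauss_kernel(sigma[ax])
    r <- (length(k) - 1L) / 2L
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    m <- aperm(out, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    mp <- m[c(rep(1L, r), seq_len(dm[1]), rep(dm[1], r)), , drop = FALSE]
    f <- stats::filter(mp, k, sides = 2)
    m <- matrix(f[r + seq_len(dm[1]), ], nrow = dm[1])
    m <- array(m, dm)
    out <- aperm(m, order(perm))
  }
  out
}
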