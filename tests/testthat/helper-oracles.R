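# Independent brute-force oracles used across the suite.

# exact nearest-foreground distance by exhaustive search
brute_edt <- function(occ, spacing = c(1, 1, 1)) {
  d <- dim(occ)
  fg <- which(occ, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(fg) == 0) return(out)
  fgs <- t(fg) * spacing
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  out[] <- apply(co, 1, function(p) sqrt(min(colSums((fgs - p * spacing)^2))))
  out
}

# exhaustive largest-covering-sphere local thickness (same digital
# definition as the implementation, independent code path)
brute_thickness <- function(occ) {
  d <- dim(occ)
  r <- brute_edt(!occ)          # inscribed radius at every voxel
  fg <- which(occ, arr.ind = TRUE)
  out <- array(0, d)
  for (i in seq_len(nrow(fg))) {
    p <- fg[i, ]
    best <- 0
    for (j in seq_len(nrow(fg))) {
      c_ <- fg[j, ]
      rc <- r[c_[1], c_[2], c_[3]]
      if (sum((p - c_)^2) < rc^2) best <- max(best, 2 * rc - 1)
    }
    out[p[1], p[2], p[3]] <- max(best, 1)
  }
  out
}

# naive sliding-window 2x2x2 configuration tally
naive_config_counts <- function(occ) {
  p <- array(FALSE, dim(occ) + 2L)
  p[1 + seq_len(dim(occ)[1]), 1 + seq_len(dim(occ)[2]), 1 + seq_len(dim(occ)[3])] <- occ
  d <- dim(p)
  counts <- integer(256)
  for (x in seq_len(d[1] - 1)) for (y in seq_len(d[2] - 1)) for (z in seq_len(d[3] - 1)) {
    cfg <- 0L
    for (k in 0:1) for (j in 0:1) for (i in 0:1)
      if (p[x + i, y + j, z + k]) cfg <- cfg + 2L^(i + 2L * j + 4L * k)
    counts[cfg + 1L] <- counts[cfg + 1L] + 1L
  }
  counts
}

# finite-difference Hessian eigenvalues at one voxel of a smooth field
fd_hessian_eigs <- function(f, at, h = 1) {
  i <- at[1]; j <- at[2]; k <- at[3]
  H <- matrix(0, 3, 3)
  idx <- function(di, dj, dk) f[i + di, j + dj, k + dk]
  H[1,1] <- (idx(1,0,0) - 2*idx(0,0,0) + idx(-1,0,0)) / h^2
  H[2,2] <- (idx(0,1,0) - 2*idx(0,0,0) + idx(0,-1,0)) / h^2
  H[3,3] <- (idx(0,0,1) - 2*idx(0,0,0) + idx(0,0,-1)) / h^2
  H[1,2] <- H[2,1] <- (idx(1,1,0) - idx(1,-1,0) - idx(-1,1,0) + idx(-1,-1,0)) / (4*h^2)
  H[1,3] <- H[3,1] <- (idx(1,0,1) - idx(1,0,-1) - idx(-1,0,1) + idx(-1,0,-1)) / (4*h^2)
  H[2,3] <- H[3,2] <- (idx(0,1,1) - idx(0,1,-1) - idx(0,-1,1) + idx(0,-1,-1)) / (4*h^2)
  eigen(H, symmetric = TRUE)$values
}

# random volume split by two overlapping half-space windows along x:
# a pair family on which Minkowski additivity holds exactly on the lattice
split_pair <- function(n = 6, density = 0.5) {
  X <- array(stats::runif(n^3) < density, rep(n, 3))
  t1 <- sample.int(n - 2, 1) + 1          # 2..n-1
  t2 <- t1 + sample.int(n - t1, 1) - 1    # t1..n-1
  A <- X; A[(t2 + 1):n, , ] <- FALSE
  B <- X; B[1:(t1 - 1), , ] <- FALSE
  list(a = binary_volume(A), b = binary_volume(B))
}

tiny_ball_vol <- function(r = 3) make_ball(r)
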