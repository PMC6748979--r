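## The four 3D Minkowski functionals of a binary voxel volume.
##
## The volume is realized as a union of closed unit cubes, which makes the
## foreground 26-connected and the background 6-connected (the standard
## Jordan-separating pair).  All functionals are linear in the histogram of
## 2 x 2 x 2 voxel configurations of the one-layer-padded volume:
##   * volume        - foreground voxel count (exact integer),
##   * Euler number  - alternating cell count of the cubical complex,
##                     via a 256-entry lookup table derived from
##                     minimal-vertex cell attribution (exact integer),
##   * surface area  - Cauchy-Crofton estimate over the 13 lattice
##                     directions with spherical direction weights
##                     (converges for smooth objects); the exact digital
##                     boundary face count is reported as a diagnostic,
##   * mean breadth  - Crofton over the three axis directions: mean over
##                     axes of the summed 2D Euler characteristics of the
##                     slices; normalized so a ball's mean breadth is its
##                     diameter.

# ---- configuration machinery -----------------------------------------------

## 256 x 8 logical matrix: row c+1 holds the bits of configuration c.
## Bit n = 1 + i + 2j + 4k is the voxel at window offset (i, j, k).
config_bits <- function() {
  cfg <- 0:255
  m <- matrix(FALSE, 256L, 8L)
  for (n in 1:8) m[, n] <- bitwAnd(cfg, bitwShiftL(1L, n - 1L)) > 0L
  m
}

## Euler lookup table for the closed-cube (foreground-26 / background-6)
## convention.  A cell of the cubical complex is attributed to the 2x2x2
## window centred on its minimal lattice vertex; it is present when any
## incident voxel is foreground.  Contribution = V - E + F - C.
euler_lut_26 <- function() {
  b <- config_bits()
  bit <- function(i, j, k) b[, 1L + i + 2L * j + 4L * k]
  v <- rowSums(b) > 0
  e_x <- bit(1,0,0) | bit(1,1,0) | bit(1,0,1) | bit(1,1,1)
  e_y <- bit(0,1,0) | bit(1,1,0) | bit(0,1,1) | bit(1,1,1)
  e_z <- bit(0,0,1) | bit(1,0,1) | bit(0,1,1) | bit(1,1,1)
  f_x <- bit(0,1,1) | bit(1,1,1)   # face normal to x (spans y, z)
  f_y <- bit(1,0,1) | bit(1,1,1)
  f_z <- bit(1,1,0) | bit(1,1,1)
  cc <- bit(1,1,1)
  as.numeric(v) - (e_x + e_y + e_z) + (f_x + f_y + f_z) - as.numeric(cc)
}

## Dual (foreground-6 / background-26) table: open-star complex, a cell is
## present only when all incident voxels are foreground; weights (-1)^codim.
euler_lut_6 <- function() {
  b <- config_bits()
  bit <- function(i, j, k) b[, 1L + i + 2L * j + 4L * k]
  v <- rowSums(b) == 8
  e_x <- bit(1,0,0) & bit(1,1,0) & bit(1,0,1) & bit(1,1,1)
  e_y <- bit(0,1,0) & bit(1,1,0) & bit(0,1,1) & bit(1,1,1)
  e_z <- bit(0,0,1) & bit(1,0,1) & bit(0,1,1) & bit(1,1,1)
  f_x <- bit(0,1,1) & bit(1,1,1)
  f_y <- bit(1,0,1) & bit(1,1,1)
  f_z <- bit(1,1,0) & bit(1,1,1)
  cc <- bit(1,1,1)
  as.numeric(cc) - (f_x + f_y + f_z) + (e_x + e_y + e_z) - as.numeric(v)
}

## Per-configuration transition counts for the Crofton surface estimate.
## Pair multiplicities (1/4 axis, 1/2 face diagonal, 1 space diagonal)
## compensate for windows sharing the same voxel pair.
surface_luts <- function() {
  b <- config_bits()
  bit <- function(i, j, k) b[, 1L + i + 2L * j + 4L * k]
  x <- function(p, q) abs(as.numeric(p) - as.numeric(q))
  ax <- rep(0, 256)
  for (j in 0:1) for (k in 0:1) ax <- ax + x(bit(0,j,k), bit(1,j,k)) / 4
  for (i in 0:1) for (k in 0:1) ax <- ax + x(bit(i,0,k), bit(i,1,k)) / 4
  for (i in 0:1) for (j in 0:1) ax <- ax + x(bit(i,j,0), bit(i,j,1)) / 4
  fd <- rep(0, 256)
  for (k in 0:1) fd <- fd + (x(bit(0,0,k), bit(1,1,k)) + x(bit(0,1,k), bit(1,0,k))) / 2
  for (j in 0:1) fd <- fd + (x(bit(0,j,0), bit(1,j,1)) + x(bit(0,j,1), bit(1,j,0))) / 2
  for (i in 0:1) fd <- fd + (x(bit(i,0,0), bit(i,1,1)) + x(bit(i,0,1), bit(i,1,0))) / 2
  sd_ <- x(bit(0,0,0), bit(1,1,1)) + x(bit(0,0,1), bit(1,1,0)) +
         x(bit(0,1,0), bit(1,0,1)) + x(bit(0,1,1), bit(1,0,0))
  list(axis = ax, facediag = fd, spacediag = sd_)
}

## 2D Euler contribution (closed squares, 8-connected foreground) of a
## 2 x 2 pixel window, minimal-vertex attribution: V - E + F.
chi2d_w <- function(b00, b10, b01, b11) {
  v <- b00 | b10 | b01 | b11
  e1 <- b10 | b11     # edge +x: pixels with i = 1
  e2 <- b01 | b11     # edge +y
  f <- b11
  as.numeric(v) - (e1 + e2) + as.numeric(f)
}

## Mean-breadth tables: per axis, the summed slice chi_2D expressed on 3D
## configurations (each 2D window appears in exactly two 3D windows).
breadth_luts <- function() {
  b <- config_bits()
  bit <- function(i, j, k) b[, 1L + i + 2L * j + 4L * k]
  # slices perpendicular to z: 2D bits are (i, j) at fixed k
  bz <- (chi2d_w(bit(0,0,0), bit(1,0,0), bit(0,1,0), bit(1,1,0)) +
         chi2d_w(bit(0,0,1), bit(1,0,1), bit(0,1,1), bit(1,1,1))) / 2
  by <- (chi2d_w(bit(0,0,0), bit(1,0,0), bit(0,0,1), bit(1,0,1)) +
         chi2d_w(bit(0,1,0), bit(1,1,0), bit(0,1,1), bit(1,1,1))) / 2
  bx <- (chi2d_w(bit(0,0,0), bit(0,1,0), bit(0,0,1), bit(0,1,1)) +
         chi2d_w(bit(1,0,0), bit(1,1,0), bit(1,0,1), bit(1,1,1))) / 2
  list(x = bx, y = by, z = bz)
}

.vm_luts <- new.env(parent = emptyenv())
get_luts <- function() {
  if (is.null(.vm_luts$euler26)) {
    .vm_luts$euler26 <- euler_lut_26()
    .vm_luts$euler6 <- euler_lut_6()
    .vm_luts$surface <- surface_luts()
    .vm_luts$breadth <- breadth_luts()
  }
  .vm_luts
}

# Spherical quadrature weights for the 26-neighbourhood directions
# (Voronoi areas on the unit sphere / 4 pi): 6 axis, 12 face-diagonal,
# 8 space-diagonal unit vectors.
.crofton_w <- c(axis = 0.045778, facediag = 0.036981, spacediag = 0.035196)

#' Histogram of 2x2x2 voxel configurations
#'
#' Counts every 2x2x2 neighbourhood configuration of the volume after
#' padding it with one layer of background on all faces.  Configuration
#' index is \eqn{\sum b_{ijk} 2^{i + 2j + 4k}} over window offsets
#' \eqn{(i,j,k) \in \{0,1\}^3}.  All four Minkowski functionals are linear
#' functionals of this histogram.
#'
#' @param vol a [binary_volume()].
#' @return integer vector of length 256; entries sum to
#'   `(nx+1)*(ny+1)*(nz+1)`.
#' @export
config_counts <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  p <- pad3(vol$occupancy)
  d <- dim(p)
  sx <- seq_len(d[1] - 1L); sy <- seq_len(d[2] - 1L); sz <- seq_len(d[3] - 1L)
  cfg <- array(0, d - 1L)
  for (k in 0:1) for (j in 0:1) for (i in 0:1) {
    w <- 2^(i + 2L * j + 4L * k)
    cfg <- cfg + w * p[sx + i, sy + j, sz + k]
  }
  tabulate(as.vector(cfg) + 1L, nbins = 256L)
}

#' The four 3D Minkowski functionals of a binary volume
#'
#' @param vol a [binary_volume()]; its `connectivity` field selects the
#'   digital convention (default foreground-26 / background-6).
#' @param units_mode `"voxel"` (default) or `"physical"`.  Volume and Euler
#'   number are exact in either mode; in physical mode surface and mean
#'   breadth are exact only for isotropic spacing (anisotropic grids are
#'   scaled by the mean voxel dimension, with a warning).
#' @return an object of class `mf_vector`: a list with `volume`,
#'   `surface_area` (Crofton-weighted), `surface_area_facecount` (exact
#'   digital boundary faces, diagnostic), `mean_breadth` (ball-diameter
#'   normalization), `mean_curvature_integral` (\eqn{2\pi\times} mean
#'   breadth), `euler` (exact integer) and `units_mode`.
#' @export
minkowski_3d <- function(vol, units_mode = c("voxel", "physical")) {
  units_mode <- match.arg(units_mode)
  stopifnot(inherits(vol, "binary_volume"))
  luts <- get_luts()
  counts <- config_counts(vol)
  elut <- if (identical(vol$connectivity, "26-6")) luts$euler26 else luts$euler6
  euler <- round(sum(counts * elut))
  volume <- sum(vol$occupancy)
  s <- luts$surface
  surf <- 4 * (.crofton_w[["axis"]] * sum(counts * s$axis) +
               .crofton_w[["facediag"]] * sum(counts * s$facediag) / sqrt(2) +
               .crofton_w[["spacediag"]] * sum(counts * s$spacediag) / sqrt(3))
  facecount <- sum(counts * (s$axis)) * 1  # axis transitions = boundary faces
  br <- luts$breadth
  breadth <- (sum(counts * br$x) + sum(counts * br$y) + sum(counts * br$z)) / 3
  if (units_mode == "physical") {
    sp <- vol$spacing
    volume <- volume * prod(sp)
    if (max(sp) / min(sp) > 1 + 1e-9) {
      warnf("anisotropic spacing: physical surface/breadth use the mean voxel dimension")
      s2 <- prod(sp)^(2 / 3); s1 <- prod(sp)^(1 / 3)
    } else {
      s2 <- sp[1]^2; s1 <- sp[1]
    }
    surf <- surf * s2; facecount <- facecount * s2; breadth <- breadth * s1
  }
  structure(list(volume = volume,
                 surface_area = unname(surf),
                 surface_area_facecount = unname(facecount),
                 mean_breadth = unname(breadth),
                 mean_curvature_integral = unname(2 * pi * breadth),
                 euler = as.integer(euler),
                 units_mode = units_mode),
            class = "mf_vector")
}

#' @export
print.mf_vector <- function(x, ...) {
  cat(sprintf("<mf_vector> [%s units]\n", x$units_mode))
  cat(sprintf("  volume        %g\n", x$volume))
  cat(sprintf("  surface area  %.4g (face count %g)\n",
              x$surface_area, x$surface_area_facecount))
  cat(sprintf("  mean breadth  %.4g\n", x$mean_breadth))
  cat(sprintf("  Euler number  %d\n", x$euler))
  invisible(x)
}

#' @export
as.data.frame.mf_vector <- function(x, ...) {
  data.frame(vol = x$volume, surf_area = x$surface_area,
             mean_breadth = x$mean_breadth, euler3D = x$euler)
}

# ---- connected components ---------------------------------------------------

# positive half of the 26- and 6-neighbourhoods
.offsets26 <- local({
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  o[o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0))), ,
    drop = FALSE]
})
.offsets6 <- .offsets26[rowSums(abs(.offsets26)) == 1, , drop = FALSE]

#' Label connected components of a 3D logical array
#'
#' @param occ 3D logical array.
#' @param connectivity 26 or 6.
#' @return list with `labels` (integer array, 0 = background) and `sizes`
#'   (voxel count per component, decreasing label order not guaranteed).
#' @export
label_components <- function(occ, connectivity = 26) {
  stopifnot(is.array(occ), length(dim(occ)) == 3L)
  offs <- if (connectivity == 26) .offsets26 else if (connectivity == 6) .offsets6
          else stopf("connectivity must be 26 or 6")
  d <- dim(occ)
  idx <- which(occ)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(list(labels = labels, sizes = integer(0)))
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sh <- shift3(occ, o[1], o[2], o[3])
    w <- which(occ & sh)
    if (length(w)) {
      lin <- o[1] + d[1] * (o[2] + d[2] * o[3])
      edges[[r]] <- cbind(vid[w - lin], vid[w])
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    labels[idx] <- seq_along(idx)
    return(list(labels = labels, sizes = rep(1L, length(idx))))
  }
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

# ---- Betti-number oracle ----------------------------------------------------

## Direct (non-LUT) Euler characteristic of the closed cubical complex:
## count distinct vertices, edges, faces and cubes by array shifts.
chi_cell_complex <- function(occ) {
  p <- pad3(occ)
  any8 <- function(pairs) {
    d <- dim(p)
    sx <- seq_len(d[1] - 1L); sy <- seq_len(d[2] - 1L); sz <- seq_len(d[3] - 1L)
    acc <- array(FALSE, d - 1L)
    for (q in pairs) acc <- acc | p[sx + q[1], sy + q[2], sz + q[3]]
    sum(acc)
  }
  all_off <- expand.grid(0:1, 0:1, 0:1)
  offs <- lapply(seq_len(8), function(r) as.integer(all_off[r, ]))
  V <- any8(offs)                                             # lattice vertices
  E <- any8(offs[vapply(offs, function(o) o[1] == 1L, TRUE)]) +
       any8(offs[vapply(offs, function(o) o[2] == 1L, TRUE)]) +
       any8(offs[vapply(offs, function(o) o[3] == 1L, TRUE)])
  FF <- any8(offs[vapply(offs, function(o) o[2] == 1L && o[3] == 1L, TRUE)]) +
        any8(offs[vapply(offs, function(o) o[1] == 1L && o[3] == 1L, TRUE)]) +
        any8(offs[vapply(offs, function(o) o[1] == 1L && o[2] == 1L, TRUE)])
  C <- sum(occ)
  V - E + FF - C
}

#' Betti numbers of a small binary volume (exhaustive oracle)
#'
#' Independent topology oracle for testing: `b0` is the number of
#' 26-connected foreground components, `b2` the number of 6-connected
#' background components fully enclosed by the foreground, and
#' `b1 = b0 + b2 - chi` where `chi` is the Euler characteristic obtained
#' by directly counting vertices, edges, faces and cubes of the cubical
#' complex (a code path independent of the lookup table used by
#' [minkowski_3d()]).
#'
#' @param vol a [binary_volume()] with grid at most 20 voxels per side.
#' @return named integer vector `(b0, b1, b2)`.
#' @export
betti_numbers_small <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  d <- dim(vol$occupancy)
  if (any(d > 20L)) stopf("betti_numbers_small is exhaustive; grid must be <= 20^3")
  occ <- vol$occupancy
  b0 <- length(label_components(occ, 26)$sizes)
  pbg <- !pad3(occ)                       # padded background
  lab <- label_components(pbg, 6)
  border <- unique(c(lab$labels[1, , ], lab$labels[dim(pbg)[1], , ],
                     lab$labels[, 1, ], lab$labels[, dim(pbg)[2], ],
                     lab$labels[, , 1], lab$labels[, , dim(pbg)[3]]))
  b2 <- length(setdiff(seq_along(lab$sizes), border[border > 0]))
  chi <- chi_cell_complex(occ)
  b1 <- b0 + b2 - chi
  c(b0 = b0, b1 = as.integer(b1), b2 = b2)
}

# ---- additivity -------------------------------------------------------------

#' Additivity residual of the Minkowski functionals
#'
#' Computes `MF(A union B) - MF(A) - MF(B) + MF(A intersect B)` for each of
#' the four functionals, on the voxel lattice.  The residual is identically
#' zero whenever the two volumes touch only where they overlap (for example
#' two overlapping sampling windows of a common specimen).  Pairs that make
#' voxel contact outside their overlap pick up boundary terms from the
#' lower-dimensional polyhedral intersection that the voxel-set intersection
#' cannot represent; see the package vignette.
#'
#' @param a,b two [binary_volume()]s on the same grid.
#' @return named numeric vector of residuals
#'   `(volume, surface_area, mean_breadth, euler)`.
#' @export
mf_additivity_check <- function(a, b) {
  stopifnot(inherits(a, "binary_volume"), inherits(b, "binary_volume"))
  if (!identical(dim(a$occupancy), dim(b$occupancy)))
    stopf("volumes must share a grid")
  mk <- function(occ) minkowski_3d(binary_volume(occ, a$spacing, a$connectivity))
  m_a <- mk(a$occupancy); m_b <- mk(b$occupancy)
  m_u <- mk(a$occupancy | b$occupancy); m_i <- mk(a$occupancy & b$occupancy)
  res <- function(f) m_u[[f]] - m_a[[f]] - m_b[[f]] + m_i[[f]]
  c(volume = res("volume"), surface_area = res("surface_area"),
    mean_breadth = res("mean_breadth"), euler = res("euler"))
}
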