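## Local thickness: the diameter of the largest inscribed sphere through
## each foreground voxel (Hildebrand-Ruegsegger), by exact EDT followed by
## sphere propagation.  Inscribed spheres are only well defined on
## isotropic grids, so anisotropic volumes are resampled (nearest
## neighbour) to their smallest spacing first and the result mapped back.

#' Local thickness map of a binary volume
#'
#' Every foreground voxel is assigned the diameter of the largest sphere
#' that fits inside the foreground and covers it.  A sphere centred at a
#' foreground voxel `c` has radius `EDT(c)` (distance to the nearest
#' background voxel centre); the assigned diameter is `2 EDT(c) - 1`,
#' measuring to the digital surface, so an isolated voxel has thickness 1.
#' Distances are computed within the grid: the volume boundary is not
#' treated as background, so tubes running through the field of view keep
#' their lateral calibre at the open ends.
#'
#' @param vol a [binary_volume()] with non-empty foreground.
#' @return a [thickness_map()]; diameters are in micrometres (equal to
#'   voxel units when the spacing is 1).
#' @export
local_thickness <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  occ <- vol$occupancy
  if (!any(occ)) stopf("local thickness of an empty foreground is undefined")
  if (!any(!occ)) stopf("volume has no background: thickness is unbounded")
  sp <- vol$spacing
  iso <- max(sp) / min(sp) <= 1 + 1e-9
  if (iso) {
    occ_iso <- occ
    unit <- sp[1]
  } else {
    unit <- min(sp)
    d <- dim(occ)
    d_iso <- pmax(2L, as.integer(round(d * sp / unit)))
    # nearest-neighbour index maps per axis
    maps <- lapply(1:3, function(a)
      pmin(d[a], pmax(1L, as.integer(round((seq_len(d_iso[a]) - 0.5) *
                                             d[a] / d_iso[a] + 0.5)))))
    occ_iso <- occ[maps[[1]], maps[[2]], maps[[3]]]
  }
  di <- dim(occ_iso)
  r <- .edt3d_cpp(as.logical(!occ_iso), as.integer(di), c(1, 1, 1))
  th <- .local_thickness_cpp(as.logical(occ_iso), r, as.integer(di))
  th <- array(th, di)
  if (!iso) {
    d <- dim(occ)
    back <- lapply(1:3, function(a)
      pmin(di[a], pmax(1L, as.integer(round((seq_len(d[a]) - 0.5) *
                                              di[a] / d[a] + 0.5)))))
    th <- th[back[[1]], back[[2]], back[[3]]]
    th[!occ] <- 0
    th[occ & th <= 0] <- 1  # resampling can miss single-voxel structures
  }
  thickness_map(th * unit, vol,
                meta = list(isotropic = iso, unit = unit))
}

#' Calibre statistics of a thickness map
#'
#' Mean and standard deviation of the local diameter over the measured
#' (foreground) voxels - the per-sample calibre summary.
#'
#' @param map a [thickness_map()].
#' @return list with `mean_diameter`, `sd`, `n_voxels`.
#' @export
thickness_stats <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  d <- map$diameters[map$diameters > 0]
  if (length(d) == 0) stopf("empty thickness map")
  list(mean_diameter = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0,
       n_voxels = length(d))
}
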