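## Domain containers for 3D volumes.
##
## Axis order is (x, y, z) with z the optical-section index; TIFF pages map
## to z.  Coordinates are 0-based in all geometric formulas; R indexing is
## 1-based as usual.  Spacing is (dx, dy, dz) in micrometres per voxel; the
## default (1, 1, 1) expresses everything in voxel units.

#' Construct a z-stack (3D intensity volume)
#'
#' @param voxels 3D numeric array of non-negative intensities, dimension
#'   `(nx, ny, nz)` with at least 2 planes in z.
#' @param spacing numeric length-3, physical size of a voxel `(dx, dy, dz)`
#'   in micrometres.  Defaults to voxel units `(1, 1, 1)`.
#' @param meta free-form named list of provenance (sample id, age, ...).
#' @return an object of class `zstack` with fields `voxels`, `spacing`,
#'   `meta`.
#' @export
zstack <- function(voxels, spacing = c(1, 1, 1), meta = list()) {
  voxels <- as_volume_array(voxels)
  if (dim(voxels)[3] < 2L)
    stopf("a z-stack needs at least 2 planes in z, got %d", dim(voxels)[3])
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stopf("z-stack intensities must all be finite")
  if (any(voxels < 0))
    stopf("z-stack intensities must be >= 0")
  check_spacing(spacing)
  structure(list(voxels = voxels, spacing = as.numeric(spacing), meta = meta),
            class = "zstack")
}

#' Construct a binary occupancy volume
#'
#' @param occupancy 3D array coercible to logical/0-1: 1 = vessel,
#'   0 = everything else.
#' @param spacing voxel size `(dx, dy, dz)` in micrometres.
#' @param connectivity declared digital connectivity pair for foreground /
#'   background, either `"26-6"` (default) or `"6-26"`.
#' @param meta free-form named list.
#' @return an object of class `binary_volume`.
#' @export
binary_volume <- function(occupancy, spacing = c(1, 1, 1),
                          connectivity = c("26-6", "6-26"), meta = list()) {
  connectivity <- match.arg(connectivity)
  occupancy <- as_volume_array(occupancy)
  if (anyNA(occupancy)) stopf("occupancy must not contain NA")
  u <- unique(as.vector(occupancy))
  if (!all(u %in% c(0, 1)))
    stopf("occupancy values must be strictly in {0, 1}")
  check_spacing(spacing)
  structure(list(occupancy = array(as.logical(occupancy), dim(occupancy)),
                 spacing = as.numeric(spacing),
                 connectivity = connectivity, meta = meta),
            class = "binary_volume")
}

#' Construct a local-thickness map
#'
#' @param diameters 3D numeric array of local vessel diameters (micrometres),
#'   zero outside the foreground.
#' @param source the `binary_volume` the map annotates.
#' @param meta free-form named list.
#' @return an object of class `thickness_map`.
#' @export
thickness_map <- function(diameters, source, meta = list()) {
  diameters <- as_volume_array(diameters)
  stopifnot(inherits(source, "binary_volume"))
  if (!identical(dim(diameters), dim(source$occupancy)))
    stopf("diameters and source volume dimensions differ")
  if (any(diameters < 0)) stopf("diameters must be >= 0")
  fg <- source$occupancy
  if (any(diameters[fg] <= 0) || any(diameters[!fg] != 0))
    stopf("diameters must be > 0 exactly on foreground voxels")
  structure(list(diameters = diameters, source = source, meta = meta),
            class = "thickness_map")
}

as_volume_array <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stopf("expected a 3D array, got dimensions [%s]",
          paste(dim(x) %||% length(x), collapse = ", "))
  storage.mode(x) <- if (is.logical(x)) "logical" else "double"
  x
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive finite numbers (dx, dy, dz)")
  invisible(TRUE)
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<zstack> %d x %d x %d voxels, spacing (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<binary_volume> %d x %d x %d, %d foreground voxels (%.2f%%), connectivity %s\n",
              d[1], d[2], d[3], sum(x$occupancy),
              100 * mean(x$occupancy), x$connectivity))
  invisible(x)
}

#' @export
print.thickness_map <- function(x, ...) {
  fg <- x$diameters[x$diameters > 0]
  cat(sprintf("<thickness_map> %s voxels measured, diameter mean %.2f sd %.2f\n",
              format(length(fg), big.mark = ","),
              mean(fg), stats::sd(fg)))
  invisible(x)
}

## Shift a 3D array by (dx, dy, dz), filling vacated entries with `fill`.
## Used throughout for neighbourhood counting.
shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1] - abs(dx)); sy <- seq_len(d[2] - abs(dy)); sz <- seq_len(d[3] - abs(dz))
  dst <- list(sx + max(dx, 0), sy + max(dy, 0), sz + max(dz, 0))
  src <- list(sx + max(-dx, 0), sy + max(-dy, 0), sz + max(-dz, 0))
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## Pad a 3D logical array with `layers` of background on every face.
pad3 <- function(a, layers = 1L, value = FALSE) {
  d <- dim(a)
  out <- array(value, d + 2L * layers)
  out[layers + seq_len(d[1]), layers + seq_len(d[2]), layers + seq_len(d[3])] <- a
  out
}
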