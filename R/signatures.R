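## Dilation analysis: inflate the vessel set by thresholding its exact
## Euclidean distance transform, evaluate the four Minkowski functionals
## at each radius, and summarize each of the four signature curves by ten
## fixed features.

#' Exact Euclidean distance transform
#'
#' At each background voxel, the exact Euclidean distance (voxel units by
#' default; anisotropic spacing honoured through per-axis weights) to the
#' nearest foreground voxel centre; zero on the foreground.
#'
#' @param vol a [binary_volume()].
#' @param units `"voxel"` (x-y pixel units, the dilation-radius
#'   convention) or `"physical"` (micrometres).
#' @return 3D numeric array; all-`Inf` (with a warning) when the
#'   foreground is empty.
#' @export
edt <- function(vol, units = c("voxel", "physical")) {
  units <- match.arg(units)
  stopifnot(inherits(vol, "binary_volume"))
  if (!any(vol$occupancy)) warnf("empty foreground: distance field is infinite")
  sp <- if (units == "physical") vol$spacing else vol$spacing / vol$spacing[1]
  d <- dim(vol$occupancy)
  array(.edt3d_cpp(as.logical(vol$occupancy), as.integer(d), as.numeric(sp)), d)
}

#' Dilate a volume to a given radius of its distance field
#'
#' @param dist distance field from [edt()].
#' @param r dilation radius (same units as `dist`); `r = 0` returns the
#'   original set exactly.
#' @param spacing,connectivity carried into the result.
#' @return a [binary_volume()] with occupancy `dist <= r`.
#' @export
dilate_at <- function(dist, r, spacing = c(1, 1, 1), connectivity = "26-6") {
  stopifnot(is.array(dist), length(dim(dist)) == 3, r >= 0)
  binary_volume(array(dist <= r, dim(dist)), spacing = spacing,
                connectivity = connectivity)
}

#' Minkowski-functional dilation signatures
#'
#' Evaluates [minkowski_3d()] on dilated copies of the volume over a range
#' of radii (the EDT is computed once and thresholded per radius).
#'
#' @param vol a [binary_volume()].
#' @param radii ascending dilation radii in x-y voxel units, starting
#'   at 0.  The default covers `0 .. ceil(3 * mean vessel radius)` from
#'   the local-thickness statistics, capped at 25.
#' @param units_mode passed to [minkowski_3d()].
#' @return an object of class `mf_signature`: list with `radii` and
#'   `curves` (data frame with columns `vol`, `surf_area`, `mean_breadth`,
#'   `euler3D`, one row per radius).
#' @export
mf_signature <- function(vol, radii = NULL, units_mode = "voxel") {
  stopifnot(inherits(vol, "binary_volume"))
  if (is.null(radii)) radii <- default_radii(vol)
  radii <- as.numeric(radii)
  if (length(radii) < 1 || radii[1] != 0 || is.unsorted(radii, strictly = TRUE))
    stopf("radii must be strictly increasing and start at 0")
  dist <- edt(vol)
  rows <- lapply(radii, function(r) {
    v <- if (r == 0) vol else dilate_at(dist, r, vol$spacing, vol$connectivity)
    as.data.frame(minkowski_3d(v, units_mode))
  })
  structure(list(radii = radii, curves = do.call(rbind, rows)),
            class = "mf_signature")
}

default_radii <- function(vol) {
  r_mean <- tryCatch(thickness_stats(local_thickness(vol))$mean_diameter / 2,
                     error = function(e) 3)
  0:min(25L, max(2L, ceiling(3 * r_mean)))
}

#' @export
print.mf_signature <- function(x, ...) {
  cat(sprintf("<mf_signature> %d radii (0..%g)\n", length(x$radii), max(x$radii)))
  print(utils::head(cbind(radius = x$radii, x$curves), 4))
  if (length(x$radii) > 4) cat(sprintf("  ... %d more radii\n", length(x$radii) - 4))
  invisible(x)
}

#' @export
plot.mf_signature <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  labs <- c(vol = "Volume", surf_area = "Surface area",
            mean_breadth = "Mean breadth", euler3D = "Euler number")
  for (nm in names(labs)) {
    graphics::plot(x$radii, x$curves[[nm]], type = "b", pch = 16, cex = 0.6,
                   xlab = "dilation radius (voxels)", ylab = labs[[nm]], ...)
  }
  invisible(x)
}

#' @export
as.data.frame.mf_signature <- function(x, ...) {
  cbind(radius = x$radii, x$curves)
}

#' Normalize a collection of signatures for plotting
#'
#' Volume, surface-area and mean-breadth curves are divided by the global
#' maximum across the whole collection; Euler curves are affinely mapped
#' by the global (min, max) range to `[0, 1]`.
#'
#' @param sigs list of `mf_signature` objects (or a single one).
#' @return list of normalized `mf_signature`s with the scaling recorded in
#'   attribute `"scaling"` of the list.
#' @export
normalize_for_report <- function(sigs) {
  if (inherits(sigs, "mf_signature")) sigs <- list(sigs)
  stopifnot(length(sigs) >= 1, all(vapply(sigs, inherits, TRUE, "mf_signature")))
  scaling <- list()
  for (nm in c("vol", "surf_area", "mean_breadth")) {
    mx <- max(vapply(sigs, function(s) max(s$curves[[nm]]), 0))
    if (mx == 0) { warnf("zero range for %s: left unscaled", nm); mx <- 1 }
    scaling[[nm]] <- list(max = mx)
    sigs <- lapply(sigs, function(s) { s$curves[[nm]] <- s$curves[[nm]] / mx; s })
  }
  lo <- min(vapply(sigs, function(s) min(s$curves$euler3D), 0))
  hi <- max(vapply(sigs, function(s) max(s$curves$euler3D), 0))
  if (hi <= lo) { warnf("zero range for euler3D: left unscaled"); hi <- lo + 1 }
  scaling$euler3D <- list(min = lo, max = hi)
  sigs <- lapply(sigs, function(s) {
    s$curves$euler3D <- (s$curves$euler3D - lo) / (hi - lo); s
  })
  attr(sigs, "scaling") <- scaling
  sigs
}

# ---- the 40 features --------------------------------------------------------

.mf_prefixes <- c("vol", "surf_area", "mean_breadth", "euler3D")
.mf_feature_names <- c("var", "std", "mean", "median", "max", "maxScale",
                       "min", "minScale", "dmax", "dmaxScale")

#' Canonical names of the 40 signature features
#'
#' The cross product of the four functional prefixes (`vol`, `surf_area`,
#' `mean_breadth`, `euler3D`) and the ten per-curve summaries (`var`,
#' `std`, `mean`, `median`, `max`, `maxScale`, `min`, `minScale`, `dmax`,
#' `dmaxScale`), joined by underscores, e.g. `"surf_area_dmax"`.
#'
#' @return character vector of length 40.
#' @export
feature_names <- function() {
  as.vector(t(outer(.mf_prefixes, .mf_feature_names, paste, sep = "_")))
}

## Ten summaries of one curve y(r).  Population variance; derivative =
## forward difference assigned to the left abscissa; ties broken toward
## the smallest abscissa (which.max/min already do).
curve_features <- function(r, y) {
  stopifnot(length(r) == length(y), length(r) >= 2)
  v <- mean((y - mean(y))^2)
  dy <- diff(y) / diff(r)
  c(var = v, std = sqrt(v), mean = mean(y), median = stats::median(y),
    max = max(y), maxScale = r[which.max(y)],
    min = min(y), minScale = r[which.min(y)],
    dmax = max(dy), dmaxScale = r[which.max(dy)])
}

#' Extract the 40-feature summary of a dilation signature
#'
#' @param sig an `mf_signature` with at least 2 radii.
#' @return named numeric vector of length 40 (see [feature_names()]).
#' @export
extract_features <- function(sig) {
  stopifnot(inherits(sig, "mf_signature"))
  if (length(sig$radii) < 2)
    stopf("signature has a single radius: derivative features undefined")
  out <- lapply(.mf_prefixes, function(p)
    curve_features(sig$radii, sig$curves[[p]]))
  names(out) <- .mf_prefixes
  res <- unlist(lapply(.mf_prefixes, function(p) {
    v <- out[[p]]
    names(v) <- paste(p, .mf_feature_names, sep = "_")
    v
  }))
  res[feature_names()]
}

#' Average feature vectors across fields of view
#'
#' Per-sample features from several volumes of the same specimen are the
#' unweighted mean of the per-volume feature vectors (the functionals are
#' additive, so averages are well defined).
#'
#' @param feature_list list of length-40 named feature vectors.
#' @return one length-40 named feature vector.
#' @export
average_features <- function(feature_list) {
  stopifnot(length(feature_list) >= 1)
  m <- do.call(rbind, lapply(feature_list, function(f) f[feature_names()]))
  colMeans(m)
}
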