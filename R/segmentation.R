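## Adaptive structure filter: multi-scale Hessian vesselness segmentation.
##
## At each scale sigma (in physical units, converted per axis to voxels so
## anisotropic stacks are not z-smeared), the stack is Gaussian-smoothed,
## the sigma^2-normalized Hessian is formed by central finite differences,
## and its eigenvalues feed the Frangi bright-tube vesselness.  The
## adaptive filter takes, voxel-wise, the maximum of log(eps + vesselness)
## across scales; by default that tube score detects tubular support and
## the conditioned intensity inside it is what gets thresholded (a
## core-referenced half-maximum cut), so vessels are delineated at their
## imaged calibre.  Cleaning removes small connected components.

#' Parameters of the adaptive structure filter
#'
#' @param scales Gaussian sigmas (um) of the structural filters, one per
#'   vessel calibre probed, or `"auto"` to derive 5 log-spaced scales from
#'   0.5x to 2x the mean vessel radius estimated by a provisional
#'   single-scale pass plus local thickness.
#' @param alpha,beta Frangi plate/blob sensitivity constants.
#' @param gamma structureness constant; `NULL` (default) uses half the
#'   maximum Frobenius norm of the Hessian over the stack, per scale.
#' @param threshold_method `"core"` (default): a first-pass isodata mask
#'   is eroded to its core, the vessel level is read off as the median
#'   core score, and the final threshold is `core_fraction` of that
#'   level - a half-maximum-style calibre criterion with a fixed
#'   compensation for axial blur.  Alternatives: `"isodata"`
#'   (Ridler-Calvard midpoint of class means), `"otsu"` (maximum
#'   between-class variance), `"fixed"`.
#' @param fixed_threshold threshold in `[0, 1]` when `threshold_method`
#'   is `"fixed"`.
#' @param core_fraction fraction of the core vessel level used by the
#'   `"core"` method.  The half-maximum criterion (0.5) overestimates
#'   tube width when the axial PSF is comparable to the vessel radius;
#'   0.6 was calibrated once on rendered cylinders of known radius
#'   (volume consistency) and frozen.
#' @param min_cluster_voxels components smaller than this are removed.
#' @param intensity_outlier_percentiles intensities are clipped to this
#'   percentile range, then rescaled, before filtering (outlier
#'   elimination in voxel values).
#' @param combine `"gated_intensity"` (default): the thresholded tube
#'   score detects tubular support and the returned score is the
#'   conditioned intensity inside it, so thresholding recovers vessel
#'   calibre rather than the ridge of the tube score; `"vesselness"`
#'   returns the rescaled multi-scale tube score itself.
#' @param dark_vessels set `TRUE` to segment dark tubes on a bright
#'   background (the stack is inverted first).
#' @return a `filter_params` list.
#' @export
filter_params <- function(scales = "auto", alpha = 0.5, beta = 0.5,
                          gamma = NULL,
                          threshold_method = c("core", "isodata", "otsu", "fixed"),
                          fixed_threshold = NULL, core_fraction = 0.6,
                          min_cluster_voxels = 64,
                          intensity_outlier_percentiles = c(0.5, 99.9),
                          combine = c("gated_intensity", "vesselness"),
                          dark_vessels = FALSE) {
  threshold_method <- match.arg(threshold_method)
  combine <- match.arg(combine)
  if (!identical(scales, "auto")) {
    stopifnot(length(scales) >= 1, all(scales > 0))
  }
  stopifnot(alpha > 0, beta > 0, is.null(gamma) || gamma > 0,
            min_cluster_voxels >= 1,
            length(intensity_outlier_percentiles) == 2)
  structure(list(scales = scales, alpha = alpha, beta = beta, gamma = gamma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 core_fraction = core_fraction,
                 min_cluster_voxels = min_cluster_voxels,
                 intensity_outlier_percentiles = intensity_outlier_percentiles,
                 combine = combine, dark_vessels = dark_vessels),
            class = "filter_params")
}

#' Eigenvalues of the scale-normalized Hessian
#'
#' Smooths the stack with an anisotropy-corrected Gaussian (`sigma` in
#' physical units, divided per axis by the voxel spacing), forms the
#' Hessian by central finite differences on the voxel lattice scaled to
#' physical units, multiplies by `sigma^2` (scale normalization), and
#' returns its eigenvalue fields ordered by increasing magnitude.
#'
#' @param stack a [zstack()].
#' @param sigma scale (um).
#' @return list of three 3D arrays `lambda1`, `lambda2`, `lambda3` with
#'   `|lambda1| <= |lambda2| <= |lambda3|` voxel-wise.
#' @export
hessian_eigenvalues <- function(stack, sigma) {
  stopifnot(inherits(stack, "zstack"), sigma > 0)
  sp <- stack$spacing
  if (sigma < max(sp) / 2)
    warnf("scale sigma = %g um is under-resolved for voxel spacing (%g, %g, %g)",
          sigma, sp[1], sp[2], sp[3])
  s_vox <- sigma / sp
  img <- gauss_smooth3(stack$voxels, s_vox)
  # central differences with replicated edges (no spurious border response)
  shifte <- function(a, ax, o) {
    d <- dim(a)
    idx <- lapply(seq_along(d), function(i) {
      s <- seq_len(d[i])
      if (i == ax) pmin(d[i], pmax(1L, s + o)) else s
    })
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  d1 <- function(a, ax) (shifte(a, ax, 1L) - shifte(a, ax, -1L)) / (2 * sp[ax])
  d2 <- function(a, ax) (shifte(a, ax, 1L) - 2 * a + shifte(a, ax, -1L)) / sp[ax]^2
  hxx <- d2(img, 1); hyy <- d2(img, 2); hzz <- d2(img, 3)
  gx <- d1(img, 1)
  hxy <- d1(gx, 2); hxz <- d1(gx, 3)
  hyz <- d1(d1(img, 2), 3)
  n <- sigma^2
  eig <- sym_eigen3(n * hxx, n * hyy, n * hzz, n * hxy, n * hxz, n * hyz)
  order_by_magnitude(eig)
}

## Closed-form eigenvalues of voxel-wise symmetric 3x3 matrices
## (trigonometric method), vectorized over arrays.  Returns algebraically
## sorted fields e1 <= e2 <= e3.
sym_eigen3 <- function(axx, ayy, azz, axy, axz, ayz) {
  q <- (axx + ayy + azz) / 3
  dxx <- axx - q; dyy <- ayy - q; dzz <- azz - q
  p2 <- dxx^2 + dyy^2 + dzz^2 + 2 * (axy^2 + axz^2 + ayz^2)
  p <- sqrt(p2 / 6)
  # det of (A - q I) / p, guarded where p ~ 0 (isotropic point: all eig = q)
  safe_p <- ifelse(p > 0, p, 1)
  b_xx <- dxx / safe_p; b_yy <- dyy / safe_p; b_zz <- dzz / safe_p
  b_xy <- axy / safe_p; b_xz <- axz / safe_p; b_yz <- ayz / safe_p
  detb <- b_xx * (b_yy * b_zz - b_yz^2) - b_xy * (b_xy * b_zz - b_yz * b_xz) +
          b_xz * (b_xy * b_yz - b_yy * b_xz)
  r <- pmin(1, pmax(-1, detb / 2))
  phi <- acos(r) / 3
  e3 <- q + 2 * p * cos(phi)
  e1 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  zero <- p2 <= 0
  if (any(zero)) { e1[zero] <- q[zero]; e2[zero] <- q[zero]; e3[zero] <- q[zero] }
  list(e1 = e1, e2 = e2, e3 = e3)
}

## Reorder algebraically sorted eigenvalue fields by |.|.
order_by_magnitude <- function(eig) {
  a1 <- abs(eig$e1); a2 <- abs(eig$e2); a3 <- abs(eig$e3)
  # lambda1: smallest magnitude; lambda3: largest; lambda2: the remainder
  l1 <- ifelse(a1 <= a2 & a1 <= a3, eig$e1, ifelse(a2 <= a3, eig$e2, eig$e3))
  l3 <- ifelse(a3 >= a2 & a3 >= a1, eig$e3, ifelse(a2 >= a1, eig$e2, eig$e1))
  l2 <- eig$e1 + eig$e2 + eig$e3 - l1 - l3
  list(lambda1 = l1, lambda2 = l2, lambda3 = l3)
}

#' Frangi bright-tube vesselness from Hessian eigenvalues
#'
#' \deqn{V = (1 - e^{-R_A^2 / 2\alpha^2}) e^{-R_B^2 / 2\beta^2}
#'           (1 - e^{-S^2 / 2\gamma^2})}
#' with \eqn{R_A = |\lambda_2|/|\lambda_3|},
#' \eqn{R_B = |\lambda_1|/\sqrt{|\lambda_2 \lambda_3|}},
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2 + \lambda_3^2}}, and
#' \eqn{V = 0} wherever \eqn{\lambda_2 > 0} or \eqn{\lambda_3 > 0}
#' (bright tubes have two large negative curvatures).
#'
#' @param eigs eigenvalue fields from [hessian_eigenvalues()].
#' @param alpha,beta sensitivity constants.
#' @param gamma structureness constant; `NULL` uses half the maximum of
#'   `S` over the stack.
#' @return 3D score array in `[0, 1]`.
#' @export
vesselness <- function(eigs, alpha = 0.5, beta = 0.5, gamma = NULL) {
  l1 <- eigs$lambda1; l2 <- eigs$lambda2; l3 <- eigs$lambda3
  s <- sqrt(l1^2 + l2^2 + l3^2)
  if (is.null(gamma)) gamma <- max(s) / 2
  if (gamma <= 0) gamma <- 1  # flat stack: scores all zero anyway
  a3 <- abs(l3)
  safe3 <- ifelse(a3 > 0, a3, 1)
  ra <- abs(l2) / safe3
  rb2 <- l1^2 / ifelse(a3 > 0, abs(l2 * l3), 1)
  v <- (1 - exp(-ra^2 / (2 * alpha^2))) *
       exp(-rb2 / (2 * beta^2)) *
       (1 - exp(-s^2 / (2 * gamma^2)))
  v[l2 > 0 | l3 > 0 | a3 == 0] <- 0
  v
}

#' Adaptive structure filter: combined multi-scale tube score
#'
#' Runs [vesselness()] at every scale and takes, at each voxel, the
#' maximum of `log(eps + V)` across scales (`eps = 1e-6`), rescaled to
#' `[0, 1]`.  With the default `combine = "gated_intensity"` the filter
#' works in two stages: the thresholded tube score *detects* tubular
#' support (Otsu's threshold on the non-zero tube scores, expanded by the
#' largest probed calibre so the full vessel cross-section is covered),
#' and the returned score is the percentile-clipped, rescaled intensity
#' inside that support (zero outside).  Thresholding the result therefore
#' *delineates* vessels at their imaged calibre while non-tubular
#' structure stays suppressed.  `combine = "vesselness"` returns the
#' rescaled tube score itself.
#'
#' @param stack a [zstack()].
#' @param params a [filter_params()]; `params$scales` must hold at least
#'   2 numeric scales (use [segment_stack()] for automatic scales).
#' @return 3D score array in `[0, 1]`.
#' @export
adaptive_filter <- function(stack, params = filter_params(scales = c(1, 2))) {
  stopifnot(inherits(stack, "zstack"), inherits(params, "filter_params"))
  scales <- params$scales
  if (identical(scales, "auto"))
    stopf("adaptive_filter needs numeric scales; use segment_stack() for scales = 'auto'")
  if (length(scales) < 2)
    warnf("single-scale filter: the adaptive maximum reduces to plain vesselness")
  stack <- prepare_stack(stack, params)
  eps <- 1e-6
  combined <- NULL
  for (s in scales) {
    v <- vesselness(hessian_eigenvalues(stack, s),
                    params$alpha, params$beta, params$gamma)
    lv <- log(eps + v)
    combined <- if (is.null(combined)) lv else pmax(combined, lv)
  }
  lo <- log(eps); hi <- max(combined)
  if (hi <= lo) return(array(0, dim(stack$voxels)))
  gate <- (combined - lo) / (hi - lo)
  if (identical(params$combine, "vesselness")) return(gate)
  # detection: strong tubular support, expanded to cover the full calibre
  nz <- gate[gate > 0]
  gcut <- if (diff(range(nz)) <= 0) nz[1] / 2 else otsu_threshold(nz)
  support <- gate > gcut
  if (any(support)) {
    reach <- 2 + max(scales) / (2 * min(stack$spacing))
    d <- edt(binary_volume(support, spacing = stack$spacing))
    support <- d <= reach
  }
  # delineation: conditioned intensity inside the support, smoothed by a
  # small matched filter when the stack is measurably noisy
  img <- stack$voxels
  sm <- gauss_smooth3(img, rep(1, 3))
  noise <- stats::mad(img - sm)
  if (noise > 0.02) img <- sm
  img[!support] <- 0
  img
}

## Intensity conditioning: optional inversion, percentile clipping
## (outlier elimination in voxel values) and rescaling to [0, 1].
prepare_stack <- function(stack, params) {
  v <- stack$voxels
  if (isTRUE(params$dark_vessels)) v <- max(v) - v
  pr <- stats::quantile(v, params$intensity_outlier_percentiles / 100,
                        names = FALSE)
  if (pr[2] > pr[1]) {
    v[v < pr[1]] <- pr[1]
    v[v > pr[2]] <- pr[2]
    v <- (v - pr[1]) / (pr[2] - pr[1])
  }
  zstack(v, stack$spacing, stack$meta)
}

#' Otsu's threshold
#'
#' Maximizes between-class variance over a histogram of the values.
#'
#' @param x numeric vector.
#' @param nbins histogram resolution.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) <= 0)
    stopf("degenerate (all-equal) score field: use a fixed threshold")
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nbins]; mt <- m[nbins]
  w0 <- w[-nbins]; m0 <- m[-nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1)
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 / (w0[valid] * w1[valid])
  # the criterion plateaus across an empty inter-class gap: take the
  # midpoint of the maximizing interval
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  mean(mids[range(top)])
}

#' Isodata (Ridler-Calvard) threshold
#'
#' Iterates `t <- (mean(x[x <= t]) + mean(x[x > t])) / 2` to convergence:
#' the threshold ends midway between the two class means, i.e. at the
#' half-level between background and foreground intensity.
#'
#' @param x numeric vector.
#' @return threshold value.
#' @export
isodata_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0)
    stopf("degenerate (all-equal) score field: use a fixed threshold")
  t <- mean(x)
  for (i in 1:100) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-8) { t <- t_new; break }
    t <- t_new
  }
  t
}

## Core-referenced fractional threshold: erode the first-pass isodata
## mask by 2 voxels, take the median score of the remaining core as the
## vessel level, and cut at `fraction` of it.
core_threshold <- function(score, nz, fraction) {
  thr0 <- isodata_threshold(nz)
  m0 <- score > thr0
  depth <- edt(binary_volume(array(!m0, dim(score))))
  core <- m0 & depth >= 2
  if (!any(core)) return(thr0)
  fraction * stats::median(score[core])
}

#' Binarise a score field
#'
#' Thresholds the non-zero scores (zeros are the filter's rejected
#' voxels, not evidence): isodata by default, Otsu, or a fixed value.
#' The threshold used is recorded in the result's `meta`.
#'
#' @param score 3D array of scores in `[0, 1]`.
#' @param params a [filter_params()].
#' @param spacing voxel spacing carried into the result.
#' @return a [binary_volume()].
#' @export
binarise <- function(score, params = filter_params(), spacing = c(1, 1, 1)) {
  stopifnot(is.array(score), length(dim(score)) == 3)
  if (min(score) < 0 || max(score) > 1)
    stopf("scores must lie in [0, 1]")
  if (identical(params$threshold_method, "fixed")) {
    thr <- params$fixed_threshold %||% stopf("fixed_threshold not set")
  } else {
    nz <- score[score > 0]
    if (length(nz) == 0) stopf("degenerate (all-zero) score field: use a fixed threshold")
    thr <- if (diff(range(nz)) <= 0) nz[1] / 2
           else if (identical(params$threshold_method, "otsu")) otsu_threshold(nz)
           else if (identical(params$threshold_method, "isodata")) isodata_threshold(nz)
           else core_threshold(score, nz, params$core_fraction %||% 0.6)
  }
  binary_volume(array(score > thr, dim(score)), spacing = spacing,
                meta = list(threshold = thr, threshold_method = params$threshold_method))
}

#' Remove small connected components
#'
#' Labels foreground components with the volume's declared foreground
#' connectivity and drops those below `params$min_cluster_voxels`.
#'
#' @param vol a [binary_volume()].
#' @param params a [filter_params()].
#' @return a [binary_volume()]; empty output is allowed (with a warning).
#' @export
clean <- function(vol, params = filter_params()) {
  stopifnot(inherits(vol, "binary_volume"))
  fg_conn <- if (identical(vol$connectivity, "26-6")) 26 else 6
  lab <- label_components(vol$occupancy, fg_conn)
  keep <- which(lab$sizes >= params$min_cluster_voxels)
  occ <- array(lab$labels %in% keep & lab$labels > 0, dim(vol$occupancy))
  if (!any(occ)) warnf("cleaning removed every component")
  out <- vol
  out$occupancy <- occ
  out$meta$removed_components <- length(lab$sizes) - length(keep)
  out$meta$kept_components <- length(keep)
  out
}

#' Segment a z-stack into a binary vessel model
#'
#' The full adaptive-structure-filter chain: optional automatic scale
#' selection (a provisional single-scale pass whose local thickness sets
#' the calibre range), [adaptive_filter()], [binarise()], [clean()].
#' Deterministic: the same stack and parameters give a bit-identical mask.
#'
#' @param stack a [zstack()].
#' @param params a [filter_params()].
#' @return a [binary_volume()] with the chosen scales and threshold in
#'   its `meta`.
#' @export
segment_stack <- function(stack, params = filter_params()) {
  stopifnot(inherits(stack, "zstack"))
  scales <- params$scales
  if (identical(scales, "auto")) scales <- auto_scales(stack, params)
  p2 <- params
  p2$scales <- scales
  score <- vm_stage("adaptive_filter", adaptive_filter(stack, p2))
  vol <- binarise(score, p2, spacing = stack$spacing)
  vol <- clean(vol, p2)
  vol$meta$scales <- scales
  vol$meta$params <- unclass(p2)
  vol
}

## Scale bootstrap: provisional single-scale segmentation -> local
## thickness -> 5 log-spaced sigmas covering 0.5x..2x the mean radius.
auto_scales <- function(stack, params) {
  sp <- stack$spacing
  sigma0 <- 1.5 * min(sp[1:2])
  p0 <- params
  p0$scales <- c(sigma0, 2 * sigma0)
  p0$min_cluster_voxels <- max(8, params$min_cluster_voxels %/% 4)
  prov <- tryCatch({
    sc <- adaptive_filter(stack, p0)
    clean(binarise(sc, p0, spacing = sp), p0)
  }, error = function(e) NULL)
  if (is.null(prov) || !any(prov$occupancy)) {
    vm_log("auto scales: provisional segmentation empty, using fallback")
    return(sigma0 * c(0.5, 0.84, 1.41, 2.38, 4))
  }
  th <- thickness_stats(local_thickness(prov))
  r_mean <- max(th$mean_diameter / 2, min(sp))
  exp(seq(log(0.5 * r_mean), log(2 * r_mean), length.out = 5))
}

#' Dice overlap of two binary volumes
#'
#' @param a,b [binary_volume()]s on the same grid.
#' @return `2|A & B| / (|A| + |B|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_volume"), inherits(b, "binary_volume"),
            identical(dim(a$occupancy), dim(b$occupancy)))
  na <- sum(a$occupancy); nb <- sum(b$occupancy)
  if (na + nb == 0) return(1)
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}
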