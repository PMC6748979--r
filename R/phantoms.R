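## Synthetic tubular phantoms with known geometry and topology.
##
## Geometry lives in voxel-centre coordinates: voxel (i, j, k) sits at the
## integer point (i, j, k), 1-based.  Networks are built so that their
## component and independent-cycle counts are guaranteed by construction:
## loops are bridge arcs welded onto a backbone tube at two contiguous
## overlap regions, and intended-disjoint structures keep a clearance of
## at least 2 * max radius + 3 voxels, so the ground-truth topology is
## independent of the digital connectivity convention.

#' Rasterize a tube around a polyline centreline
#'
#' Sets every voxel whose centre lies within `radius` of the polyline.
#'
#' @param centreline numeric matrix (n x 3) of 3D points in voxel
#'   coordinates (voxel centres at integers, 1-based).
#' @param radius tube radius in voxels.
#' @param grid_shape integer length-3 `(nx, ny, nz)`.
#' @param spacing passed to [binary_volume()].
#' @return a [binary_volume()].
#' @export
make_tube <- function(centreline, radius, grid_shape, spacing = c(1, 1, 1)) {
  centreline <- rbind(centreline)
  stopifnot(ncol(centreline) == 3, radius > 0)
  lo <- apply(centreline, 2, min) - radius
  hi <- apply(centreline, 2, max) + radius
  if (any(lo < 0.5) || any(hi > grid_shape + 0.5))
    stopf("tube exits the grid: extent [%s]-[%s] vs shape (%s)",
          paste(round(lo, 1), collapse = ","), paste(round(hi, 1), collapse = ","),
          paste(grid_shape, collapse = ","))
  occ <- array(FALSE, grid_shape)
  rasterize_tube(occ, centreline, radius)
}

## Paint a tube into an existing occupancy array (no bounds check).
rasterize_tube <- function(occ, centreline, radius) {
  grid_shape <- dim(occ)
  nseg <- max(1L, nrow(centreline) - 1L)
  for (s in seq_len(nseg)) {
    a <- centreline[s, ]
    b <- centreline[min(s + 1L, nrow(centreline)), ]
    lo <- pmax(1L, floor(pmin(a, b) - radius))
    hi <- pmin(grid_shape, ceiling(pmax(a, b) + radius))
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    px <- rep(xs, times = length(ys) * length(zs))
    py <- rep(rep(ys, each = length(xs)), times = length(zs))
    pz <- rep(zs, each = length(xs) * length(ys))
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-12) {
      d2 <- (px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2
    } else {
      t <- pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] +
                            (pz - a[3]) * ab[3]) / len2))
      d2 <- (px - a[1] - t * ab[1])^2 + (py - a[2] - t * ab[2])^2 +
            (pz - a[3] - t * ab[3])^2
    }
    inside <- d2 <= radius^2
    if (any(inside)) {
      sub <- occ[xs, ys, zs, drop = FALSE]
      sub[inside] <- TRUE
      occ[xs, ys, zs] <- sub
    }
  }
  if (!is.logical(occ)) storage.mode(occ) <- "logical"
  binary_volume(occ)
}

#' Digitized solid ball
#' @param radius ball radius (voxels).
#' @param grid_shape grid dimensions; defaults to a snug grid.
#' @param center ball centre (voxel coordinates); defaults to the grid centre.
#' @return a [binary_volume()].
#' @export
make_ball <- function(radius, grid_shape = rep(2 * ceiling(radius) + 5, 3),
                      center = (grid_shape + 1) / 2) {
  g <- coord_grids(grid_shape)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  binary_volume(array(d2 <= radius^2, grid_shape))
}

#' Digitized solid torus (one tunnel)
#' @param major_R distance from torus centre to tube centreline (voxels).
#' @param minor_r tube radius (voxels), `major_R > minor_r >= 1`.
#' @param grid_shape grid dimensions; defaults to a snug grid.
#' @param center torus centre.
#' @return a [binary_volume()]; the tube circles the z axis through `center`.
#' @export
make_torus <- function(major_R, minor_r,
                       grid_shape = c(rep(2 * ceiling(major_R + minor_r) + 5, 2),
                                      2 * ceiling(minor_r) + 5),
                       center = (grid_shape + 1) / 2) {
  stopifnot(major_R > minor_r, minor_r >= 1)
  if (major_R + minor_r > min((grid_shape[1:2] - 1) / 2) ||
      minor_r > (grid_shape[3] - 1) / 2)
    stopf("torus does not fit in the grid")
  g <- coord_grids(grid_shape)
  rho <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  d2 <- (rho - major_R)^2 + (g$z - center[3])^2
  binary_volume(array(d2 <= minor_r^2, grid_shape))
}

#' Hollow spherical shell (one enclosed cavity)
#' @param outer,inner outer and inner shell radii (voxels), `outer > inner >= 1`.
#' @param grid_shape grid dimensions; defaults to a snug grid.
#' @param center shell centre.
#' @return a [binary_volume()].
#' @export
make_shell <- function(outer, inner, grid_shape = rep(2 * ceiling(outer) + 5, 3),
                       center = (grid_shape + 1) / 2) {
  stopifnot(outer > inner, inner >= 1)
  g <- coord_grids(grid_shape)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  binary_volume(array(d2 <= outer^2 & d2 > inner^2, grid_shape))
}

coord_grids <- function(grid_shape) {
  list(x = array(rep(seq_len(grid_shape[1]), times = prod(grid_shape[2:3])), grid_shape),
       y = array(rep(rep(seq_len(grid_shape[2]), each = grid_shape[1]),
                     times = grid_shape[3]), grid_shape),
       z = array(rep(seq_len(grid_shape[3]), each = prod(grid_shape[1:2])), grid_shape))
}

#' Specification of a synthetic tubular network
#'
#' @param n_components number of disjoint sub-networks (>= 1).
#' @param n_loops total number of independent cycles, distributed
#'   round-robin over components.
#' @param radius_mean,radius_sd tube radius distribution (voxels); draws are
#'   truncated at 1.
#' @param tortuosity amplitude (voxels) of the sinusoidal in-plane
#'   perturbation of each backbone centreline.
#' @param grid_shape grid dimensions `(nx, ny, nz)`.
#' @param seed integer; fixes all randomness.
#' @return a `network_spec` list.
#' @export
network_spec <- function(n_components = 1, n_loops = 0, radius_mean = 3,
                         radius_sd = 0, tortuosity = 2,
                         grid_shape = c(64, 64, 32), seed = 1) {
  stopifnot(n_components >= 1, n_loops >= 0, radius_mean >= 1, radius_sd >= 0,
            tortuosity >= 0, length(grid_shape) == 3)
  structure(list(n_components = as.integer(n_components),
                 n_loops = as.integer(n_loops),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 tortuosity = tortuosity,
                 grid_shape = as.integer(grid_shape),
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate a tubular network with known topology
#'
#' Builds `n_components` disjoint tortuous backbone tubes (sinusoidal
#' lateral wiggle in y) and welds half-sine bridge arcs onto them, one arc
#' per requested loop.  Each arc follows the backbone's lateral wiggle and
#' lifts away from it in z by `2 * radius + 3` voxels at its apex, so it
#' contacts the backbone in exactly two contiguous weld regions and
#' contributes exactly one independent cycle.  The network therefore has
#' the requested component and loop counts (Euler number
#' `components - loops`) by construction; the measured topology is verified
#' before returning.
#'
#' @param spec a [network_spec()].
#' @return list with `volume` (a [binary_volume()]) and `truth`: a list with
#'   `components`, `loops`, `euler`, per-component `centrelines`, arc
#'   anchors and `radii`.
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  gs <- spec$grid_shape
  k <- spec$n_components
  margin <- 2
  r_max <- max(1, spec$radius_mean + 2 * spec$radius_sd)
  arc_half <- max(2 * r_max, 6)        # half-span of a bridge arc in x
  lift <- 2 * r_max + 3                # apex height of a bridge arc in z
  # loops per component, round-robin
  loops <- rep(spec$n_loops %/% k, k)
  extra <- spec$n_loops %% k
  if (extra > 0) loops[seq_len(extra)] <- loops[seq_len(extra)] + 1L

  # lateral (y) slabs per component with clearance
  slab <- gs[2] / k
  envelope <- spec$tortuosity + r_max
  if (slab < 2 * envelope + (if (k > 1) 2 * r_max + 3 else 0))
    stopf("cannot place %d components without contact; use a larger grid", k)
  if (any(loops > 0) && (gs[3] + 1) / 2 + lift + r_max + 1 > gs[3])
    stopf("bridge arcs (lift %.1f) do not fit in %d z-planes; use a larger grid",
          lift, gs[3])

  for (attempt in 1:3) {
    rs <- split_seed(spec$seed, "network", attempt)
    occ <- array(FALSE, gs)
    truth <- list(components = k, loops = spec$n_loops,
                  euler = k - spec$n_loops,
                  centrelines = vector("list", k),
                  arcs = vector("list", k), radii = numeric(k))
    for (c_i in seq_len(k)) {
      set.seed(split_seed(rs, "component", c_i))
      r_t <- max(1, spec$radius_mean + spec$radius_sd * stats::rnorm(1))
      y_c <- (c_i - 0.5) * slab + 0.5
      z_c <- (gs[3] + 1) / 2
      x0 <- margin + r_t + 1; x1 <- gs[1] - margin - r_t
      if (x1 - x0 < 8) stopf("grid too small in x for a backbone tube")
      freq <- stats::runif(1, 1, 2); phase <- stats::runif(1, 0, 2 * pi)
      y_of <- function(x) y_c + spec$tortuosity *
        sin(2 * pi * freq * (x - x0) / (x1 - x0) + phase)
      xs <- seq(x0, x1, by = 1)
      backbone <- cbind(xs, y_of(xs), rep(z_c, length(xs)))
      occ <- rasterize_tube(occ, backbone, r_t)$occupancy
      truth$centrelines[[c_i]] <- backbone
      truth$radii[c_i] <- r_t
      # bridge arcs: anchor intervals pairwise disjoint along the backbone
      L <- loops[c_i]
      if (L > 0) {
        a <- arc_half
        if (x1 - x0 < 2 * a + (L - 1) * (2 * a + 2 * r_t + 3))
          stopf("cannot fit %d loops on one backbone; use a larger grid or more components", L)
        ax <- if (L == 1) (x0 + x1) / 2 else seq(x0 + a, x1 - a, length.out = L)
        arcs <- matrix(0, L, 3)
        for (l in seq_len(L)) {
          sgn <- if (l %% 2 == 1) 1 else -1
          h <- 2 * r_t + 3
          xa <- seq(ax[l] - a, ax[l] + a, by = 0.75)
          u <- (xa - (ax[l] - a)) / (2 * a)
          arc <- cbind(xa, y_of(xa), z_c + sgn * h * sin(pi * u))
          occ <- rasterize_tube(occ, arc, r_t)$occupancy
          arcs[l, ] <- c(ax[l] - a, ax[l] + a, sgn)
        }
        truth$arcs[[c_i]] <- arcs
      }
    }
    vol <- binary_volume(occ)
    meas <- measure_topology(vol)
    if (meas$b0 == k && meas$b1 == spec$n_loops && meas$b2 == 0)
      return(list(volume = vol, truth = truth))
  }
  stopf("network generation produced unintended contacts after 3 attempts; use a larger grid")
}

## Topology at any grid size: b0 (26-conn foreground), b2 (enclosed 6-conn
## background), b1 from the cell-complex Euler characteristic.
measure_topology <- function(vol) {
  occ <- vol$occupancy
  b0 <- length(label_components(occ, 26)$sizes)
  pbg <- !pad3(occ)
  lab <- label_components(pbg, 6)
  border <- unique(c(lab$labels[1, , ], lab$labels[dim(pbg)[1], , ],
                     lab$labels[, 1, ], lab$labels[, dim(pbg)[2], ],
                     lab$labels[, , 1], lab$labels[, , dim(pbg)[3]]))
  b2 <- length(setdiff(seq_along(lab$sizes), border[border > 0]))
  chi <- chi_cell_complex(occ)
  list(b0 = b0, b1 = b0 + b2 - chi, b2 = b2, chi = chi)
}

# ---- synthetic cohorts ------------------------------------------------------

#' Age-effect model for synthetic cohorts
#'
#' Maps an age (years) to network parameters.  The default emulates the
#' qualitative ageing findings the statistics layer should recover: loop
#' density and tortuosity flat until an inflection age, then rising.
#'
#' @param inflection age (years) at which loop density starts rising.
#' @param loop_base,loop_gain loops at/below the inflection and the number
#'   of additional loops gained over the following 30 years (the ramp
#'   saturates 30 years past the inflection).
#' @param tort_base,tort_gain same for the tortuosity amplitude (voxels).
#' @param radius_mean constant mean tube radius (voxels).
#' @return a function `age -> named list` of [network_spec()] overrides.
#' @export
age_effect_model <- function(inflection = 55, loop_base = 1, loop_gain = 2.5,
                             tort_base = 1.5, tort_gain = 1.5,
                             radius_mean = 3) {
  force(inflection)
  function(age) {
    late <- min(1, max(0, age - inflection) / 30)
    list(n_loops = loop_base + round(loop_gain * late),
         tortuosity = tort_base + tort_gain * late,
         radius_mean = radius_mean)
  }
}

#' Null (age-independent) effect model
#' @param ... fixed [network_spec()] overrides applied at every age.
#' @return a function `age -> named list`.
#' @export
constant_effect_model <- function(...) {
  fixed <- list(...)
  function(age) fixed
}

#' Generate a synthetic cohort of vessel networks
#'
#' Draws ages uniformly over `age_range`, maps each age through
#' `effect_model` to network parameters, and generates one network per
#' sample (optionally rendered to a noisy z-stack).  Fully reproducible:
#' per-sample seeds are split off `seed`, so the cohort is independent of
#' generation order.
#'
#' @param n_samples number of samples.
#' @param age_range ages (years) drawn uniformly over this interval.
#' @param effect_model function `age -> named list` of [network_spec()]
#'   overrides, e.g. [age_effect_model()].
#' @param seed integer master seed.
#' @param grid_shape grid for every sample.
#' @param render optional [render_spec()]; when given, `volumes` holds
#'   [zstack()]s instead of ground-truth [binary_volume()]s.
#' @param n_components components per network.
#' @return list with `volumes`, `ages`, and `truths` (per-sample ground
#'   truth from [make_network()]).
#' @export
make_cohort <- function(n_samples, age_range = c(9, 84),
                        effect_model = age_effect_model(), seed = 1,
                        grid_shape = c(96, 64, 32), render = NULL,
                        n_components = 2) {
  stopifnot(n_samples >= 1, length(age_range) == 2)
  set.seed(split_seed(seed, "cohort-ages"))
  ages <- sort(stats::runif(n_samples, age_range[1], age_range[2]))
  volumes <- vector("list", n_samples)
  truths <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    ov <- effect_model(ages[i])
    args <- list(n_components = n_components, grid_shape = grid_shape,
                 seed = split_seed(seed, "cohort-sample", i))
    args[names(ov)] <- ov
    net <- make_network(do.call(network_spec, args))
    truths[[i]] <- c(net$truth, list(age = ages[i]))
    if (is.null(render)) {
      volumes[[i]] <- net$volume
    } else {
      rs <- render
      rs$seed <- split_seed(seed, "cohort-render", i)
      volumes[[i]] <- render_zstack(net$volume, rs)
    }
  }
  list(volumes = volumes, ages = ages, truths = truths)
}
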