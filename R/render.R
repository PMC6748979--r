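## Confocal-style rendering of binary phantoms: anisotropic PSF blur,
## background autofluorescence (constant plus a linear gradient, which in
## aged tissue is the dominant nuisance), additive Gaussian noise and
## impulse ("speckle") noise.

#' Rendering specification for synthetic z-stacks
#'
#' @param psf_sigma Gaussian point-spread sigmas `(sx, sy, sz)` in voxels;
#'   `c(0, 0, 0)` disables blur.  The default widens along z, mimicking the
#'   elongated confocal PSF with 1 um optical sections.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; the rendered vessel signal is `signal_level`).
#' @param speckle_rate fraction of voxels replaced by bright impulses.
#' @param background_level constant background level; a linear gradient of
#'   the same amplitude is added along x (autofluorescence is rarely flat).
#' @param signal_level vessel intensity before degradation.
#' @param seed integer seed; the same spec renders bit-identically.
#' @return a `render_spec` list.
#' @export
render_spec <- function(psf_sigma = c(1, 1, 2), noise_sd = 0.2,
                        speckle_rate = 5e-4, background_level = 0.05,
                        signal_level = 1, seed = 1) {
  stopifnot(length(psf_sigma) == 3, all(psf_sigma >= 0), noise_sd >= 0,
            speckle_rate >= 0, background_level >= 0, signal_level > 0)
  structure(list(psf_sigma = psf_sigma, noise_sd = noise_sd,
                 speckle_rate = speckle_rate,
                 background_level = background_level,
                 signal_level = signal_level, seed = as.integer(seed)),
            class = "render_spec")
}

#' Render a binary volume as a noisy confocal-like z-stack
#'
#' Intensity model: `blur(foreground * signal_level) + background + noise`,
#' clipped at zero.  Deterministic given the spec's seed.
#'
#' @param vol a [binary_volume()] ground-truth vessel model.
#' @param spec a [render_spec()].
#' @return a [zstack()] carrying the render parameters in its `meta`.
#' @export
render_zstack <- function(vol, spec = render_spec()) {
  stopifnot(inherits(vol, "binary_volume"), inherits(spec, "render_spec"))
  d <- dim(vol$occupancy)
  img <- array(as.numeric(vol$occupancy) * spec$signal_level, d)
  if (any(spec$psf_sigma > 0)) img <- gauss_smooth3(img, spec$psf_sigma)
  if (spec$background_level > 0) {
    grad <- array(rep(seq(0, 1, length.out = d[1]), times = prod(d[2:3])), d)
    img <- img + spec$background_level * (1 + grad)
  }
  set.seed(split_seed(spec$seed, "render-noise"))
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
  if (spec$speckle_rate > 0) {
    n_sp <- round(spec$speckle_rate * prod(d))
    if (n_sp > 0) {
      at <- sample.int(prod(d), n_sp)
      img[at] <- spec$signal_level * stats::runif(n_sp, 1, 2)
    }
  }
  img[img < 0] <- 0
  zstack(img, spacing = vol$spacing,
         meta = list(render = unclass(spec), truth_foreground = sum(vol$occupancy)))
}

#' The standard validation phantom
#'
#' A fixed two-component, three-loop tortuous network used throughout the
#' package's validation: returned both as ground truth and as rendered
#' stacks (a clean identity rendering and a degraded one at a given
#' signal-to-noise ratio with PSF `(1, 1, 2)` voxels).
#'
#' @param seed integer seed.
#' @param snr signal-to-noise ratio `signal_level / noise_sd` of the
#'   degraded rendering.
#' @return list with `truth` ([binary_volume()]), `clean` and `noisy`
#'   ([zstack()]s), and the generating specs.
#' @export
standard_phantom <- function(seed = 1, snr = 5) {
  nspec <- network_spec(n_components = 2, n_loops = 3, radius_mean = 3,
                        radius_sd = 0, tortuosity = 2,
                        grid_shape = c(96, 64, 32), seed = split_seed(seed, "net"))
  net <- make_network(nspec)
  clean <- render_zstack(net$volume,
                         render_spec(psf_sigma = c(0, 0, 0), noise_sd = 0,
                                     speckle_rate = 0, background_level = 0,
                                     seed = split_seed(seed, "clean")))
  noisy_spec <- render_spec(psf_sigma = c(1, 1, 2), noise_sd = 1 / snr,
                            speckle_rate = 5e-4, background_level = 0.05,
                            signal_level = 1, seed = split_seed(seed, "noisy"))
  noisy <- render_zstack(net$volume, noisy_spec)
  list(truth = net$volume, truth_meta = net$truth, clean = clean,
       noisy = noisy, network_spec = nspec, render_spec = noisy_spec)
}
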