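# Hessian eigenvalues, vesselness, adaptive filter, binarisation, cleaning.

test_that("Hessian eigenvalues vanish on a constant stack", {
  st <- zstack(array(5, c(12, 12, 8)))
  eig <- hessian_eigenvalues(st, sigma = 1)
  expect_lt(max(abs(eig$lambda1)), 1e-10)
  expect_lt(max(abs(eig$lambda3)), 1e-10)
})

test_that("on a bright tube axis: lambda1 ~ 0, lambda2 ~ lambda3 < 0", {
  tube <- make_tube(cbind(c(4, 28), 16, 16), radius = 3, c(32, 32, 32))
  st <- zstack(array(as.numeric(tube$occupancy), c(32, 32, 32)))
  eig <- hessian_eigenvalues(st, sigma = 3)
  at <- c(16, 16, 16)  # a point on the axis
  l1 <- eig$lambda1[at[1], at[2], at[3]]
  l2 <- eig$lambda2[at[1], at[2], at[3]]
  l3 <- eig$lambda3[at[1], at[2], at[3]]
  expect_lt(abs(l1), 0.15 * abs(l3))
  expect_lt(l2, 0); expect_lt(l3, 0)
  expect_lt(abs(l2 - l3) / abs(l3), 0.25)
})

test_that("eigenvalues match a finite-difference Hessian oracle on a smooth field", {
  g <- vesselmink:::coord_grids(c(16, 16, 16))
  f <- exp(-((g$x - 8.3)^2 / 18 + (g$y - 7.6)^2 / 10 + (g$z - 8.9)^2 / 26)) +
       0.3 * sin(g$x / 3) * cos(g$y / 4)
  st <- zstack(f + 2)
  # tiny sigma so Gaussian pre-smoothing is negligible against the oracle
  eig <- suppressWarnings(hessian_eigenvalues(st, sigma = 0.05))
  for (at in list(c(8, 8, 9), c(5, 11, 7), c(12, 6, 10))) {
    want <- sort(fd_hessian_eigs(f, at)) * 0.05^2
    got <- sort(c(eig$lambda1[at[1], at[2], at[3]],
                  eig$lambda2[at[1], at[2], at[3]],
                  eig$lambda3[at[1], at[2], at[3]]))
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("vesselness matches its closed form on ideal eigenvalue patterns", {
  dims <- c(2, 2, 2)
  zero <- array(0, dims)
  # all-zero eigenvalues: score 0
  expect_equal(vesselness(list(lambda1 = zero, lambda2 = zero, lambda3 = zero)),
               zero)
  # ideal tube axis (lambda1 = 0, lambda2 = lambda3 = -s, s >> gamma):
  # R_A = 1, R_B = 0 -> V -> (1 - e^{-1/(2 alpha^2)}); alpha = 0.5 -> 1 - e^-2
  s <- 100
  v <- vesselness(list(lambda1 = zero, lambda2 = array(-s, dims),
                       lambda3 = array(-s, dims)),
                  alpha = 0.5, beta = 0.5, gamma = 1)
  expect_equal(v[1], (1 - exp(-2)) * (1 - exp(-(2 * s^2) / 2)), tolerance = 1e-6)
  expect_equal(v[1], 0.8647, tolerance = 1e-3)
  # bright-structure polarity: positive lambda2/lambda3 scores 0
  v0 <- vesselness(list(lambda1 = zero, lambda2 = array(s, dims),
                        lambda3 = array(s, dims)))
  expect_equal(v0, zero)
})

test_that("multi-scale combination dominates single scales and preserves ranking", {
  # two-radius phantom: thin (r = 1.5) and fat (r = 5) tubes
  occ <- make_tube(cbind(c(7, 41), 12, 16), 1.5, c(48, 36, 32))$occupancy |
         make_tube(cbind(c(7, 41), 26, 16), 5, c(48, 36, 32))$occupancy
  st <- render_zstack(binary_volume(occ),
                      render_spec(psf_sigma = c(1, 1, 1), noise_sd = 0,
                                  speckle_rate = 0, background_level = 0))
  vmode <- function(scales) adaptive_filter(st, filter_params(
    scales = scales, combine = "vesselness"))
  s_small <- suppressWarnings(vmode(c(1.4, 1.5)))
  s_big <- suppressWarnings(vmode(c(4.9, 5)))
  s_multi <- vmode(c(1.5, 2.2, 3.3, 5))
  axis_thin <- cbind(20:30, 12, 16); axis_fat <- cbind(20:30, 26, 16)
  score_at <- function(sc, ax) mean(sc[ax])
  # the multiscale filter scores both axes strongly; each single-scale
  # filter is clearly weaker on the mismatched calibre
  expect_gt(score_at(s_multi, axis_thin), 0.95 * score_at(s_small, axis_thin))
  expect_gt(score_at(s_multi, axis_fat), 0.95 * score_at(s_big, axis_fat))
  expect_gt(score_at(s_multi, axis_fat), score_at(s_small, axis_fat))
  expect_gt(score_at(s_multi, axis_thin), score_at(s_big, axis_thin))
})

test_that("adding a scale never decreases the combined log-score", {
  net <- make_network(network_spec(seed = 8, grid_shape = c(48, 32, 20)))
  st <- render_zstack(net$volume, render_spec(noise_sd = 0.1, seed = 2))
  p2 <- filter_params(scales = c(1.5, 3), combine = "vesselness")
  p3 <- filter_params(scales = c(1.5, 3, 4.5), combine = "vesselness")
  # compare unscaled combined maxima via the internal log-max: use the fact
  # that the [0,1] rescale is monotone with a fixed floor at log(eps)
  s2 <- adaptive_filter(st, p2)
  s3 <- adaptive_filter(st, p3)
  # rescaled by each field's own max: compare on the raw log scale
  eps <- 1e-6
  raw <- function(s, st_, p_) {
    hi2 <- max(vapply(p_$scales, function(sg)
      max(log(eps + vesselness(hessian_eigenvalues(
        vesselmink:::prepare_stack(st_, p_), sg), p_$alpha, p_$beta))), 0))
    s * (hi2 - log(eps)) + log(eps)
  }
  expect_true(all(raw(s3, st, p3) >= raw(s2, st, p2) - 1e-8))
})

test_that("Otsu and isodata thresholds behave on bimodal scores", {
  set.seed(5)
  x <- c(rnorm(4000, 0.2, 0.05), rnorm(4000, 0.8, 0.05))
  x <- x[x > 0 & x < 1]
  t_otsu <- otsu_threshold(x)
  expect_gt(t_otsu, 0.4); expect_lt(t_otsu, 0.6)
  # brute-force sweep of the between-class variance criterion
  cand <- seq(0.05, 0.95, by = 0.001)
  bcv <- vapply(cand, function(t) {
    w0 <- mean(x <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(x[x <= t]) - mean(x[x > t]))^2
  }, 0)
  top <- which(bcv >= max(bcv) * (1 - 1e-9))
  expect_equal(t_otsu, mean(cand[range(top)]), tolerance = 0.01)
  t_iso <- isodata_threshold(x)
  expect_gt(t_iso, 0.4); expect_lt(t_iso, 0.6)
  expect_error(otsu_threshold(rep(0.5, 10)), "degenerate")
})

test_that("binarise recovers indicator scores and rejects degenerate fields", {
  set.seed(6)
  truth <- array(runif(1000) < 0.3, c(10, 10, 10))
  sc <- array(as.numeric(truth), dim(truth))
  for (thr in c(0.1, 0.5, 0.9)) {
    m <- binarise(sc, filter_params(threshold_method = "fixed",
                                    fixed_threshold = thr))
    expect_identical(m$occupancy, truth)
  }
  # default method also recovers it (all non-zero scores equal)
  m <- binarise(sc, filter_params())
  expect_identical(m$occupancy, truth)
  expect_true(m$meta$threshold > 0 && m$meta$threshold < 1)
  expect_error(binarise(array(0, c(5, 5, 5)), filter_params()), "degenerate")
  expect_error(binarise(array(2, c(5, 5, 5)), filter_params()), "\\[0, 1\\]")
})

test_that("clean removes small clusters and keeps large ones", {
  occ <- array(FALSE, c(30, 12, 12))
  occ[2:11, 2:11, 2:6] <- TRUE                       # 500 voxels
  occ[20:24, 2:3, 2] <- TRUE                         # 10 voxels
  v <- binary_volume(occ)
  out <- clean(v, filter_params(min_cluster_voxels = 100))
  expect_identical(sum(out$occupancy), 500L)
  expect_identical(out$meta$removed_components, 1L)
  # min_cluster_voxels = 1 is the identity
  expect_identical(clean(v, filter_params(min_cluster_voxels = 1))$occupancy,
                   occ)
  # cleaning everything warns but returns an empty volume
  expect_warning(clean(v, filter_params(min_cluster_voxels = 1e6)),
                 "every component")
})

test_that("segmentation is deterministic and affine-intensity invariant", {
  ph <- standard_phantom(seed = 6, snr = 5)
  p <- filter_params(scales = c(1.5, 2.1, 3, 4.2, 6))
  m1 <- segment_stack(ph$noisy, p)
  m2 <- segment_stack(ph$noisy, p)
  expect_identical(m1$occupancy, m2$occupancy)
  resc <- zstack(3.7 * ph$noisy$voxels + 11, ph$noisy$spacing)
  m3 <- segment_stack(resc, p)
  expect_identical(m3$occupancy, m1$occupancy)
})

test_that("cleaning removes noise components but keeps the true network", {
  ph <- standard_phantom(seed = 2, snr = 5)
  p <- filter_params(scales = c(1.5, 2.1, 3, 4.2, 6))
  sc <- adaptive_filter(ph$noisy, p)
  raw <- binarise(sc, p, spacing = ph$noisy$spacing)
  cleaned <- clean(raw, p)
  lab_truth <- label_components(ph$truth$occupancy, 26)
  lab_clean <- label_components(cleaned$occupancy, 26)
  # every ground-truth component survives cleaning
  expect_gte(length(lab_clean$sizes), length(lab_truth$sizes))
  overlap <- cleaned$occupancy & ph$truth$occupancy
  expect_gt(sum(overlap) / sum(ph$truth$occupancy), 0.85)
})
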