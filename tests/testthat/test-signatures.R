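# EDT, dilation, signatures and the 40-feature summary.

test_that("EDT matches elementary distances and the exhaustive oracle", {
  occ <- array(FALSE, c(9, 9, 3)); occ[2, 2, 2] <- TRUE
  d <- edt(binary_volume(occ))
  expect_equal(d[5, 6, 2], 5)            # a 3-4-5 triangle
  expect_equal(d[2, 2, 2], 0)
  expect_equal(edt(binary_volume(array(TRUE, c(4, 4, 4)))),
               array(0, c(4, 4, 4)))
  expect_warning(edt(binary_volume(array(FALSE, c(4, 4, 4)))), "empty")

  set.seed(17)
  for (i in 1:8) {
    occ <- array(runif(512) < runif(1, 0.05, 0.5), c(8, 8, 8))
    if (!any(occ)) next
    expect_equal(edt(binary_volume(occ)), brute_edt(occ), tolerance = 1e-12)
  }
  # anisotropic spacing honoured in physical units
  occ <- array(FALSE, c(9, 3, 9)); occ[2, 2, 2] <- TRUE
  dphys <- edt(binary_volume(occ, spacing = c(2, 2, 1)), units = "physical")
  expect_equal(dphys[5, 2, 2], 6)        # 3 voxels x 2 um
  expect_equal(dphys[2, 2, 6], 4)        # 4 voxels x 1 um
})

test_that("dilation is the identity at r = 0 and nested in r", {
  set.seed(18)
  occ <- array(runif(1000) < 0.1, c(10, 10, 10))
  v <- binary_volume(occ)
  d <- edt(v)
  expect_identical(dilate_at(d, 0)$occupancy, occ)
  prev <- dilate_at(d, 0)$occupancy
  for (r in c(1, 2, 3.5)) {
    cur <- dilate_at(d, r)$occupancy
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("two balls merge at exactly the midpoint dilation radius", {
  # centres 10 apart, radius 3: the midpoint enters both dilations at r = 2
  occ <- array(FALSE, c(28, 13, 13))
  occ <- occ | make_ball(3, c(28, 13, 13), c(9, 7, 7))$occupancy |
               make_ball(3, c(28, 13, 13), c(19, 7, 7))$occupancy
  v <- binary_volume(occ)
  sig <- mf_signature(v, radii = 0:3)
  expect_identical(sig$curves$euler3D, c(2L, 2L, 1L, 1L))
  # fractionally below the merge radius the components are still separate
  d <- edt(v)
  expect_identical(minkowski_3d(dilate_at(d, 1.99))$euler, 2L)
  expect_identical(minkowski_3d(dilate_at(d, 2))$euler, 1L)
})

test_that("signatures respect dilation monotonicity and ground-truth topology", {
  net <- make_network(network_spec(n_components = 1, n_loops = 3,
                                   radius_mean = 2, tortuosity = 1,
                                   grid_shape = c(96, 40, 26), seed = 19))
  sig <- mf_signature(net$volume, radii = 0:8)
  expect_true(all(diff(sig$curves$vol) >= 0))
  # euler starts at k - L = -2
  expect_identical(sig$curves$euler3D[1], -2L)
  # radii validation
  expect_error(mf_signature(net$volume, radii = c(1, 2)), "start at 0")
  expect_error(mf_signature(net$volume, radii = c(0, 2, 2)), "increasing")
  # saturation: radii beyond the grid give the full-grid functional
  small <- make_ball(2, c(9, 9, 9))
  sat <- mf_signature(small, radii = c(0, 30))
  expect_identical(sat$curves$vol[2], as.integer(prod(dim(small$occupancy))))
  expect_identical(sat$curves$euler3D[2], 1L)
})

test_that("a tree keeps Euler number 1 until self-contacts create loops", {
  net <- make_network(network_spec(n_components = 1, n_loops = 0,
                                   radius_mean = 2, tortuosity = 3,
                                   grid_shape = c(64, 40, 20), seed = 23))
  sig <- mf_signature(net$volume, radii = 0:4)
  expect_identical(sig$curves$euler3D[1], 1L)
  expect_true(all(sig$curves$euler3D[1:2] == 1L))
})

test_that("normalization maps the collection extremes to [0, 1] and is invertible", {
  net <- make_network(network_spec(seed = 25, grid_shape = c(48, 32, 28),
                                   n_loops = 1))
  s1 <- mf_signature(net$volume, radii = 0:6)
  b <- make_ball(4, c(48, 32, 28), c(24, 16, 14))
  s2 <- mf_signature(b, radii = 0:6)
  normed <- normalize_for_report(list(s1, s2))
  sc <- attr(normed, "scaling")
  for (nm in c("vol", "surf_area", "mean_breadth")) {
    mx <- max(normed[[1]]$curves[[nm]], normed[[2]]$curves[[nm]])
    expect_equal(mx, 1)
    # argmax abscissas preserved (monotone map)
    expect_identical(which.max(normed[[1]]$curves[[nm]]),
                     which.max(s1$curves[[nm]]))
    # denormalization recovers the originals
    expect_equal(normed[[1]]$curves[[nm]] * sc[[nm]]$max, s1$curves[[nm]],
                 tolerance = 1e-12)
  }
  eu <- c(normed[[1]]$curves$euler3D, normed[[2]]$curves$euler3D)
  expect_equal(range(eu), c(0, 1))
  back <- normed[[1]]$curves$euler3D * (sc$euler3D$max - sc$euler3D$min) +
    sc$euler3D$min
  expect_equal(back, as.numeric(s1$curves$euler3D), tolerance = 1e-12)
  # single signature: its own max maps to 1
  n1 <- normalize_for_report(s1)
  expect_equal(max(n1[[1]]$curves$vol), 1)
})

test_that("the worked curve yields the published hand-computed features", {
  sig <- structure(list(radii = 0:3,
                        curves = data.frame(vol = c(0, 1, 4, 9),
                                            surf_area = c(0, 1, 4, 9),
                                            mean_breadth = c(0, 1, 4, 9),
                                            euler3D = c(0, 1, 4, 9))),
                   class = "mf_signature")
  f <- extract_features(sig)
  expect_length(f, 40)
  expect_identical(names(f), feature_names())
  expect_equal(unname(f["vol_mean"]), 3.5)
  expect_equal(unname(f["vol_median"]), 2.5)
  expect_equal(unname(f["vol_max"]), 9)
  expect_equal(unname(f["vol_maxScale"]), 3)
  expect_equal(unname(f["vol_min"]), 0)
  expect_equal(unname(f["vol_minScale"]), 0)
  expect_equal(unname(f["vol_dmax"]), 5)
  expect_equal(unname(f["vol_dmaxScale"]), 2)
  expect_equal(unname(f["vol_var"]), mean((c(0, 1, 4, 9) - 3.5)^2))
  # all four blocks see the same curve here
  expect_equal(unname(f["euler3D_dmax"]), 5)
})

test_that("constant curves have zero variance and ties break to the smallest abscissa", {
  sig <- structure(list(radii = 0:2,
                        curves = data.frame(vol = c(5, 5, 5), surf_area = c(5, 5, 5),
                                            mean_breadth = c(5, 5, 5),
                                            euler3D = c(5, 5, 5))),
                   class = "mf_signature")
  f <- extract_features(sig)
  expect_equal(unname(f["vol_var"]), 0)
  expect_equal(unname(f["vol_std"]), 0)
  expect_equal(unname(f["vol_dmax"]), 0)
  expect_equal(unname(f["vol_dmaxScale"]), 0)
  expect_equal(unname(f["vol_maxScale"]), 0)
  # a single-radius signature has no derivative
  sig1 <- structure(list(radii = 0, curves = data.frame(
    vol = 1, surf_area = 1, mean_breadth = 1, euler3D = 1)),
    class = "mf_signature")
  expect_error(extract_features(sig1), "single radius")
})

test_that("feature properties hold over random curves", {
  set.seed(29)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    y <- rnorm(n)
    sig <- structure(list(radii = 0:(n - 1),
                          curves = data.frame(vol = y, surf_area = y,
                                              mean_breadth = y, euler3D = y)),
                     class = "mf_signature")
    f <- extract_features(sig)
    expect_equal(unname(f["vol_std"]^2), unname(f["vol_var"]), tolerance = 1e-12)
    expect_gte(f[["vol_max"]], f[["vol_median"]])
    expect_gte(f[["vol_median"]], f[["vol_min"]])
    # maxScale is invariant under positive rescaling of y
    sig2 <- sig; sig2$curves[] <- lapply(sig2$curves, function(v) 3.7 * v)
    expect_identical(extract_features(sig2)[["vol_maxScale"]], f[["vol_maxScale"]])
  }
})

test_that("per-sample features average across fields of view", {
  set.seed(30)
  f1 <- stats::setNames(rnorm(40), feature_names())
  f2 <- stats::setNames(rnorm(40), feature_names())
  avg <- average_features(list(f1, f2))
  expect_equal(unname(avg), unname((f1 + f2) / 2)[match(feature_names(), names(f1))])
})
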