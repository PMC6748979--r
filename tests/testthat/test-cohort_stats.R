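# z-scores, PCA, age groups, pairwise ANOVA, stepwise regression.

test_that("z-scoring uses sample SD, is idempotent, and rejects constants", {
  tab <- synthetic_feature_cohort(n = 3, coefficients = c(0, 0), seed = 1)
  tab[, "vol_var"] <- c(1, 2, 3)
  z <- zscore(tab)
  expect_equal(unname(z[, "vol_var"]), c(-1, 0, 1))   # sample SD convention
  z2 <- zscore(z)
  expect_equal(as.matrix(z2[, feature_names()]), as.matrix(z[, feature_names()]),
               tolerance = 1e-12)
  tab2 <- tab; tab2[, "vol_mean"] <- 5
  expect_error(zscore(tab2), "vol_mean")
})

test_that("PCA recovers degenerate and random-table spectra", {
  # samples exactly on a line in feature space: one component explains all
  tab <- synthetic_feature_cohort(n = 10, coefficients = c(0, 0), seed = 2)
  t_line <- as.numeric(scale(seq_len(10)))
  m <- outer(t_line, rnorm(40, sd = 1))
  tab[, feature_names()] <- m
  p <- pca_features(tab)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)

  # explained variances equal brute-force covariance eigenvalues
  set.seed(3)
  tab10 <- synthetic_feature_cohort(n = 10, seed = 3)
  x <- as.matrix(tab10[, feature_names()])
  p10 <- pca_features(tab10)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(unname(p10$explained[seq_along(ev)]), ev / sum(ev),
               tolerance = 1e-9)
  # loadings orthonormal
  ll <- crossprod(p10$loadings)
  expect_equal(ll, diag(ncol(p10$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(p10$loadings)))
    expect_gte(p10$loadings[which.max(abs(p10$loadings[, j])), j], 0)

  # orthogonal rotation of the features leaves the spectrum unchanged
  q <- qr.Q(qr(matrix(rnorm(1600), 40, 40)))
  tabr <- tab10
  tabr[, feature_names()] <- x %*% q
  pr <- pca_features(tabr)
  expect_equal(pr$explained, p10$explained, tolerance = 1e-9)
  expect_error(pca_features(tab10[1:2, ]), "3 samples")
})

test_that("PC1 tracks a planted age factor through zscore + PCA", {
  tab <- synthetic_factor_cohort(n = 40, n_informative = 10, effect_size = 1,
                                 seed = 4)
  p <- pca_features(zscore(tab))
  expect_gte(abs(cor(p$scores[, 1], tab$age)), 0.7)
})

test_that("the six age groups have the published boundaries", {
  g <- age_groups(c(44, 45, 9, 84, 70, 74, 75, 80))
  expect_identical(as.character(g),
                   c("5-44", "45-54", "5-44", "80-84", "70-74", "70-74",
                     "75-79", "80-84"))
  expect_identical(nlevels(age_groups(c(10, 50))), 6L)
  expect_error(age_groups(c(30, 85)), "85")
  expect_error(age_groups(4), "outside")
})

test_that("pairwise ANOVA matches hand-computed sums of squares and Bonferroni", {
  tab <- synthetic_feature_cohort(n = 6, coefficients = c(0, 0), seed = 5)
  tab[, "vol_mean"] <- c(1, 2, 3, 4, 5, 6)
  groups <- factor(c("a", "a", "a", "b", "b", "b"))
  res <- anova_pairwise(tab, groups, features = c("vol_mean", "vol_var"))
  row <- res[res$feature == "vol_mean", ]
  # brute force: SSB = n1 n2 / n (m1 - m2)^2, F = SSB / (SSW / (n - 2))
  m1 <- 2; m2 <- 5
  ssb <- 3 * 3 / 6 * (m1 - m2)^2  # = sum n_i (m_i - grand)^2
  ssw <- sum((c(1, 2, 3) - m1)^2) + sum((c(4, 5, 6) - m2)^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  expect_equal(row$F, f_hand, tolerance = 1e-9)
  expect_equal(row$p, pf(f_hand, 1, 4, lower.tail = FALSE), tolerance = 1e-9)
  # family = pairs x features = 1 x 2 here
  expect_equal(row$p_adj, min(1, 2 * row$p), tolerance = 1e-12)

  # two identical groups: F = 0, p = 1
  tab2 <- tab
  tab2[, "vol_mean"] <- c(1, 2, 3, 1, 2, 3)
  res2 <- anova_pairwise(tab2, groups, features = "vol_mean")
  expect_equal(res2$F, 0, tolerance = 1e-12)
  expect_equal(res2$p_adj, 1)

  expect_error(anova_pairwise(tab, factor(c("a", "a", "a", "a", "a", "b"))),
               "degenerate")
  # min(1, m p) saturates: m = 3, p = 0.4 -> 1
  expect_identical(min(1, 3 * 0.4), 1)
})

test_that("stepwise regression recovers exact and planted models", {
  set.seed(6)
  X <- matrix(rnorm(40 * 30), 30, 40, dimnames = list(NULL, feature_names()))
  # y exactly one feature: that feature alone, r2 = 1
  fit <- stepwise_ols(X, X[, "surf_area_dmax"])
  expect_identical(fit$selected, "surf_area_dmax")
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_error(stepwise_ols(X[1:4, ], rnorm(4)), "n > 5")

  # forced two-signal design: both signals recovered (entered first, with
  # dominant coefficients) in >= 95% of seeds.  Classic forward-backward
  # selection with 38 spare candidates also admits occasional noise terms
  # (each forward step has a ~85% chance that some null candidate clears
  # p_enter = 0.05), so exact support recovery is not a property of the
  # procedure; the bootstrap layer's 2-4-feature model filter is what
  # restores sparsity downstream.
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    Xs <- matrix(rnorm(40 * 40), 40, 40, dimnames = list(NULL, feature_names()))
    y <- 2 * Xs[, 1] + Xs[, 2] + rnorm(40, sd = 0.1)
    f <- stepwise_ols(Xs, y)
    both_in <- all(feature_names()[1:2] %in% f$selected)
    first_two <- identical(f$selected[1:2], feature_names()[1:2])
    if (both_in && first_two) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("null stepwise selections occur near the nominal entry rate", {
  # calibration regime (n large relative to the candidate pool)
  runs <- 60; n <- 200; tot <- 0
  for (s in seq_len(runs)) {
    set.seed(split_seed(7, "null-unit", s))
    X <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, feature_names()))
    tot <- tot + length(stepwise_ols(X, rnorm(n, 60, 10))$selected)
  }
  rate <- tot / (runs * 40)
  ci <- 1.96 * sqrt(0.05 * 0.95 / (runs * 40))
  expect_lt(abs(rate - 0.05), ci + 0.01)
})

test_that("bootstrap stepwise is deterministic and honours the size filter", {
  tab <- synthetic_feature_cohort(n = 30, seed = 8)
  r1 <- bootstrap_stepwise(tab, n_boot = 40, n_repeats = 2, seed = 9,
                           age_min = NULL)
  r2 <- bootstrap_stepwise(tab, n_boot = 40, n_repeats = 2, seed = 9,
                           age_min = NULL)
  expect_identical(r1$frequency, r2$frequency)
  expect_identical(r1$model_size_percentiles, r2$model_size_percentiles)

  # removing the size filter can only raise per-repeat selection counts
  r_all <- bootstrap_stepwise(tab, n_boot = 40, n_repeats = 2, seed = 9,
                              model_size_filter = c(1, 40), age_min = NULL)
  # compare raw counts: frequencies are per filtered model, so compare the
  # number of models any feature appears in
  expect_gte(r_all$n_filtered, r1$n_filtered)
  expect_true(all(r_all$model_size_percentiles >= c(1, 1, 1)))
  expect_true(!is.unsorted(r_all$model_size_percentiles))
})

test_that("the planted cohort tops the bootstrap selection frequencies", {
  tab <- synthetic_feature_cohort(n = 52, seed = 10)
  rep_ <- bootstrap_stepwise(tab, n_boot = 60, n_repeats = 3, seed = 11)
  top2 <- rep_$frequency$feature[1:2]
  expect_setequal(top2, c("surf_area_dmax", "euler3D_mean"))
  # and in every repeat individually
  for (i in seq_len(nrow(rep_$per_repeat))) {
    ord <- names(sort(rep_$per_repeat[i, ], decreasing = TRUE))[1:2]
    expect_setequal(ord, c("surf_area_dmax", "euler3D_mean"))
  }
  expect_true(all(rep_$frequency$freq_mean >= 0 & rep_$frequency$freq_mean <= 100))
})
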