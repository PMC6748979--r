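## Cohort statistics: z-scores, PCA, age groups, pairwise ANOVA with
## Bonferroni correction, and bootstrap stepwise regression of age on the
## 40 signature features with selection-frequency reporting.

#' Assemble and validate a sample table
#'
#' One row per sample: `sample_id`, `age` (years), optional `group`, and
#' the 40 signature features named as in [feature_names()].
#'
#' @param features matrix or data frame of feature columns (40, canonical
#'   names) or a full table already containing `sample_id`/`age`.
#' @param ages sample ages in years (> 0); omit when `features` already
#'   has an `age` column.
#' @param sample_id unique ids; default `s1..sn`.
#' @param group optional group labels.
#' @return a `sample_table` (data frame subclass).
#' @export
sample_table <- function(features, ages = NULL, sample_id = NULL, group = NULL) {
  features <- as.data.frame(features)
  if (is.null(ages) && "age" %in% names(features)) {
    ages <- features$age
    if (is.null(sample_id) && "sample_id" %in% names(features))
      sample_id <- features$sample_id
    if (is.null(group) && "group" %in% names(features))
      group <- features$group
  }
  want <- feature_names()
  missing <- setdiff(want, names(features))
  extra <- setdiff(setdiff(names(features), want),
                   c("sample_id", "age", "group"))
  if (length(missing) || length(extra))
    stopf("feature schema mismatch:%s%s",
          if (length(missing)) paste0(" missing [", paste(missing, collapse = ", "), "]") else "",
          if (length(extra)) paste0(" unexpected [", paste(extra, collapse = ", "), "]") else "")
  feats <- features[, want, drop = FALSE]
  n <- nrow(feats)
  if (n > 0) {
    if (is.null(ages)) stopf("ages are required")
    ages <- as.numeric(ages)
    if (length(ages) != n || anyNA(ages) || any(ages <= 0))
      stopf("ages must be %d positive numbers", n)
    if (anyNA(feats)) stopf("missing feature values")
  } else ages <- numeric(0)
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  if (anyDuplicated(sample_id)) stopf("sample ids must be unique")
  out <- cbind(data.frame(sample_id = as.character(sample_id),
                          age = ages, stringsAsFactors = FALSE),
               feats)
  if (!is.null(group)) out$group <- group
  class(out) <- c("sample_table", "data.frame")
  out
}

feature_matrix <- function(t) {
  as.matrix(t[, feature_names(), drop = FALSE])
}

#' z-score the feature columns of a sample table
#'
#' Each feature column is centred and scaled to unit sample standard
#' deviation (denominator n - 1).  Idempotent up to numerical noise.
#'
#' @param t a [sample_table()] with at least 2 samples.
#' @return the z-scored `sample_table`.
#' @export
zscore <- function(t) {
  stopifnot(inherits(t, "sample_table"))
  if (nrow(t) < 2) stopf("z-scoring needs at least 2 samples")
  x <- feature_matrix(t)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant feature column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  t[, feature_names()] <- scale(x)
  attr(t, "zscored") <- TRUE
  t
}

#' Principal components of the feature table
#'
#' Eigen-decomposition of the feature covariance (apply [zscore()] first
#' for the correlation-scale analysis).  Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param t a [sample_table()] with at least 3 samples.
#' @param n_components how many components to keep (default all).
#' @return object of class `vm_pca`: `scores` (samples x components),
#'   `loadings` (features x components, orthonormal), `explained`
#'   (variance fractions), `ages`.
#' @export
pca_features <- function(t, n_components = NULL) {
  stopifnot(inherits(t, "sample_table"))
  if (nrow(t) < 3) stopf("PCA needs at least 3 samples")
  x <- feature_matrix(t)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components %||% ncol(p$rotation), ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]; scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2
  structure(list(scores = scores, loadings = load,
                 explained = ev / sum(ev), ages = t$age),
            class = "vm_pca")
}

#' @export
print.vm_pca <- function(x, ...) {
  k <- min(3, length(x$explained))
  cat(sprintf("<vm_pca> %d samples, %d components\n", nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  explained variance: %s (first two: %.0f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$explained[1:k]), collapse = ", "),
              100 * sum(x$explained[1:2])))
  invisible(x)
}

#' Biplot of the first two components
#' @param x a `vm_pca`.
#' @param n_vectors label the this many highest-loading features.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vm_pca <- function(x, n_vectors = 6, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  cols <- grDevices::hcl.colors(7, "Zissou 1")[cut(x$ages, 6)]
  graphics::plot(s, col = cols, pch = 16,
                 xlab = sprintf("PC1 (%.0f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * x$explained[2]), ...)
  mag <- sqrt(rowSums(x$loadings[, 1:2]^2))
  top <- order(mag, decreasing = TRUE)[seq_len(min(n_vectors, nrow(x$loadings)))]
  sc <- 0.8 * max(abs(s)) / max(mag[top])
  graphics::arrows(0, 0, sc * x$loadings[top, 1], sc * x$loadings[top, 2],
                   length = 0.08, col = "grey30")
  graphics::text(sc * x$loadings[top, 1:2] * 1.08, labels = rownames(x$loadings)[top],
                 cex = 0.7, col = "grey10")
  invisible(x)
}

#' Bin ages into the standard six age groups
#'
#' Half-open bins `[lo, hi)` with default edges 5, 45, 55, 70, 75, 80, 85,
#' i.e. groups 5-44, 45-54, 55-69, 70-74, 75-79, 80-84 years.
#'
#' @param ages numeric ages (years).
#' @param edges bin edges (length m + 1 for m groups).
#' @return factor of group labels like `"45-54"`.
#' @export
age_groups <- function(ages, edges = c(5, 45, 55, 70, 75, 80, 85)) {
  stopifnot(length(edges) >= 2, !is.unsorted(edges, strictly = TRUE))
  out_of_range <- ages < edges[1] | ages >= edges[length(edges)]
  if (any(out_of_range))
    stopf("age(s) outside [%g, %g): sample(s) %s with age %s",
          edges[1], edges[length(edges)],
          paste(which(out_of_range), collapse = ", "),
          paste(ages[out_of_range], collapse = ", "))
  labs <- paste0(edges[-length(edges)], "-", edges[-1] - 1)
  cut(ages, breaks = edges, right = FALSE, labels = labs)
}

#' Pairwise one-way ANOVA per feature with Bonferroni correction
#'
#' For every feature and every pair of groups, the one-way ANOVA F test;
#' Bonferroni correction over the whole family (all pairs x all features
#' tested in the call): `p_adj = min(1, m p)`.
#'
#' @param t a [sample_table()].
#' @param groups factor of group labels, one per row of `t` (e.g. from
#'   [age_groups()]); groups with fewer than 2 samples are an error.
#' @param features which features to test (default all 40).
#' @return data frame with `feature`, `group1`, `group2`, `F`, `df1`,
#'   `df2`, `p`, `p_adj`.
#' @export
anova_pairwise <- function(t, groups, features = feature_names()) {
  stopifnot(inherits(t, "sample_table"), length(groups) == nrow(t))
  groups <- droplevels(as.factor(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stopf("need at least 2 groups")
  if (any(sizes < 2))
    stopf("degenerate group(s) with < 2 samples: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  pairs <- utils::combn(levels(groups), 2)
  x <- feature_matrix(t)[, features, drop = FALSE]
  res <- list()
  for (pi in seq_len(ncol(pairs))) {
    g1 <- pairs[1, pi]; g2 <- pairs[2, pi]
    sel <- groups %in% c(g1, g2)
    gg <- droplevels(groups[sel])
    for (f in features) {
      y <- x[sel, f]
      a <- stats::oneway.test(y ~ gg, var.equal = TRUE)
      res[[length(res) + 1]] <- data.frame(
        feature = f, group1 = g1, group2 = g2,
        F = unname(a$statistic), df1 = unname(a$parameter[1]),
        df2 = unname(a$parameter[2]), p = a$p.value)
    }
  }
  out <- do.call(rbind, res)
  m <- nrow(out)
  out$p_adj <- pmin(1, m * out$p)
  out
}

# ---- stepwise regression ----------------------------------------------------

## RSS of y ~ 1 + X[, cols] via least squares (QR).
.rss <- function(X1, y, cols) {
  f <- stats::.lm.fit(X1[, c(1L, cols + 1L), drop = FALSE], y)
  sum(f$residuals^2)
}

#' Forward-backward stepwise linear regression on partial-F p-values
#'
#' The classical procedure: at each cycle the candidate with the smallest
#' partial-F p-value below `p_enter` is added, then selected terms with
#' partial-F p-value above `p_remove` are removed (worst first).  Stops
#' when no move is possible, at the iteration cap (`2 *` number of
#' features), or on a cycle (the better-fitting of the cycling models is
#' kept and flagged).
#'
#' @param X numeric feature matrix (samples x features, named columns).
#' @param y response (ages).
#' @param p_enter,p_remove inclusion / exclusion p-value thresholds.
#' @return list with `selected` (column names, in entry order), `r2`,
#'   `F_overall`, `p_overall`, `p_values` (partial-F p per selected
#'   feature in the final model), `coefficients`, `converged`.
#' @export
stepwise_ols <- function(X, y, p_enter = 0.05, p_remove = 0.1) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= 5) stopf("need n > 5 samples")
  if (anyNA(X) || anyNA(y)) stopf("missing values are not allowed")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  X1 <- cbind(1, X)
  tss <- sum((y - mean(y))^2)
  sel <- integer(0)
  rss_cur <- tss
  seen <- character(0)
  converged <- TRUE
  best_cycle <- NULL
  tol0 <- 1e-10 * max(tss, 1)
  for (it in seq_len(2L * k)) {
    moved <- FALSE
    if (rss_cur <= tol0) break   # numerically perfect fit: nothing to gain
    # forward
    cand <- setdiff(seq_len(k), sel)
    if (length(cand) && n - length(sel) - 2 >= 1) {
      ps <- vapply(cand, function(j) {
        rss_j <- .rss(X1, y, c(sel, j))
        df2 <- n - length(sel) - 2
        if (rss_j >= rss_cur || rss_j <= 0) return(1)
        f <- (rss_cur - rss_j) / (rss_j / df2)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, 0)
      if (min(ps) < p_enter) {
        j <- cand[which.min(ps)]
        sel <- c(sel, j)
        rss_cur <- .rss(X1, y, sel)
        moved <- TRUE
      }
      if (rss_cur <= tol0) break
    }
    # backward
    repeat {
      if (length(sel) == 0) break
      df2 <- n - length(sel) - 1
      if (df2 < 1) break
      ps <- vapply(seq_along(sel), function(i) {
        rss_wo <- .rss(X1, y, sel[-i])
        f <- (rss_wo - rss_cur) / (rss_cur / df2)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, 0)
      if (max(ps) > p_remove) {
        sel <- sel[-which.max(ps)]
        rss_cur <- .rss(X1, y, sel)
        moved <- TRUE
      } else break
    }
    key <- paste(sort(sel), collapse = ",")
    if (key %in% seen) {
      converged <- FALSE
      if (!is.null(best_cycle) && best_cycle$rss < rss_cur) {
        sel <- best_cycle$sel; rss_cur <- best_cycle$rss
      }
      break
    }
    seen <- c(seen, key)
    if (is.null(best_cycle) || rss_cur < best_cycle$rss)
      best_cycle <- list(sel = sel, rss = rss_cur)
    if (!moved) break
  }
  # final model statistics
  p_sel <- length(sel)
  r2 <- if (tss > 0) 1 - rss_cur / tss else 0
  if (p_sel > 0 && n - p_sel - 1 >= 1 && tss > 0 && rss_cur > 0) {
    F_overall <- ((tss - rss_cur) / p_sel) / (rss_cur / (n - p_sel - 1))
    p_overall <- stats::pf(F_overall, p_sel, n - p_sel - 1, lower.tail = FALSE)
  } else { F_overall <- NA_real_; p_overall <- NA_real_ }
  pv <- if (p_sel > 0) {
    df2 <- n - p_sel - 1
    vapply(seq_along(sel), function(i) {
      rss_wo <- .rss(X1, y, sel[-i])
      f <- (rss_wo - rss_cur) / (rss_cur / df2)
      stats::pf(f, 1, df2, lower.tail = FALSE)
    }, 0)
  } else numeric(0)
  names(pv) <- colnames(X)[sel]
  cf <- if (p_sel > 0) {
    fit <- stats::.lm.fit(X1[, c(1L, sel + 1L), drop = FALSE], y)
    stats::setNames(fit$coefficients, c("(Intercept)", colnames(X)[sel]))
  } else stats::setNames(mean(y), "(Intercept)")
  list(selected = colnames(X)[sel], r2 = r2, F_overall = F_overall,
       p_overall = p_overall, p_values = pv, coefficients = cf,
       converged = converged)
}

#' Bootstrap stepwise regression with selection-frequency reporting
#'
#' Repeats, `n_repeats` times, `n_boot` bootstrap resamples of the
#' subjects (sampling rows with replacement), running [stepwise_ols()] of
#' age on the 40 features in each resample.  Feature selection frequencies
#' are tallied over the *conservative* models whose selected-feature count
#' falls within `model_size_filter`, and reported as mean +/- SD across
#' the repeats.
#'
#' @param t a [sample_table()] (>= 10 samples after the age restriction).
#' @param n_boot bootstrap cycles per repeat.
#' @param n_repeats independent repeats.
#' @param p_enter,p_remove stepwise thresholds.
#' @param model_size_filter keep models selecting between these many
#'   features (inclusive).
#' @param age_min only samples at least this old enter the regression
#'   (the age range where the features are near-linear in age); `NULL`
#'   keeps everyone.
#' @param seed integer seed; repeats use independently split seeds.
#' @return object of class `stepwise_report`: `frequency` (data frame:
#'   feature, freq_mean (%), freq_sd, p_median), `model_size_percentiles`
#'   (25/50/75 over all resamples), `r2_mean`, `r2_se`, `median_F`
#'   (over filtered models), `n_models`, `n_filtered`, `n_skipped`,
#'   and the call parameters.
#' @export
bootstrap_stepwise <- function(t, n_boot = 3000, n_repeats = 6,
                               p_enter = 0.05, p_remove = 0.1,
                               model_size_filter = c(2, 4),
                               age_min = 40, seed = 1) {
  stopifnot(inherits(t, "sample_table"))
  if (!is.null(age_min)) t <- t[t$age >= age_min, , drop = FALSE]
  n <- nrow(t)
  if (n < 10) stopf("need at least 10 samples, got %d", n)
  X <- feature_matrix(t)
  y <- t$age
  feats <- colnames(X)
  sel_freq <- matrix(0, n_repeats, length(feats), dimnames = list(NULL, feats))
  sizes <- integer(0)
  r2s <- numeric(0); Fs <- numeric(0)
  pvals <- stats::setNames(vector("list", length(feats)), feats)
  n_skipped <- 0L; n_filtered <- 0L
  for (rep_i in seq_len(n_repeats)) {
    set.seed(split_seed(seed, "bootstrap-repeat", rep_i))
    counts <- stats::setNames(numeric(length(feats)), feats)
    n_kept <- 0L
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      yb <- y[rows]
      if (stats::sd(yb) == 0) { n_skipped <- n_skipped + 1L; next }
      fit <- tryCatch(stepwise_ols(X[rows, , drop = FALSE], yb,
                                   p_enter, p_remove),
                      error = function(e) NULL)
      if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
      sizes <- c(sizes, length(fit$selected))
      if (length(fit$selected) >= model_size_filter[1] &&
          length(fit$selected) <= model_size_filter[2]) {
        n_kept <- n_kept + 1L
        counts[fit$selected] <- counts[fit$selected] + 1
        r2s <- c(r2s, fit$r2)
        Fs <- c(Fs, fit$F_overall)
        for (f in fit$selected)
          pvals[[f]] <- c(pvals[[f]], fit$p_values[[f]])
      }
    }
    n_filtered <- n_filtered + n_kept
    if (n_kept > 0) sel_freq[rep_i, ] <- 100 * counts / n_kept
  }
  freq <- data.frame(
    feature = feats,
    freq_mean = colMeans(sel_freq),
    freq_sd = apply(sel_freq, 2, stats::sd),
    p_median = vapply(pvals, function(p) if (length(p)) stats::median(p) else NA_real_, 0),
    row.names = NULL)
  freq <- freq[order(-freq$freq_mean), ]
  structure(list(
    frequency = freq,
    per_repeat = sel_freq,
    model_size_percentiles = stats::quantile(sizes, c(0.25, 0.5, 0.75),
                                             names = FALSE, type = 1),
    r2_mean = mean(r2s), r2_se = stats::sd(r2s) / sqrt(length(r2s)),
    median_F = stats::median(Fs, na.rm = TRUE),
    n_models = n_repeats * n_boot, n_filtered = n_filtered,
    n_skipped = n_skipped, n_samples = n,
    params = list(n_boot = n_boot, n_repeats = n_repeats, p_enter = p_enter,
                  p_remove = p_remove, model_size_filter = model_size_filter,
                  age_min = age_min, seed = seed)),
    class = "stepwise_report")
}

#' @export
print.stepwise_report <- function(x, n = 10, ...) {
  cat(sprintf("<stepwise_report> %d samples, %d x %d bootstrap stepwise regressions\n",
              x$n_samples, x$params$n_repeats, x$params$n_boot))
  cat(sprintf("  model size 25/50/75th percentiles: %s\n",
              paste(x$model_size_percentiles, collapse = "/")))
  cat(sprintf("  conservative models (%d-%d features): %d of %d; r2 = %.3f +/- %.3f (mean +/- SE), median F = %.1f\n",
              x$params$model_size_filter[1], x$params$model_size_filter[2],
              x$n_filtered, x$n_models - x$n_skipped, x$r2_mean, x$r2_se,
              x$median_F))
  cat(sprintf("  top %d selection frequencies (%% of conservative fits, mean +/- SD over repeats):\n", n))
  top <- utils::head(x$frequency, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-22s %5.1f +/- %.2f   p_med %s\n", top$feature[i],
                top$freq_mean[i], top$freq_sd[i],
                format.pval(top$p_median[i], digits = 2)))
  invisible(x)
}

#' Synthetic cohort with an age-driven common factor
#'
#' Generates a table whose informative features all load on a latent age
#' factor (`feature = loading * z(age) + noise`), giving the correlated
#' feature structure real signatures show; the remaining features are
#' independent noise.  The fixture for PCA-level properties.
#'
#' @param n number of samples.
#' @param n_informative number of features loading on the age factor.
#' @param effect_size loading in feature-SD units.
#' @param age_range ages drawn uniformly over this interval.
#' @param seed integer seed.
#' @return a [sample_table()].
#' @export
synthetic_factor_cohort <- function(n = 40, n_informative = 10,
                                    effect_size = 1, age_range = c(40, 85),
                                    seed = 1) {
  set.seed(split_seed(seed, "factor-cohort"))
  age <- stats::runif(n, age_range[1], age_range[2])
  z_age <- as.numeric(scale(age))
  x <- matrix(stats::rnorm(n * 40), n, 40, dimnames = list(NULL, feature_names()))
  idx <- seq_len(n_informative)
  signs <- rep(c(1, -1), length.out = n_informative)
  x[, idx] <- x[, idx] + outer(z_age, effect_size * signs)
  sample_table(as.data.frame(x), ages = age)
}

#' Synthetic feature-level cohort with a planted age signal
#'
#' Generates 40 independent standard-normal features and an age that is a
#' linear function of a chosen subset plus noise - the null/recovery
#' fixture for the statistics layer.  With `coefficients = 0` the table is
#' a pure null (age independent of every feature).
#'
#' @param n number of samples.
#' @param planted feature names carrying signal.
#' @param coefficients regression coefficients (years per SD of feature).
#' @param noise_sd residual age noise (years).
#' @param age_center mean age (years).
#' @param seed integer seed.
#' @return a [sample_table()].
#' @export
synthetic_feature_cohort <- function(n = 52,
                                     planted = c("surf_area_dmax", "euler3D_mean"),
                                     coefficients = c(8, 4), noise_sd = 2,
                                     age_center = 62, seed = 1) {
  stopifnot(all(planted %in% feature_names()),
            length(coefficients) == length(planted))
  set.seed(split_seed(seed, "feature-cohort"))
  x <- matrix(stats::rnorm(n * 40), n, 40, dimnames = list(NULL, feature_names()))
  age <- age_center + as.vector(x[, planted, drop = FALSE] %*% coefficients) +
    stats::rnorm(n, sd = noise_sd)
  age <- pmax(1, age)
  sample_table(as.data.frame(x), ages = age)
}
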