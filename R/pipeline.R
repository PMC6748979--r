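## End-to-end orchestration: stack -> mask -> thickness -> signature ->
## features (per sample), and manifest -> sample table -> cohort reports.

#' Run the full per-sample analysis chain
#'
#' Segmentation, local thickness, dilation signature and the 40-feature
#' summary for one z-stack.  Deterministic: rerunning with the same stack
#' and config gives identical results.  When `out_dir` is given, every
#' intermediate is written with a JSON provenance sidecar.
#'
#' @param stack a [zstack()] or a TIFF path.
#' @param config named list of options: any [filter_params()] argument,
#'   plus `radii` (dilation radii) and `units_mode`.
#' @param out_dir optional output directory for intermediates.
#' @param sample_id label used in file names and error messages.
#' @return list with `features` (length-40 vector), `mask`, `thickness`
#'   (its [thickness_stats()]), `signature`, and `threshold`/`scales`
#'   provenance.
#' @export
run_sample <- function(stack, config = list(), out_dir = NULL,
                       sample_id = "sample") {
  if (is.character(stack)) stack <- read_zstack(stack)
  stopifnot(inherits(stack, "zstack"))
  fp_args <- intersect(names(config), names(formals(filter_params)))
  params <- do.call(filter_params, config[fp_args])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("sample '%s' failed at stage %s: %s", sample_id, name,
            conditionMessage(e)))
  }
  mask <- stage("segmentation", segment_stack(stack, params))
  thick <- stage("thickness", local_thickness(mask))
  tstats <- thickness_stats(thick)
  radii <- config$radii %||% default_radii_from_stats(tstats)
  sig <- stage("signature", mf_signature(mask, radii,
                                         units_mode = config$units_mode %||% "voxel"))
  feats <- stage("features", extract_features(sig))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    base <- file.path(out_dir, sample_id)
    write_volume(mask, paste0(base, "_mask.tif"))
    write_volume(thick, paste0(base, "_thickness.tif"))
    utils::write.csv(as.data.frame(sig), paste0(base, "_signature.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(sample_id = sample_id,
           package_version = as.character(utils::packageVersion("vesselmink")),
           scales = mask$meta$scales, threshold = mask$meta$threshold,
           radii = radii, thickness = tstats,
           config = config),
      paste0(base, "_provenance.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(features = feats, mask = mask, thickness = tstats, signature = sig,
       threshold = mask$meta$threshold, scales = mask$meta$scales)
}

default_radii_from_stats <- function(tstats) {
  0:min(25L, max(2L, ceiling(3 * tstats$mean_diameter / 2)))
}

#' Run the analysis over a cohort and compute cohort statistics
#'
#' Applies [run_sample()] to every manifest entry, assembles the
#' [sample_table()], and runs the requested statistics.  Samples that fail
#' are excluded with a warning and counted (`n_excluded`), mirroring
#' field-of-view triage in practice; the run only fails when every sample
#' does.
#'
#' @param manifest data frame with columns `sample_id`, `path` (TIFF) and
#'   `age`; alternatively `volumes` + `ages` may be given directly.
#' @param config per-sample config (see [run_sample()]) plus statistics
#'   switches: `pca` (default TRUE), `anova` (default FALSE: needs enough
#'   samples per age group), `stepwise` (default FALSE), `n_boot`,
#'   `n_repeats`, `model_size_filter`, `age_min`.
#' @param volumes optional list of [zstack()]s (instead of manifest paths).
#' @param ages ages for `volumes`.
#' @param out_dir optional directory for per-sample intermediates.
#' @param seed seed for the statistics layer.
#' @return list with `table` (a [sample_table()]), `reports` (named list:
#'   `pca`, `anova`, `stepwise` as requested), `n_excluded`, `failures`.
#' @export
run_cohort <- function(manifest = NULL, config = list(), volumes = NULL,
                       ages = NULL, out_dir = NULL, seed = 1) {
  if (is.null(volumes)) {
    stopifnot(is.data.frame(manifest),
              all(c("sample_id", "path", "age") %in% names(manifest)),
              nrow(manifest) >= 1)
    ids <- as.character(manifest$sample_id)
    ages <- manifest$age
    inputs <- as.list(manifest$path)
  } else {
    stopifnot(length(volumes) >= 1, length(ages) == length(volumes))
    ids <- names(volumes) %||% paste0("s", seq_along(volumes))
    inputs <- volumes
  }
  feats <- list(); kept <- integer(0); failures <- character(0)
  for (i in seq_along(inputs)) {
    res <- tryCatch(run_sample(inputs[[i]], config, out_dir, ids[i]),
                    error = function(e) {
                      warnf("%s", conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) {
      feats[[length(feats) + 1]] <- res$features
      kept <- c(kept, i)
    } else failures <- c(failures, ids[i])
  }
  if (length(kept) == 0) stopf("all %d samples failed", length(inputs))
  tab <- sample_table(as.data.frame(do.call(rbind, feats)),
                      ages = ages[kept], sample_id = ids[kept])
  reports <- list()
  if (isTRUE(config$pca %||% TRUE) && nrow(tab) >= 3)
    reports$pca <- tryCatch(pca_features(zscore(tab)), error = function(e) {
      warnf("PCA skipped: %s", conditionMessage(e))
      NULL
    })
  if (isTRUE(config$anova %||% FALSE)) {
    groups <- age_groups(tab$age)
    reports$anova <- anova_pairwise(tab, groups)
  }
  if (isTRUE(config$stepwise %||% FALSE)) {
    reports$stepwise <- bootstrap_stepwise(
      tab,
      n_boot = config$n_boot %||% 3000,
      n_repeats = config$n_repeats %||% 6,
      model_size_filter = config$model_size_filter %||% c(2, 4),
      age_min = config$age_min %||% 40,
      seed = split_seed(seed, "cohort-stepwise"))
  }
  summary <- list(n_samples = length(inputs), n_excluded = length(failures),
                  excluded = failures)
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_feature_table(tab, file.path(out_dir, "features.csv"))
  }
  list(table = tab, reports = reports, n_excluded = length(failures),
       failures = failures, summary = summary)
}
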