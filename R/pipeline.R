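#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' the package defaults: k = 7 CAPs, TR = 2 s, |Z| > 1.96 attribution,
#' 5 k-means initializations capped at 500 iterations, covariate set
#' (age, sex, education, site, mean_fd), 5 x 5 nested CV, and feature
#' selection at p < 0.05. Any element can be overridden via \code{...} or
#' by a YAML file with the same field names.
#'
#' @param ... named overrides.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    k = 7L,
    seed = 1L,
    tr_seconds = 2,
    z_threshold = 1.96,
    n_init = 5L,
    max_iter = 500L,
    k_range = NULL,                    # e.g. 2:20 to emit validity.tsv
    covariates = c("age", "sex", "education", "site", "mean_fd"),
    contrast = c("control", "patient"),
    score_col = "hamd",
    score_group = "patient",
    alpha = 0.05,
    entropy_base = 2,
    classify = TRUE,
    outer_folds = 5L, inner_folds = 5L,
    cost_grid = 2^seq(-5, 15, 2), gamma_grid = 2^seq(-15, 3, 2),
    n_perm = 0L)                       # > 0 enables the permutation test
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields as in [default_config()].
#' @return configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full CAP dynamics pipeline
#'
#' Orchestrates standardize -> pool -> cluster -> Z maps -> network
#' attribution -> dynamics -> adjusted group statistics -> symptom
#' correlations -> (optionally) nested-CV SVM classification, writing every
#' stage's tables under \code{out_dir} together with the serialized
#' configuration, so a rerun with the same inputs, config and seed
#' reproduces the outputs exactly.
#'
#' @param cohort cohort list ([load_cohort()] or [simulate_cohort()] output).
#' @param out_dir output directory; created if missing. \code{NULL} skips
#'   writing and only returns results.
#' @param config configuration list from [default_config()] /
#'   [read_config()].
#' @return invisibly, a list with \code{model}, \code{zmaps},
#'   \code{attribution}, \code{similarity}, \code{dynamics} (long table),
#'   \code{stats}, \code{correlations}, \code{validity} (if requested),
#'   \code{classification} (if requested), \code{config}.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, config = default_config()) {
  std <- standardize_cohort(cohort)
  pooled <- pool_frames(std$series)
  model <- kmeans_correlation(pooled, config$k, n_init = config$n_init,
                              max_iter = config$max_iter, seed = config$seed)
  zres <- compute_cap_zmaps(std$series, model$assignments, k = config$k)
  attribution <- attribute_networks(zres$zmaps, cohort$atlas,
                                    z_threshold = config$z_threshold)
  similarity <- cap_similarity(zres$zmaps)
  validity <- if (!is.null(config$k_range))
    compute_validity(pooled, config$k_range, seed = config$seed,
                     n_init = config$n_init, max_iter = config$max_iter)
  profiles <- cohort_dynamics(model, tr_seconds = config$tr_seconds,
                              base = config$entropy_base)
  dyn <- dynamics_table(profiles)
  stats_tab <- group_contrast_table(dyn, cohort$manifest,
                                    covariate_names = config$covariates,
                                    group_levels = config$contrast)
  correlations <- tryCatch(
    symptom_correlation_table(dyn, cohort$manifest,
                              score_col = config$score_col,
                              group = config$score_group,
                              covariate_names = config$covariates),
    error = function(e) NULL)
  classification <- NULL
  if (isTRUE(config$classify)) {
    classification <- tryCatch({
      feats <- select_features(stats_tab, alpha = config$alpha)
      keep <- cohort$manifest$group %in% config$contrast
      ids <- cohort$manifest$subject_id[keep]
      x <- feature_matrix(dyn, feats, ids)
      labels <- factor(cohort$manifest$group[keep], levels = config$contrast)
      rep_ <- if (config$n_perm > 0L)
        permutation_test(x, labels, n_perm = config$n_perm, seed = config$seed,
                         outer_folds = config$outer_folds,
                         inner_folds = config$inner_folds,
                         cost_grid = config$cost_grid,
                         gamma_grid = config$gamma_grid)
      else
        nested_cv_svm(x, labels, outer_folds = config$outer_folds,
                      inner_folds = config$inner_folds,
                      cost_grid = config$cost_grid,
                      gamma_grid = config$gamma_grid, seed = config$seed)
      list(features = feats, report = rep_)
    }, error = function(e) {
      message("classification skipped: ", conditionMessage(e))
      NULL
    })
  }
  result <- list(model = model, zmaps = zres$zmaps,
                 attribution = attribution, similarity = similarity,
                 dynamics = dyn, stats = stats_tab,
                 correlations = correlations, validity = validity,
                 classification = classification, config = config)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  invisible(result)
}

.write_tsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  cfg$cost_grid <- as.numeric(cfg$cost_grid)
  cfg$gamma_grid <- as.numeric(cfg$gamma_grid)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(k = res$model$k, seed = res$model$seed, inertia = res$model$inertia,
         sizes = res$model$sizes,
         config_hash = unname(tools::md5sum(file.path(out_dir, "config.yaml")))),
    file.path(out_dir, "capmodel.json"), auto_unbox = TRUE, digits = NA)
  .write_tsv(res$model$centroids, file.path(out_dir, "centroids.tsv"))
  .write_tsv(res$zmaps, file.path(out_dir, "zmaps.tsv"))
  adir <- file.path(out_dir, "assignments")
  dir.create(adir, showWarnings = FALSE)
  for (sid in names(res$model$assignments))
    writeLines(as.character(res$model$assignments[[sid]]),
               file.path(adir, paste0(sid, ".tsv")))
  if (!is.null(res$validity)) .write_tsv(res$validity, file.path(out_dir, "validity.tsv"))
  .write_tsv(res$dynamics, file.path(out_dir, "dynamics.tsv"))
  .write_tsv(res$stats, file.path(out_dir, sprintf(
    "stats_%s_vs_%s.tsv", res$config$contrast[1], res$config$contrast[2])))
  if (!is.null(res$correlations))
    .write_tsv(res$correlations, file.path(out_dir, "correlations.tsv"))
  .write_tsv(as.data.frame(res$attribution$proportion),
             file.path(out_dir, "network_attribution.tsv"))
  if (!is.null(res$classification)) {
    rep_ <- res$classification$report
    obs <- if (!is.null(rep_$observed)) rep_$observed else rep_
    jsonlite::write_json(
      list(features = res$classification$features,
           mean = as.list(obs$mean),
           p_accuracy = rep_$p_accuracy, p_auc = rep_$p_auc),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE, digits = NA)
    .write_tsv(obs$folds, file.path(out_dir, "classification_folds.tsv"))
  }
  invisible(out_dir)
}
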