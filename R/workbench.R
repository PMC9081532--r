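# End-to-end orchestration of the synthetic study: simulate -> spectra ->
# refit -> CTS-MS -> per-type models -> evaluation -> metastasis cascade ->
# similarity -> connection score -> cfDNA combination.

#' Study configuration
#'
#' Collects every tunable of the synthetic study: the global seed (fanned
#' out to per-stage seeds by fixed offsets), the selection thresholds, the
#' generator scale, and the analysis variant flags.
#'
#' @param seed Global integer seed.
#' @param n_types,n_train,n_test Cohort scale (types; train/test samples per
#'   type).
#' @param n_signatures Catalog size (needs `n_types + 2`).
#' @param burden_meanlog,burden_sdlog Log-normal mutation-burden parameters.
#' @param concentration Dirichlet concentration of per-sample exposures.
#' @param presence_cutoff Contribution above which a signature counts as
#'   observed (default 0.06).
#' @param min_fraction,min_fc,min_diff CTS-MS selection thresholds
#'   (defaults 0.20, 1.5, 0.1).
#' @param mutation_min_freq,mutation_min_diff Mutation-marker thresholds
#'   (defaults 0.05, 0.1).
#' @param refit_cutoff Minimum reportable exposure in refitting (default 0.06).
#' @param mapping_threshold De novo-to-catalog similarity threshold (0.75).
#' @param stage1_threshold Liver-score threshold of the cascade (0.5).
#' @param n_met_per_origin,drift Metastasis generator settings.
#' @param dilution,dropout cfDNA generator settings.
#' @param similarity_variant Aggregate similarity variant, `"mean"` or
#'   `"mean_square"`.
#' @param connection_mode Connection-score reading, `"induced"` or `"full"`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 17, n_types = 10, n_train = 100, n_test = 100,
                       n_signatures = 12, burden_meanlog = log(200),
                       burden_sdlog = 0.8, concentration = 50,
                       presence_cutoff = 0.06, min_fraction = 0.20,
                       min_fc = 1.5, min_diff = 0.1,
                       mutation_min_freq = 0.05, mutation_min_diff = 0.1,
                       refit_cutoff = 0.06, mapping_threshold = 0.75,
                       stage1_threshold = 0.5, n_met_per_origin = 50,
                       drift = 0.05, dilution = 0.3, dropout = 0.1,
                       similarity_variant = c("mean", "mean_square"),
                       connection_mode = c("induced", "full")) {
  stopifnot(seed == round(seed), n_types >= 4, n_train >= 2, n_test >= 2,
            n_signatures >= n_types + 2,
            concentration > 0,
            presence_cutoff >= 0, presence_cutoff < 1,
            min_fraction >= 0, min_fraction <= 1,
            min_fc > 0, min_diff >= 0, min_diff < 1,
            mutation_min_freq >= 0, mutation_min_freq < 1,
            refit_cutoff >= 0, refit_cutoff < 1,
            mapping_threshold >= 0, mapping_threshold <= 1,
            stage1_threshold >= 0, stage1_threshold <= 1,
            drift > 0, dilution > 0, dilution <= 1, dropout >= 0, dropout < 1)
  structure(list(
    seed = as.integer(seed), n_types = n_types, n_train = n_train,
    n_test = n_test, n_signatures = n_signatures,
    burden_meanlog = burden_meanlog, burden_sdlog = burden_sdlog,
    concentration = concentration, presence_cutoff = presence_cutoff,
    min_fraction = min_fraction, min_fc = min_fc, min_diff = min_diff,
    mutation_min_freq = mutation_min_freq,
    mutation_min_diff = mutation_min_diff, refit_cutoff = refit_cutoff,
    mapping_threshold = mapping_threshold,
    stage1_threshold = stage1_threshold,
    n_met_per_origin = n_met_per_origin, drift = drift,
    dilution = dilution, dropout = dropout,
    similarity_variant = match.arg(similarity_variant),
    connection_mode = match.arg(connection_mode)
  ), class = "run_config")
}

#' Run the full synthetic study
#'
#' Executes every stage of the pipeline on generated data with known ground
#' truth and returns a machine-readable report of plain values: two runs
#' with the same configuration produce identical reports.
#'
#' @param config A [run_config()].
#' @return A `study_report` list with elements `per_type_auc`,
#'   `ctsms` (selected signatures per type), `exposure_recovery_mae`,
#'   `cascade` (stage-1 accuracy/sensitivity/specificity, stage-2 accuracy),
#'   `concordance` (within/between medians and rank-sum p),
#'   `connection` (group means and rank-sum p), `cfdna` (MS-only and
#'   combined accuracy), `sizes`, and the echoed `config`.
#' @export
run_full_synthetic_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  base <- config$seed

  ## ground truth and cohorts -------------------------------------------
  catalog <- synthetic_catalog(config$n_signatures, seed = base + 101L)
  profiles <- default_type_profiles(catalog, config$n_types)
  types <- names(profiles)
  train <- simulate_cohort(profiles, config$n_train, catalog,
                           burden_meanlog = config$burden_meanlog,
                           burden_sdlog = config$burden_sdlog,
                           concentration = config$concentration,
                           seed = base + 102L)
  test <- simulate_cohort(profiles, config$n_test, catalog,
                          burden_meanlog = config$burden_meanlog,
                          burden_sdlog = config$burden_sdlog,
                          concentration = config$concentration,
                          seed = base + 103L)

  ## refitting ----------------------------------------------------------
  expo_tr <- refit_cohort(train$spectra, catalog,
                          cutoff = config$refit_cutoff)$exposures
  expo_te <- refit_cohort(test$spectra, catalog,
                          cutoff = config$refit_cutoff)$exposures
  recovery_mae <- mean(abs(expo_tr - train$exposures))

  ## CTS-MS and per-type models -----------------------------------------
  ctsms <- lapply(types, function(t) {
    select_cts_ms(expo_tr, train$truth$type, t,
                  min_fraction = config$min_fraction, min_fc = config$min_fc,
                  min_diff = config$min_diff,
                  presence_cutoff = config$presence_cutoff)
  })
  names(ctsms) <- types
  models <- lapply(types, function(t) {
    cand <- ctsms[[t]]$signature
    if (length(cand) == 0L) cand <- colnames(expo_tr)
    fit_one_vs_rest(expo_tr, train$truth$type == t,
                    candidate_features = cand, type_name = t,
                    seed = base + 104L)
  })
  names(models) <- types
  per_type_auc <- vapply(types, function(t) {
    auc(predict(models[[t]], expo_te), test$truth$type == t)
  }, numeric(1))

  ## metastasis cascade --------------------------------------------------
  liver_type <- types[1L]
  origin_types <- types[2:4]
  met_cohort <- test
  for (j in seq_along(origin_types)) {
    met_cohort <- simulate_metastases(met_cohort, config$n_met_per_origin,
                                      drift = config$drift,
                                      seed = base + 110L + j,
                                      origin_types = origin_types[j])
  }
  met_idx <- met_cohort$truth$compartment == "metastasis"
  met_truth <- met_cohort$truth[met_idx, , drop = FALSE]
  expo_met <- refit_cohort(met_cohort$spectra[met_idx, , drop = FALSE],
                           catalog, cutoff = config$refit_cutoff)$exposures

  origin_train_idx <- train$truth$type %in% origin_types
  origin_model <- fit_origin_model(
    build_origin_features(expo_tr[origin_train_idx, , drop = FALSE],
                          models[origin_types]),
    train$truth$type[origin_train_idx], seed = base + 120L)

  liver_primary_idx_tr <- train$truth$type == liver_type
  liver_primary_idx_te <- test$truth$type == liver_type
  stage1_expo <- rbind(expo_tr[liver_primary_idx_tr, , drop = FALSE],
                       expo_te[liver_primary_idx_te, , drop = FALSE],
                       expo_met)
  stage1_truth <- c(rep("liver-primary",
                        sum(liver_primary_idx_tr) + sum(liver_primary_idx_te)),
                    rep("non-liver-origin", nrow(expo_met)))
  trace <- trace_metastasis(stage1_expo, models[[liver_type]],
                            models[origin_types], origin_model,
                            threshold = config$stage1_threshold)
  stage1 <- confusion_stats(trace$stage1_call, stage1_truth,
                            positive_class = "liver-primary")
  routed <- which(trace$stage1_call == "non-liver-origin" &
                    stage1_truth == "non-liver-origin")
  met_origin_truth <- met_truth$type[match(trace$sample_id[routed],
                                           met_truth$sample_id)]
  stage2_accuracy <- mean(trace$origin[routed] == met_origin_truth)

  ## primary-metastasis concordance --------------------------------------
  paired_idx <- match(met_truth$paired_primary, rownames(expo_te))
  conc <- primary_met_concordance(
    expo_te[paired_idx, , drop = FALSE], expo_met,
    background = expo_te, background_types = test$truth$type,
    primary_types = met_truth$type)

  ## connection-score separation -----------------------------------------
  module <- paste0("GENE", sprintf("%03d", 1:15))
  net <- simulate_ppi(module, background_genes = 200, p_in = 0.3,
                      p_out = 0.01, seed = base + 130L)
  set.seed(base + 131L)
  clustered <- replicate(50, {
    gs <- c(sample(module, 8L), sample(setdiff(net$genes, module), 4L))
    connection_score(gs, net, mode = config$connection_mode)$score
  })
  random <- replicate(50, {
    connection_score(sample(net$genes, 12L), net,
                     mode = config$connection_mode)$score
  })
  conn_cmp <- compare_score_groups(list(clustered = clustered,
                                        random = random))

  ## cfDNA combination ---------------------------------------------------
  pair <- types[c(length(types) - 1L, length(types))]
  cf_sources <- test$truth$sample_id[test$truth$type %in% pair &
                                       test$truth$compartment == "tissue"]
  cf_cohort <- simulate_cfdna(test, config$dilution, config$dropout,
                              seed = base + 140L, sample_ids = cf_sources)
  cf_idx <- cf_cohort$truth$compartment == "cfdna"
  cf_truth <- cf_cohort$truth[cf_idx, , drop = FALSE]
  expo_cf <- refit_cohort(cf_cohort$spectra[cf_idx, , drop = FALSE],
                          catalog, cutoff = config$refit_cutoff)$exposures

  ms_call <- classify_cfdna(expo_cf, models[[pair[1]]], models[[pair[2]]])
  cf_ms_accuracy <- mean(ms_call$call == cf_truth$type)

  markers <- lapply(pair, function(t) {
    select_specific_mutations(train$gene_matrix, train$truth$type, t,
                              min_freq = config$mutation_min_freq,
                              min_diff = config$mutation_min_diff)$gene
  })
  names(markers) <- pair
  marker_union <- unique(unlist(markers))
  combined_tr <- cbind(expo_tr,
                       train$gene_matrix[, marker_union, drop = FALSE])
  combined_models <- lapply(pair, function(t) {
    cand <- c(ctsms[[t]]$signature, markers[[t]])
    if (length(cand) == 0L) cand <- colnames(combined_tr)
    fit_one_vs_rest(combined_tr, train$truth$type == t,
                    candidate_features = cand, type_name = t,
                    seed = base + 141L)
  })
  names(combined_models) <- pair
  combined_cf <- cbind(expo_cf,
                       cf_cohort$gene_matrix[cf_idx, marker_union,
                                             drop = FALSE])
  comb_call <- classify_cfdna(combined_cf, combined_models[[pair[1]]],
                              combined_models[[pair[2]]])
  cf_combined_accuracy <- mean(comb_call$call == cf_truth$type)

  ## report --------------------------------------------------------------
  structure(list(
    per_type_auc = per_type_auc,
    ctsms = lapply(ctsms, function(x) x$signature),
    exposure_recovery_mae = recovery_mae,
    cascade = list(
      liver_type = liver_type,
      origin_types = origin_types,
      stage1_accuracy = stage1$accuracy,
      stage1_sensitivity = stage1$sensitivity,
      stage1_specificity = stage1$specificity,
      stage2_accuracy = stage2_accuracy,
      n_stage1 = length(stage1_truth),
      n_stage2 = length(routed)
    ),
    concordance = list(
      within_median = stats::median(conc$within),
      between_median = stats::median(conc$between),
      p_value = conc$p_value
    ),
    connection = list(
      clustered_mean = mean(clustered),
      random_mean = mean(random),
      p_value = conn_cmp$p_value[1]
    ),
    cfdna = list(
      pair = pair,
      ms_accuracy = cf_ms_accuracy,
      combined_accuracy = cf_combined_accuracy,
      n_markers = length(marker_union)
    ),
    sizes = list(
      n_train = nrow(train$spectra), n_test = nrow(test$spectra),
      n_metastases = nrow(expo_met), n_cfdna = nrow(expo_cf)
    ),
    config = unclass(config)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic study report (seed ", x$config$seed, ")\n", sep = "")
  cat("  per-type test AUC: min ", round(min(x$per_type_auc), 3),
      ", mean ", round(mean(x$per_type_auc), 3), "\n", sep = "")
  cat("  exposure recovery MAE: ",
      signif(x$exposure_recovery_mae, 3), "\n", sep = "")
  cat("  cascade: stage-1 accuracy ", round(x$cascade$stage1_accuracy, 3),
      ", stage-2 accuracy ", round(x$cascade$stage2_accuracy, 3), "\n",
      sep = "")
  cat("  primary-met concordance: within median ",
      round(x$concordance$within_median, 3), ", p = ",
      format(x$concordance$p_value, digits = 3), "\n", sep = "")
  cat("  connection score: clustered ", round(x$connection$clustered_mean, 3),
      " vs random ", round(x$connection$random_mean, 3), ", p = ",
      format(x$connection$p_value, digits = 3), "\n", sep = "")
  cat("  cfDNA (", paste(x$cfdna$pair, collapse = " vs "), "): MS-only ",
      round(x$cfdna$ms_accuracy, 3), ", combined ",
      round(x$cfdna$combined_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' Write a study report as JSON
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
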