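#' Run the full grading pipeline on a cohort
#'
#' Executes the complete analysis on a synthetic (or equivalently structured
#' real) cohort: spatial feature extraction, patient-level stratified
#' splitting, per-channel collinearity pruning, standardization with retained
#' training parameters, repeated sequential forward selection with
#' modal-subset voting (SMOTE-balanced clinical channel,
#' borderline-SMOTE-balanced spatial channel, patient-grouped CV folds for
#' section rows), model training, TBR aggregation of section probabilities,
#' the clinical/spatial fusion-weight scan on training CV, and final
#' evaluation of the fused model on the untouched test patients.
#'
#' @param cohort A [generate_cohort()] result (or a list with the same
#'   `clinical`, `sections`, `centroids` tibbles).
#' @param clinical_model,spatial_model Model keys (see [train_model()]).
#' @param test_fraction Patient-level test proportion (default 0.30).
#' @param iterations SFFS repetitions per channel (paper protocol: 100).
#' @param folds CV folds for SFFS and the fusion scan (paper protocol: 10).
#' @param cap Maximum features per model (default 10).
#' @param tune If `TRUE`, run [random_search()] (`tune_iterations` draws) on
#'   the modal subset before final training.
#' @param tune_iterations Randomized-search draws when tuning.
#' @param config [density_config()] for feature extraction.
#' @param min_nuclei Section inclusion threshold.
#' @param threshold Decision threshold for the final panel.
#' @param seed Master seed.
#' @return An object of class `grade_pipeline`: split ids, per-channel
#'   selection results, trained models, patient-level probabilities, the
#'   [scan_weights()] fusion result and test-set [metric_panel()]s for the
#'   clinical, spatial and fused models.
#' @export
run_grade_pipeline <- function(cohort,
                               clinical_model = "lr", spatial_model = "lr",
                               test_fraction = 0.30,
                               iterations = 100L, folds = 10L, cap = 10L,
                               tune = FALSE, tune_iterations = 100L,
                               config = density_config(), min_nuclei = 10L,
                               threshold = 0.5, seed = 1L) {
  clin <- tibble::as_tibble(cohort$clinical)
  split <- split_cohort(clin[, c("patient_id", "label")], test_fraction,
                        seed = derive_seed(seed, 1L))
  label_of <- setNames(clin$label, clin$patient_id)

  ## ---- clinical channel (patient rows) ----
  clin_feats <- c("age", "er", "pr", "her2")
  Xc <- clin[, clin_feats]
  tr_c <- clin$patient_id %in% split$train
  pr_c <- prune_collinear(Xc[tr_c, c("age", "er", "pr")], clin$label[tr_c])
  keep_c <- c(pr_c$retained, "her2")
  std_c <- fit_standardizer(Xc[tr_c, keep_c])
  Zc_tr <- apply_standardizer(std_c, Xc[tr_c, keep_c])
  Zc_te <- apply_standardizer(std_c, Xc[!tr_c, keep_c])
  sel_c <- sffs_select(Zc_tr, clin$label[tr_c], model = clinical_model,
                       iterations = iterations, folds = folds, cap = cap,
                       oversample_method = "smote",
                       seed = derive_seed(seed, 2L))
  par_c <- list()
  if (tune) {
    par_c <- random_search(Zc_tr[, sel_c$modal_subset, drop = FALSE],
                           clin$label[tr_c], model = clinical_model,
                           iterations = tune_iterations, folds = folds,
                           oversample_method = "smote",
                           seed = derive_seed(seed, 3L))$best_params
  }
  set.seed(derive_seed(seed, 4L))
  ov_c <- oversample(Zc_tr[, sel_c$modal_subset, drop = FALSE],
                     clin$label[tr_c], method = "smote")
  mod_c <- train_model(ov_c$features, ov_c$labels, model = clinical_model,
                       params = par_c, feature_set = "clinical")
  set.seed(derive_seed(seed, 5L))
  pc_tr <- tibble::tibble(patient_id = clin$patient_id[tr_c],
                          prob = predict(mod_c, Zc_tr))
  pc_te <- tibble::tibble(patient_id = clin$patient_id[!tr_c],
                          prob = predict(mod_c, Zc_te))

  ## ---- spatial channel (section rows, patient-level aggregation) ----
  feats <- extract_features(cohort$centroids, config = config,
                            min_nuclei = min_nuclei)
  feat_cols <- setdiff(names(feats), c("patient_id", "section_id"))
  sec_label <- label_of[feats$patient_id]
  tr_s <- feats$patient_id %in% split$train
  pr_s <- prune_collinear(feats[tr_s, feat_cols], sec_label[tr_s])
  keep_s <- setdiff(pr_s$retained, pr_s$constant)
  std_s <- fit_standardizer(feats[tr_s, keep_s])
  Zs_tr <- apply_standardizer(std_s, feats[tr_s, keep_s])
  Zs_te <- apply_standardizer(std_s, feats[!tr_s, keep_s])
  sel_s <- sffs_select(Zs_tr, sec_label[tr_s], model = spatial_model,
                       groups = feats$patient_id[tr_s],
                       iterations = iterations, folds = folds, cap = cap,
                       oversample_method = "borderline",
                       seed = derive_seed(seed, 6L))
  par_s <- list()
  if (tune) {
    par_s <- random_search(Zs_tr[, sel_s$modal_subset, drop = FALSE],
                           sec_label[tr_s], model = spatial_model,
                           groups = feats$patient_id[tr_s],
                           iterations = tune_iterations, folds = folds,
                           oversample_method = "borderline",
                           seed = derive_seed(seed, 7L))$best_params
  }
  set.seed(derive_seed(seed, 8L))
  ov_s <- oversample(Zs_tr[, sel_s$modal_subset, drop = FALSE],
                     sec_label[tr_s], method = "borderline")
  mod_s <- train_model(ov_s$features, ov_s$labels, model = spatial_model,
                       params = par_s, feature_set = "spatial")
  set.seed(derive_seed(seed, 9L))
  tbr <- compute_tbr(cohort$sections)
  Zs_all <- apply_standardizer(std_s, feats[, keep_s])
  sec_probs <- tibble::tibble(
    patient_id = feats$patient_id,
    section_id = feats$section_id,
    prob = predict(mod_s, Zs_all)
  )
  sec_probs <- dplyr::left_join(
    sec_probs, tbr[, c("section_id", "tumor_bed_area_px")], by = "section_id")
  # re-normalize TBR over the sections that survived feature extraction
  sec_probs <- compute_tbr(sec_probs)
  pat_probs <- aggregate_sections(sec_probs)
  ps_tr <- dplyr::filter(pat_probs, .data$patient_id %in% split$train)
  ps_te <- dplyr::filter(pat_probs, .data$patient_id %in% split$test)

  ## ---- fusion scan on training CV, evaluation on the untouched test set ----
  labels_tr <- tibble::tibble(patient_id = split$train,
                              label = label_of[split$train])
  fusion <- scan_weights(pc_tr, ps_tr, labels_tr, folds = folds,
                         seed = derive_seed(seed, 10L))
  te_ids <- intersect(pc_te$patient_id, ps_te$patient_id)
  y_te <- label_of[te_ids]
  p_clin_te <- setNames(pc_te$prob, pc_te$patient_id)[te_ids]
  p_spat_te <- setNames(ps_te$prob, ps_te$patient_id)[te_ids]
  fused_te <- fuse(p_clin_te, p_spat_te, fusion$w_star)
  structure(
    list(
      split = split,
      clinical = list(pruning = pr_c, selection = sel_c, model = mod_c,
                      standardizer = std_c,
                      probs_train = pc_tr, probs_test = pc_te),
      spatial = list(pruning = pr_s, selection = sel_s, model = mod_s,
                     standardizer = std_s, features = feats,
                     section_probs = sec_probs,
                     probs_train = ps_tr, probs_test = ps_te),
      fusion = fusion,
      test_panel_clinical = evaluate(p_clin_te, y_te, threshold),
      test_panel_spatial = evaluate(p_spat_te, y_te, threshold),
      test_panel_fused = evaluate(fused_te, y_te, threshold)
    ),
    class = "grade_pipeline"
  )
}

#' @export
print.grade_pipeline <- function(x, ...) {
  cat("<grade_pipeline>\n")
  cat(sprintf("  clinical %s: %s\n", x$clinical$model$model,
              paste(x$clinical$selection$modal_subset, collapse = ", ")))
  cat(sprintf("  spatial  %s: %s\n", x$spatial$model$model,
              paste(x$spatial$selection$modal_subset, collapse = ", ")))
  cat(sprintf("  fusion w* = %.2f (clinical %.0f%%)\n",
              x$fusion$w_star, x$fusion$clinical_weight_pct))
  cat(sprintf("  test AUC: clinical %.3f, spatial %.3f, fused %.3f\n",
              x$test_panel_clinical$AUC, x$test_panel_spatial$AUC,
              x$test_panel_fused$AUC))
  invisible(x)
}
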