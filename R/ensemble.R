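#' Tumor-bed ratio of each section within its slide
#'
#' The TBR of a section is its tumor-bed pixel area divided by the summed
#' tumor-bed areas of all sections of the same patient's slide; TBRs sum to
#' one within each patient.
#'
#' @param sections Data frame with `patient_id`, `section_id`,
#'   `tumor_bed_area_px`.
#' @return The input tibble with a `tbr` column added.
#' @export
compute_tbr <- function(sections) {
  stopifnot(all(c("patient_id", "section_id", "tumor_bed_area_px") %in%
                  names(sections)))
  if (any(sections$tumor_bed_area_px < 0)) {
    stop_nucleograde("Tumor-bed areas must be >= 0.", "nucleograde_parameter_error")
  }
  out <- sections |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(tbr = .data$tumor_bed_area_px / sum(.data$tumor_bed_area_px)) |>
    dplyr::ungroup()
  if (any(!is.finite(out$tbr))) {
    stop_nucleograde("Total tumor-bed area is zero for some patient.",
                     "nucleograde_parameter_error")
  }
  out
}

#' Aggregate section-level probabilities to the patient level
#'
#' Spatial-model predictions are made per biopsy section; the patient-level
#' probability is the TBR-weighted average
#' \eqn{p_\mathrm{patient} = \sum_s \mathrm{TBR}_s\, p_s}, a convex
#' combination bounded by the section extremes. When TBRs are absent,
#' sections are weighted uniformly (with a message).
#'
#' @param section_probs Data frame with `patient_id`, `section_id`, `prob`
#'   and optionally `tbr`.
#' @return A tibble with one row per patient: `patient_id`, `prob`.
#' @export
aggregate_sections <- function(section_probs) {
  stopifnot(all(c("patient_id", "section_id", "prob") %in% names(section_probs)))
  assert_probability(section_probs$prob, "prob")
  sp <- tibble::as_tibble(section_probs)
  if (!"tbr" %in% names(sp)) {
    inform("No `tbr` column; weighting sections uniformly.")
    sp <- sp |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(tbr = 1 / dplyr::n()) |>
      dplyr::ungroup()
  }
  bad <- sp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(s = sum(.data$tbr), .groups = "drop") |>
    dplyr::filter(abs(.data$s - 1) > 1e-9)
  if (nrow(bad) > 0) {
    stop_nucleograde("TBRs must sum to 1 within each patient.",
                     "nucleograde_parameter_error")
  }
  sp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(prob = sum(.data$tbr * .data$prob), .groups = "drop")
}

#' Fuse clinical and spatial probabilities at a fixed weight
#'
#' \eqn{p = (1-w)\,p_\mathrm{clin} + w\,p_\mathrm{spat}}: weight 0 is the
#' clinical model alone, weight 1 the spatial model alone.
#'
#' @param p_clin,p_spat Probabilities in \[0, 1\] (vectorized).
#' @param w Spatial weight in \[0, 1\].
#' @return Fused probabilities.
#' @export
fuse <- function(p_clin, p_spat, w) {
  assert_probability(p_clin, "p_clin")
  assert_probability(p_spat, "p_spat")
  if (length(w) != 1L || !is.finite(w) || w < 0 || w > 1) {
    stop_nucleograde("`w` must be a single weight in [0, 1].",
                     "nucleograde_parameter_error")
  }
  (1 - w) * p_clin + w * p_spat
}

#' Scan the clinical/spatial fusion weight on training predictions
#'
#' Evaluates the weight grid 0, 0.01, ..., 1 (101 points): at each weight the
#' clinical and patient-aggregated spatial training probabilities are fused
#' and the mean k-fold cross-validated AUC is computed (folds partition the
#' training patients; AUC is measured on each held-out fold and averaged).
#' The selected weight maximizes CV AUC, with ties broken toward the smaller
#' weight (the more clinical model). Endpoints reproduce the single-channel
#' CV AUCs exactly.
#'
#' @param clinical_preds Data frame `patient_id`, `prob` (clinical model,
#'   training patients).
#' @param spatial_preds Data frame `patient_id`, `prob` (patient-aggregated
#'   spatial model, same patients).
#' @param labels Data frame `patient_id`, `label`.
#' @param folds CV folds (default 10).
#' @param step Grid step (default 0.01).
#' @param seed Seed for the fold assignment.
#' @return An object of class `fusion_result` with the weight `grid`
#'   (w, cv_auc), `w_star`, `clinical_weight_pct` and the fold assignment.
#' @export
scan_weights <- function(clinical_preds, spatial_preds, labels,
                         folds = 10L, step = 0.01, seed = 1L) {
  cp <- tibble::as_tibble(clinical_preds)
  sp <- tibble::as_tibble(spatial_preds)
  lb <- tibble::as_tibble(labels)
  if (!setequal(cp$patient_id, sp$patient_id) ||
      !setequal(cp$patient_id, lb$patient_id)) {
    stop_nucleograde("Patient ids of the prediction sets and labels must align.",
                     "nucleograde_parameter_error")
  }
  df <- cp |>
    dplyr::rename(p_clin = "prob") |>
    dplyr::inner_join(dplyr::rename(sp, p_spat = "prob"), by = "patient_id") |>
    dplyr::inner_join(lb, by = "patient_id")
  assert_probability(df$p_clin, "clinical prob")
  assert_probability(df$p_spat, "spatial prob")
  set.seed(seed)
  fold_id <- make_folds(df$label, folds)
  ws <- seq(0, 1, by = step)
  cv_auc <- vapply(ws, function(w) {
    fused <- fuse(df$p_clin, df$p_spat, w)
    aucs <- vapply(sort(unique(fold_id)), function(f) {
      sel <- fold_id == f
      if (length(unique(df$label[sel])) < 2L) return(NA_real_)
      auc_rank(fused[sel], df$label[sel])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  w_star <- ws[which.max(cv_auc)] # which.max takes the first (smallest w) tie
  structure(
    list(grid = tibble::tibble(w = ws, cv_auc = cv_auc),
         w_star = w_star,
         clinical_weight_pct = 100 * (1 - w_star),
         cv_auc_star = max(cv_auc),
         fold_id = setNames(fold_id, df$patient_id)),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(
    "<fusion_result> w* = %.2f (clinical %.0f%% / spatial %.0f%%), CV AUC %.3f over %d weights\n",
    x$w_star, x$clinical_weight_pct, 100 - x$clinical_weight_pct,
    x$cv_auc_star, nrow(x$grid)))
  invisible(x)
}

#' Scan fusion weights over every clinical x spatial model pairing
#'
#' Runs [scan_weights()] for each combination of the supplied clinical and
#' spatial prediction sets and selects the pairing (and weight) with the
#' highest training-CV AUC, keeping the test set untouched during selection.
#'
#' @param clinical_sets Named list of clinical prediction data frames.
#' @param spatial_sets Named list of spatial prediction data frames.
#' @inheritParams scan_weights
#' @return A list with `best` (clinical, spatial, fusion_result) and the
#'   full `pairings` tibble.
#' @export
scan_weight_pairings <- function(clinical_sets, spatial_sets, labels,
                                 folds = 10L, step = 0.01, seed = 1L) {
  rows <- list()
  best <- NULL
  for (cn in names(clinical_sets)) {
    for (sn in names(spatial_sets)) {
      fr <- scan_weights(clinical_sets[[cn]], spatial_sets[[sn]], labels,
                         folds = folds, step = step, seed = seed)
      rows[[paste(cn, sn, sep = "+")]] <- tibble::tibble(
        clinical = cn, spatial = sn, w_star = fr$w_star,
        cv_auc = fr$cv_auc_star)
      if (is.null(best) || fr$cv_auc_star > best$fusion$cv_auc_star) {
        best <- list(clinical = cn, spatial = sn, fusion = fr)
      }
    }
  }
  list(best = best, pairings = dplyr::bind_rows(rows))
}
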