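#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selection result into the per-subset tally
#'
#' @param x A [sffs_select()] result.
#' @param ... Unused.
#' @return Tibble of `subset`, `frequency`, `mean_auc`, ordered by the
#'   modal-subset tie-break (frequency, then AUC, then name).
#' @export
tidy.selection_result <- function(x, ...) {
  x$tally
}

#' @rdname tidy.selection_result
#' @return `glance()`: one row with the modal subset, its frequency and size.
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    modal_subset = paste(x$modal_subset, collapse = "|"),
    modal_frequency = x$modal_frequency,
    modal_size = length(x$modal_subset),
    iterations = x$iterations
  )
}

#' Tidy a fusion result into the weight grid
#'
#' @param x A [scan_weights()] result.
#' @param ... Unused.
#' @return Tibble `w`, `cv_auc` (101 rows under the default grid).
#' @export
tidy.fusion_result <- function(x, ...) {
  x$grid
}

#' @rdname tidy.fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  tibble::tibble(w_star = x$w_star,
                 clinical_weight_pct = x$clinical_weight_pct,
                 spatial_weight_pct = 100 - x$clinical_weight_pct,
                 cv_auc = x$cv_auc_star)
}

#' Tidy a metric panel into long form
#'
#' @param x A [metric_panel()].
#' @param ... Unused.
#' @return Tibble `metric`, `value`.
#' @export
tidy.metric_panel <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.metric_panel
#' @export
glance.metric_panel <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.grade_pipeline <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$split$train),
    n_test = length(x$split$test),
    w_star = x$fusion$w_star,
    clinical_weight_pct = x$fusion$clinical_weight_pct,
    auc_clinical = x$test_panel_clinical$AUC,
    auc_spatial = x$test_panel_spatial$AUC,
    auc_fused = x$test_panel_fused$AUC,
    acc_fused = x$test_panel_fused$ACC
  )
}
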