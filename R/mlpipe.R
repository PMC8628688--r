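#' Area under the ROC curve by the rank (Mann-Whitney) method
#'
#' @param probs Numeric scores/probabilities.
#' @param labels Binary labels (0/1).
#' @return AUC in \[0, 1\]; ties handled with midranks (equivalent to the
#'   trapezoid rule over all thresholds).
#' @export
auc_rank <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_nucleograde("AUC undefined: need both classes.", "nucleograde_parameter_error")
  }
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Drop collinear continuous features by outcome correlation
#'
#' For every feature pair with Pearson \eqn{r^2 \ge} `r2_threshold`, the
#' member with the lower absolute point-biserial correlation against the
#' binary outcome is dropped; pairs are visited greedily in order of
#' decreasing \eqn{r^2} until no violating pair remains. Point-biserial is
#' computed as the Pearson correlation with the 0/1 label, which is
#' mathematically identical.
#'
#' @param features Data frame or matrix of continuous feature columns.
#' @param labels Binary outcome (0/1) aligned with rows.
#' @param r2_threshold Squared-correlation threshold (default 0.7).
#' @return A list with `retained` (character), `dropped` (tibble of
#'   `dropped`, `kept`, `r2`) and `constant` (flagged zero-variance
#'   features, retained untouched).
#' @export
prune_collinear <- function(features, labels, r2_threshold = 0.7) {
  X <- as.matrix(tibble::as_tibble(features))
  labels <- as.numeric(labels)
  if (nrow(X) < 2L) {
    stop_nucleograde("Need >= 2 samples.", "nucleograde_parameter_error")
  }
  sds <- apply(X, 2, sd)
  constant <- colnames(X)[sds == 0]
  active <- setdiff(colnames(X), constant)
  rpb <- vapply(active, function(f) {
    suppressWarnings(abs(cor(X[, f], labels)))
  }, numeric(1))
  rpb[is.na(rpb)] <- 0
  cm <- suppressWarnings(cor(X[, active, drop = FALSE]))^2
  cm[lower.tri(cm, diag = TRUE)] <- NA
  pairs <- which(cm >= r2_threshold, arr.ind = TRUE)
  dropped <- tibble::tibble(dropped = character(), kept = character(),
                            r2 = numeric())
  if (nrow(pairs) > 0) {
    ord <- order(cm[pairs], decreasing = TRUE)
    pairs <- pairs[ord, , drop = FALSE]
    out <- character(0)
    for (i in seq_len(nrow(pairs))) {
      a <- active[pairs[i, 1]]; b <- active[pairs[i, 2]]
      if (a %in% out || b %in% out) next
      loser <- if (rpb[a] >= rpb[b]) b else a
      winner <- if (loser == a) b else a
      out <- c(out, loser)
      dropped <- dplyr::add_row(dropped, dropped = loser, kept = winner,
                                r2 = cm[pairs[i, 1], pairs[i, 2]])
    }
    active <- setdiff(active, out)
  }
  if (length(constant) > 0) {
    warn(sprintf("Constant feature(s) flagged: %s", paste(constant, collapse = ", ")))
  }
  list(retained = c(active, constant), dropped = dropped, constant = constant)
}

#' Patient-level stratified train/test split
#'
#' Splits patients into training and independent test sets, stratified by
#' grade label, with the per-class test count `ceiling(test_fraction * class
#' size)`. All sections of one patient fall on one side by construction.
#'
#' @param patients Data frame with `patient_id` and binary `label`.
#' @param test_fraction Test proportion (default 0.30).
#' @param seed Integer seed for the class-wise sampling.
#' @return A list with character vectors `train` and `test`.
#' @examples
#' pts <- tibble::tibble(patient_id = sprintf("P%03d", 1:138),
#'                       label = rep(c(1, 0), c(80, 58)))
#' sp <- split_cohort(pts, 0.30, seed = 1)
#' length(sp$test) # 42
#' @export
split_cohort <- function(patients, test_fraction = 0.30, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_nucleograde("`test_fraction` must lie in (0, 1).",
                     "nucleograde_parameter_error")
  }
  if (min(table(patients$label)) < 2L) {
    stop_nucleograde("Each class needs >= 2 patients.",
                     "nucleograde_parameter_error")
  }
  set.seed(seed)
  test <- character(0)
  for (cl in sort(unique(patients$label))) {
    ids <- patients$patient_id[patients$label == cl]
    n_test <- ceiling(test_fraction * length(ids))
    test <- c(test, sample(ids, n_test))
  }
  list(train = setdiff(patients$patient_id, test), test = test)
}

#' Fit z-score standardization parameters on training data
#'
#' @param features Training feature matrix/data frame.
#' @return Object of class `standardizer` holding per-feature means and
#'   standard deviations; zero-variance features are flagged and passed
#'   through unscaled.
#' @export
fit_standardizer <- function(features) {
  X <- as.matrix(tibble::as_tibble(features))
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  flagged <- colnames(X)[sigma == 0]
  sigma[sigma == 0] <- 1
  structure(list(mean = mu, sd = sigma, constant = flagged),
            class = "standardizer")
}

#' Apply retained standardization parameters
#'
#' The training means and standard deviations are re-used verbatim on any
#' later data (in particular the held-out test set), preventing leakage.
#'
#' @param std A [fit_standardizer()] result.
#' @param features Feature data with the same columns.
#' @return A tibble of standardized features.
#' @export
apply_standardizer <- function(std, features) {
  X <- as.matrix(tibble::as_tibble(features))[, names(std$mean), drop = FALSE]
  tibble::as_tibble(sweep(sweep(X, 2, std$mean), 2, std$sd, "/"))
}

#' Minority oversampling by SMOTE or borderline-SMOTE
#'
#' Raises the minority class to the majority count by interpolating between
#' minority neighbours: a synthetic sample is `x + u (x_nn - x)` with
#' `u ~ U(0,1)` and `x_nn` one of the `k` nearest minority neighbours of the
#' seed `x`. The borderline variant restricts seeds to "danger" minority
#' points, those whose `k` nearest neighbours in the full training set are at
#' least half — but not all — majority points; when no danger point exists it
#' falls back to plain SMOTE with a warning. Apply to training data only.
#'
#' Uses the current RNG state.
#'
#' @param features Feature matrix/data frame (training rows).
#' @param labels Binary labels (0/1).
#' @param method `"smote"` or `"borderline"`.
#' @param k Number of neighbours (default 5; reduced automatically when the
#'   minority class is smaller).
#' @return A list with `features` (tibble), `labels` and `n_synthetic`.
#' @export
oversample <- function(features, labels, method = c("smote", "borderline"),
                       k = 5L) {
  method <- match.arg(method)
  X <- as.matrix(tibble::as_tibble(features))
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (tab[1] == tab[2]) {
    return(list(features = tibble::as_tibble(X), labels = labels, n_synthetic = 0L))
  }
  minority <- as.integer(names(which.min(tab)))
  n_needed <- abs(diff(as.integer(tab)))
  min_idx <- which(labels == minority)
  if (length(min_idx) < 2L) {
    warn("Minority class too small to oversample; returning input unchanged.")
    return(list(features = tibble::as_tibble(X), labels = labels, n_synthetic = 0L))
  }
  k_eff <- min(k, length(min_idx) - 1L)
  Xmin <- X[min_idx, , drop = FALSE]
  seeds_pool <- seq_along(min_idx)
  if (method == "borderline") {
    k_all <- min(k, nrow(X) - 1L)
    nn_all <- FNN::get.knnx(X, Xmin, k = k_all + 1L)$nn.index
    danger <- vapply(seq_along(min_idx), function(i) {
      nb <- setdiff(nn_all[i, ], min_idx[i])[seq_len(k_all)]
      m_maj <- sum(labels[nb] != minority)
      m_maj >= k_all / 2 && m_maj < k_all
    }, logical(1))
    if (!any(danger)) {
      warn("No borderline (danger) minority points; falling back to plain SMOTE.")
    } else {
      seeds_pool <- which(danger)
    }
  }
  nn_min <- FNN::get.knn(Xmin, k = k_eff)$nn.index
  seed_pick <- sample(seeds_pool, n_needed, replace = TRUE)
  synth <- matrix(unlist(lapply(seed_pick, function(i) {
    j <- nn_min[i, sample.int(k_eff, 1)]
    u <- runif(1)
    Xmin[i, ] + u * (Xmin[j, ] - Xmin[i, ])
  })), ncol = ncol(X), byrow = TRUE,
  dimnames = list(NULL, colnames(X)))
  list(
    features = tibble::as_tibble(rbind(X, synth)),
    labels = c(labels, rep(minority, n_needed)),
    n_synthetic = n_needed
  )
}

# Internal: stratified, optionally group-aware fold assignment. Groups
# (patients) never straddle folds; stratification is by group label.
make_folds <- function(labels, n_folds, groups = NULL) {
  if (is.null(groups)) groups <- seq_along(labels)
  gdf <- dplyr::distinct(tibble::tibble(group = groups, label = labels))
  fold_of <- integer(0)
  names_of <- character(0)
  for (cl in unique(gdf$label)) {
    g <- sample(gdf$group[gdf$label == cl])
    fold_of <- c(fold_of, rep_len(seq_len(n_folds), length(g)))
    names_of <- c(names_of, as.character(g))
  }
  unname(setNames(fold_of, names_of)[as.character(groups)])
}

# Internal model registry ----------------------------------------------------

default_params <- function(model) {
  switch(model,
    knn = list(k = 5L),
    lr = list(),
    nb = list(laplace = 0),
    svm = list(cost = 1, gamma = NULL, kernel = "radial"),
    rf = list(ntree = 300L, mtry_frac = NULL, nodesize = 1L),
    xgb = list(nrounds = 100L, max_depth = 3L, eta = 0.1, subsample = 1),
    stop_nucleograde(
      sprintf("Unknown model '%s'. Supported: knn, lr, nb, svm, rf, xgb.", model),
      "nucleograde_parameter_error")
  )
}

merge_params <- function(model, params) {
  utils::modifyList(default_params(model), params %||% list())
}

# Internal: fit on (Xtr, ytr), return class-1 probabilities for Xte.
fit_predict_model <- function(model, Xtr, ytr, Xte, params = list()) {
  p <- merge_params(model, params)
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  ytr <- as.integer(ytr)
  switch(model,
    knn = {
      k <- min(p$k, nrow(Xtr))
      pred <- class::knn(Xtr, Xte, factor(ytr, levels = c(0L, 1L)),
                         k = k, prob = TRUE)
      pv <- attr(pred, "prob")
      ifelse(pred == "1", pv, 1 - pv)
    },
    lr = {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Xtr), ytr,
                                             family = binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      as.numeric(plogis(cbind(1, Xte) %*% beta))
    },
    nb = {
      fit <- e1071::naiveBayes(as.data.frame(Xtr), factor(ytr, levels = c(0L, 1L)),
                               laplace = p$laplace)
      predict(fit, as.data.frame(Xte), type = "raw")[, "1"]
    },
    svm = {
      gamma <- p$gamma %||% (1 / ncol(Xtr))
      fit <- e1071::svm(Xtr, factor(ytr, levels = c(0L, 1L)),
                        kernel = p$kernel, cost = p$cost, gamma = gamma,
                        probability = TRUE)
      pr <- predict(fit, Xte, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = {
      mtry <- if (is.null(p$mtry_frac)) max(1L, floor(sqrt(ncol(Xtr)))) else
        max(1L, round(p$mtry_frac * ncol(Xtr)))
      fit <- randomForest::randomForest(
        Xtr, factor(ytr, levels = c(0L, 1L)),
        ntree = p$ntree, mtry = min(mtry, ncol(Xtr)), nodesize = p$nodesize)
      predict(fit, Xte, type = "prob")[, "1"]
    },
    xgb = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = p$max_depth,
                      eta = p$eta, subsample = p$subsample, nthread = 1),
        data = xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1),
        nrounds = p$nrounds, verbose = 0)
      predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1))
    },
    stop_nucleograde(
      sprintf("Unknown model '%s'. Supported: knn, lr, nb, svm, rf, xgb.", model),
      "nucleograde_parameter_error")
  )
}

# Internal: mean held-out AUC over pre-built folds, oversampling each
# training fold once (all candidate columns) so feature subsets index into a
# fixed balanced design.
cv_auc_subset <- function(fold_data, subset, model, params) {
  aucs <- vapply(fold_data, function(fd) {
    probs <- fit_predict_model(model, fd$Xb[, subset, drop = FALSE], fd$yb,
                               fd$Xte[, subset, drop = FALSE], params)
    if (length(unique(fd$yte)) < 2L) return(NA_real_)
    auc_rank(probs, fd$yte)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

build_fold_data <- function(X, y, fold_id, oversample_method, k_smote = 5L) {
  lapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f; te <- fold_id == f
    ov <- if (is.null(oversample_method)) {
      list(features = X[tr, , drop = FALSE], labels = y[tr])
    } else {
      oversample(X[tr, , drop = FALSE], y[tr], method = oversample_method,
                 k = k_smote)
    }
    list(Xb = as.matrix(ov$features), yb = ov$labels,
         Xte = as.matrix(X[te, , drop = FALSE]), yte = y[te])
  })
}

#' Repeated sequential forward feature selection with modal-subset voting
#'
#' Runs plain sequential forward selection `iterations` times, each with
#' fresh cross-validation folds: starting from the empty set, the feature
#' whose addition maximizes mean CV AUC is added until the subset cap is
#' reached or no addition improves the AUC. The most discriminant subset is
#' the most frequently occurring exact subset across iterations (ties broken
#' by higher mean AUC, then lexicographic order). Class imbalance is
#' corrected inside each training fold only.
#'
#' @param features Standardized training feature data (rows = sections or
#'   patients).
#' @param labels Binary training labels aligned with rows.
#' @param model Model key (`"knn"`, `"lr"`, `"nb"`, `"svm"`, `"rf"`, `"xgb"`).
#' @param groups Optional grouping vector (patient ids for section-level
#'   rows); groups never straddle CV folds.
#' @param iterations Number of selection repetitions (default 100).
#' @param folds CV folds per repetition (default 10).
#' @param cap Maximum subset size (default 10, the 10:1 rule).
#' @param params Model hyperparameters (see [train_model()]).
#' @param oversample_method `"smote"`, `"borderline"` or `NULL` to disable.
#' @param floating If `TRUE`, each forward step is followed by conditional
#'   backward removals (floating variant); default plain forward.
#' @param seed Integer seed.
#' @return An object of class `selection_result`: tibble of per-iteration
#'   subsets, the modal subset, its frequency and AUC traces.
#' @export
sffs_select <- function(features, labels, model = "lr", groups = NULL,
                        iterations = 100L, folds = 10L, cap = 10L,
                        params = list(), oversample_method = "smote",
                        floating = FALSE, seed = 1L) {
  if (cap < 1L) {
    stop_nucleograde("`cap` must be >= 1.", "nucleograde_parameter_error")
  }
  X <- tibble::as_tibble(features)
  y <- as.integer(labels)
  feat_names <- names(X)
  runs <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    set.seed(derive_seed(seed, it))
    fold_id <- make_folds(y, folds, groups)
    fd <- build_fold_data(X, y, fold_id, oversample_method)
    selected <- character(0)
    best_auc <- -Inf
    repeat {
      remaining <- setdiff(feat_names, selected)
      if (length(selected) >= cap || length(remaining) == 0L) break
      cand_auc <- vapply(remaining, function(f) {
        cv_auc_subset(fd, c(selected, f), model, params)
      }, numeric(1))
      best_i <- which.max(cand_auc)
      if (cand_auc[best_i] <= best_auc) break
      selected <- c(selected, remaining[best_i])
      best_auc <- cand_auc[best_i]
      if (floating && length(selected) > 2L) {
        repeat {
          drop_auc <- vapply(selected, function(f) {
            cv_auc_subset(fd, setdiff(selected, f), model, params)
          }, numeric(1))
          best_d <- which.max(drop_auc)
          if (drop_auc[best_d] > best_auc) {
            selected <- setdiff(selected, selected[best_d])
            best_auc <- drop_auc[best_d]
          } else break
        }
      }
    }
    runs[[it]] <- tibble::tibble(
      iteration = it,
      subset = paste(sort(selected), collapse = "|"),
      size = length(selected),
      cv_auc = best_auc
    )
  }
  runs <- dplyr::bind_rows(runs)
  tally <- runs |>
    dplyr::group_by(.data$subset) |>
    dplyr::summarise(frequency = dplyr::n(), mean_auc = mean(.data$cv_auc),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frequency), dplyr::desc(.data$mean_auc),
                   .data$subset)
  modal <- strsplit(tally$subset[1], "|", fixed = TRUE)[[1]]
  structure(
    list(runs = runs, tally = tally, modal_subset = modal,
         modal_frequency = tally$frequency[1], model = model,
         iterations = iterations),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> model %s: modal subset (f = %d/%d):\n  %s\n",
              x$model, x$modal_frequency, x$iterations,
              paste(x$modal_subset, collapse = ", ")))
  invisible(x)
}

#' Default randomized-search spaces per model
#'
#' Conventional hyperparameter ranges for each supported classifier;
#' logistic regression has no tunable hyperparameter and an empty space.
#'
#' @param model Model key.
#' @return Named list of candidate value vectors.
#' @export
default_search_space <- function(model) {
  switch(model,
    knn = list(k = seq(1L, 25L, by = 2L)),
    lr = list(),
    nb = list(laplace = c(0, 0.5, 1)),
    svm = list(cost = 10^seq(-2, 2), gamma = 10^seq(-3, 1),
               kernel = c("radial", "linear")),
    rf = list(ntree = c(100L, 300L, 500L), mtry_frac = c(0.2, 0.4, 0.6, 0.8),
              nodesize = c(1L, 5L, 10L)),
    xgb = list(nrounds = c(50L, 100L, 200L), max_depth = 2:6,
               eta = c(0.05, 0.1, 0.3), subsample = c(0.6, 0.8, 1)),
    stop_nucleograde(
      sprintf("Unknown model '%s'. Supported: knn, lr, nb, svm, rf, xgb.", model),
      "nucleograde_parameter_error")
  )
}

#' Randomized hyperparameter search under cross-validated AUC
#'
#' Samples `iterations` configurations uniformly from the search space and
#' returns the one maximizing mean k-fold CV AUC (oversampling applied inside
#' training folds). With an empty space the model defaults are returned with
#' a warning.
#'
#' @inheritParams sffs_select
#' @param space Named list of candidate vectors; defaults to
#'   [default_search_space()].
#' @return A list with `best_params`, `best_auc` and the full `trace` tibble.
#' @export
random_search <- function(features, labels, model = "lr", groups = NULL,
                          space = default_search_space(model),
                          iterations = 100L, folds = 10L,
                          oversample_method = "smote", seed = 1L) {
  X <- tibble::as_tibble(features)
  y <- as.integer(labels)
  if (length(space) == 0L) {
    warn(sprintf("Empty search space for model '%s'; returning defaults.", model))
    return(list(best_params = default_params(model), best_auc = NA_real_,
                trace = tibble::tibble()))
  }
  set.seed(derive_seed(seed, 0L))
  fold_id <- make_folds(y, folds, groups)
  fd <- build_fold_data(X, y, fold_id, oversample_method)
  cols <- names(X)
  trace <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    set.seed(derive_seed(seed, it))
    cfg <- lapply(space, function(v) v[[sample.int(length(v), 1)]])
    auc <- cv_auc_subset(fd, cols, model, cfg)
    trace[[it]] <- tibble::tibble(iteration = it,
                                  config = list(cfg), cv_auc = auc)
  }
  trace <- dplyr::bind_rows(trace)
  best <- which.max(trace$cv_auc)
  list(best_params = trace$config[[best]], best_auc = trace$cv_auc[best],
       trace = trace)
}

#' Train a grade classifier on selected features
#'
#' @param features Standardized training features.
#' @param labels Binary training labels.
#' @param model Model key; Naive Bayes is rejected for clinical feature sets
#'   (mixed continuous/ordinal inputs violate its assumptions there).
#' @param selected Feature names to use (default all).
#' @param params Hyperparameters (e.g. from [random_search()]).
#' @param feature_set `"spatial"` or `"clinical"` (controls the Naive Bayes
#'   exclusion).
#' @return An object of class `grade_model`; use [predict.grade_model()] for
#'   class-1 (G3) probabilities.
#' @export
train_model <- function(features, labels, model = "lr",
                        selected = NULL, params = list(),
                        feature_set = c("spatial", "clinical")) {
  feature_set <- match.arg(feature_set)
  if (model == "nb" && feature_set == "clinical") {
    stop_nucleograde(
      "Naive Bayes is excluded from clinical feature sets (mixed continuous/ordinal inputs).",
      "nucleograde_parameter_error")
  }
  X <- tibble::as_tibble(features)
  selected <- selected %||% names(X)
  X <- X[, selected, drop = FALSE]
  structure(
    list(model = model, selected = selected, params = merge_params(model, params),
         X = as.matrix(X), y = as.integer(labels), feature_set = feature_set),
    class = "grade_model"
  )
}

#' Predict G3 probabilities from a trained grade model
#'
#' @param object A [train_model()] result.
#' @param newdata Feature data containing the selected columns.
#' @param ... Unused.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict.grade_model <- function(object, newdata, ...) {
  Xte <- as.matrix(tibble::as_tibble(newdata)[, object$selected, drop = FALSE])
  unname(fit_predict_model(object$model, object$X, object$y, Xte, object$params))
}

#' @export
print.grade_model <- function(x, ...) {
  cat(sprintf("<grade_model> %s (%s features): %s\n", x$model, x$feature_set,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Diagnostic metric panel from a confusion table
#'
#' @param tp,fn,tn,fp Confusion counts at the decision threshold.
#' @param auc Optional AUC to attach.
#' @return A `metric_panel` (one-row tibble subclass) with AUC, ACC, Sn, Sp,
#'   Prev, FNR, FPR, PPV, NPV, FDR, FOR (percent scale), LR+, LR-, DOR and
#'   f1 (0-1 scale), satisfying the usual identities
#'   (Sn + FNR = 100, LR+ = Sn/(100-Sp), DOR = LR+/LR-, ...).
#' @export
metric_panel <- function(tp, fn, tn, fp, auc = NA_real_) {
  sn <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  ppv <- 100 * tp / (tp + fp)
  npv <- 100 * tn / (tn + fn)
  panel <- tibble::tibble(
    AUC = auc,
    ACC = 100 * (tp + tn) / (tp + tn + fp + fn),
    Sn = sn, Sp = sp,
    Prev = 100 * (tp + fn) / (tp + tn + fp + fn),
    FNR = 100 - sn, FPR = 100 - sp,
    PPV = ppv, NPV = npv,
    FDR = 100 - ppv, FOR = 100 - npv,
    LR_plus = sn / (100 - sp),
    LR_minus = (100 - sn) / sp,
    DOR = (sn / (100 - sp)) / ((100 - sn) / sp),
    f1 = 2 * ppv * sn / (ppv + sn) / 100,
    TP = tp, FN = fn, TN = tn, FP = fp
  )
  class(panel) <- c("metric_panel", class(panel))
  panel
}

#' Evaluate patient-level probabilities against grade labels
#'
#' Binarizes at the threshold (predicted G3 when probability >= threshold),
#' forms the confusion table, and returns the extended diagnostic panel with
#' the rank-method AUC.
#'
#' @param probs Class-1 probabilities in \[0, 1\].
#' @param labels Binary labels (1 = G3).
#' @param threshold Decision threshold (default 0.5).
#' @return A [metric_panel()].
#' @export
evaluate <- function(probs, labels, threshold = 0.5) {
  assert_probability(probs, "probs")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop_nucleograde("AUC undefined: need both classes.",
                     "nucleograde_parameter_error")
  }
  pred <- as.integer(probs >= threshold)
  metric_panel(
    tp = sum(pred == 1L & labels == 1L),
    fn = sum(pred == 0L & labels == 1L),
    tn = sum(pred == 0L & labels == 0L),
    fp = sum(pred == 1L & labels == 0L),
    auc = auc_rank(probs, labels)
  )
}
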