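test_that("rank AUC matches the pROC oracle including ties", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.5)
    p <- round(runif(60), 2) # force ties
    if (length(unique(y)) < 2) next
    oracle <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                             direction = "<")))
    expect_equal(auc_rank(p, y), oracle, tolerance = 1e-12)
  }
  expect_error(auc_rank(runif(5), rep(1, 5)),
               class = "nucleograde_parameter_error")
})

test_that("collinearity pruning keeps the feature closest to the outcome", {
  set.seed(8)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  a <- y + rnorm(n, sd = 0.5)        # correlated with outcome
  b <- a + rnorm(n, sd = 0.4)        # collinear with a, attenuated vs outcome
  noise <- rnorm(n)
  stopifnot(cor(a, b)^2 > 0.7, abs(cor(a, y)) > abs(cor(b, y)))
  pr <- prune_collinear(tibble::tibble(a = a, b = b, noise = noise), y)
  expect_setequal(pr$retained, c("a", "noise"))
  expect_equal(pr$dropped$dropped, "b")
  expect_equal(pr$dropped$kept, "a")

  # duplicated column: exactly one copy survives
  pr2 <- prune_collinear(tibble::tibble(f = a, f_copy = a), y)
  expect_length(pr2$retained, 1)

  # nothing collinear: identity
  set.seed(9)
  X <- tibble::as_tibble(matrix(rnorm(300), 100,
                                dimnames = list(NULL, c("u", "v", "w"))))
  pr3 <- prune_collinear(X, rbinom(100, 1, 0.5))
  expect_setequal(pr3$retained, c("u", "v", "w"))
  expect_equal(nrow(pr3$dropped), 0)
})

test_that("patient-level split follows the per-class ceiling rule", {
  pts <- tibble::tibble(patient_id = sprintf("P%03d", 1:138),
                        label = rep(c(1L, 0L), c(80, 58)))
  sp <- split_cohort(pts, 0.30, seed = 1)
  expect_length(sp$test, 42) # ceil(.3*80)=24 G3 + ceil(.3*58)=18
  test_labels <- pts$label[match(sp$test, pts$patient_id)]
  expect_equal(sum(test_labels == 1L), 24)
  expect_equal(100 * mean(test_labels == 1L), 57.14, tolerance = 1e-3)
  # partition contract for any seed
  for (s in 1:3) {
    spx <- split_cohort(pts, 0.30, seed = s)
    expect_length(intersect(spx$train, spx$test), 0)
    expect_setequal(c(spx$train, spx$test), pts$patient_id)
  }
  sp2 <- split_cohort(tibble::tibble(patient_id = letters[1:4],
                                     label = c(0, 0, 1, 1)), 0.5, seed = 2)
  expect_length(sp2$test, 2)
  expect_error(split_cohort(tibble::tibble(patient_id = "a", label = 1), 0.3),
               class = "nucleograde_parameter_error")
})

test_that("standardization parameters fitted on training data transfer", {
  set.seed(10)
  X <- tibble::tibble(a = rnorm(50, 5, 2), b = runif(50, 0, 100))
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  expect_equal(colMeans(as.matrix(Z)), c(a = 0, b = 0), tolerance = 1e-12)
  Xnew <- tibble::tibble(a = rnorm(20, 5, 2), b = runif(20, 0, 100))
  Znew <- apply_standardizer(std, Xnew)
  expect_equal(as.matrix(Znew),
               sweep(sweep(as.matrix(Xnew), 2, std$mean), 2, std$sd, "/"),
               ignore_attr = TRUE)
})

test_that("SMOTE balances classes with synthetics on minority segments", {
  set.seed(5)
  # already balanced: unchanged
  Xb <- tibble::tibble(f1 = rnorm(20), f2 = rnorm(20))
  yb <- rep(c(0L, 1L), each = 10)
  ovb <- oversample(Xb, yb)
  expect_equal(ovb$n_synthetic, 0L)
  expect_identical(ovb$labels, yb)

  # two-point minority with k = 1: synthetics lie on the segment
  Xm <- tibble::tibble(
    f1 = c(0, 1, 5, 6, 7, 8, 9, 10),
    f2 = c(0, 1, 5, 6, 7, 8, 9, 10))
  ym <- c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  ov <- oversample(Xm, ym, k = 1L)
  expect_equal(sum(ov$labels == 1L), sum(ov$labels == 0L))
  synth <- as.matrix(ov$features)[-(1:8), , drop = FALSE]
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 1))
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12) # on the diagonal

  # the paper's 58/80 imbalance is raised to 80/80
  set.seed(6)
  Ximb <- tibble::as_tibble(matrix(rnorm(138 * 3), 138,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  yimb <- rep(c(1L, 0L), c(80, 58))
  ov2 <- oversample(Ximb, yimb)
  expect_equal(as.integer(table(ov2$labels)), c(80L, 80L))
})

test_that("borderline SMOTE seeds only danger points and falls back cleanly", {
  set.seed(14)
  # minority cluster far from majority: no danger points -> fallback warning
  Xfar <- tibble::tibble(f1 = c(rnorm(6, 0, 0.1), rnorm(20, 10, 0.1)),
                         f2 = c(rnorm(6, 0, 0.1), rnorm(20, 10, 0.1)))
  yfar <- rep(c(1L, 0L), c(6, 20))
  expect_warning(ovf <- oversample(Xfar, yfar, method = "borderline", k = 3L),
                 "danger")
  expect_equal(sum(ovf$labels == 1L), 20)

  # overlapping classes: borderline succeeds without warning
  set.seed(15)
  Xov <- tibble::tibble(f1 = c(rnorm(15, 0), rnorm(40, 1)),
                        f2 = c(rnorm(15, 0), rnorm(40, 1)))
  yov <- rep(c(1L, 0L), c(15, 40))
  expect_no_warning(ov <- oversample(Xov, yov, method = "borderline"))
  expect_equal(sum(ov$labels == 1L), 40)
})

test_that("metric panel identities hold to 1e-9 on random confusion tables", {
  set.seed(20)
  for (i in 1:25) {
    counts <- sample(1:50, 4, replace = TRUE)
    p <- metric_panel(counts[1], counts[2], counts[3], counts[4])
    expect_equal(p$Sn + p$FNR, 100, tolerance = 1e-9)
    expect_equal(p$Sp + p$FPR, 100, tolerance = 1e-9)
    expect_equal(p$PPV + p$FDR, 100, tolerance = 1e-9)
    expect_equal(p$NPV + p$FOR, 100, tolerance = 1e-9)
    expect_equal(p$LR_plus, p$Sn / (100 - p$Sp), tolerance = 1e-9)
    expect_equal(p$LR_minus, (100 - p$Sn) / p$Sp, tolerance = 1e-9)
    expect_equal(p$DOR, p$LR_plus / p$LR_minus, tolerance = 1e-9)
    expect_equal(p$f1, 2 * p$PPV * p$Sn / (p$PPV + p$Sn) / 100,
                 tolerance = 1e-9)
  }
})

test_that("the published confusion-consistent metric rows are reproduced", {
  # clinical LR row: Sn 75.00, Sp 72.22 from TP=18 FN=6 TN=13 FP=5
  p <- metric_panel(tp = 18, fn = 6, tn = 13, fp = 5)
  expect_equal(p$Sn, 75, tolerance = 5e-3)
  expect_equal(p$Sp, 72.22, tolerance = 5e-3)
  expect_equal(p$PPV, 78.26, tolerance = 5e-3)
  expect_equal(p$ACC, 73.81, tolerance = 5e-3)
  expect_equal(p$LR_plus, 2.70, tolerance = 5e-3)
  expect_equal(p$LR_minus, 0.35, tolerance = 2e-2)
  expect_equal(p$DOR, 7.80, tolerance = 5e-3)
  expect_equal(p$f1, 0.77, tolerance = 1e-2)
  # clinical K-NN row: Sn 75.00 / Sp 50.00
  q <- metric_panel(tp = 18, fn = 6, tn = 9, fp = 9)
  expect_equal(q$LR_plus, 1.50, tolerance = 1e-9)
  expect_equal(q$LR_minus, 0.50, tolerance = 1e-9)
  expect_equal(q$DOR, 3.00, tolerance = 1e-9)
  expect_equal(q$Prev, 57.14, tolerance = 5e-3)
})

test_that("evaluate() produces a perfect panel under perfect separation", {
  y <- rep(c(0L, 1L), each = 10)
  p <- c(runif(10, 0, 0.3), runif(10, 0.7, 1))
  panel <- evaluate(p, y)
  expect_equal(panel$AUC, 1)
  expect_equal(panel$FNR, 0)
  expect_equal(panel$FPR, 0)
  expect_equal(panel$ACC, 100)
  expect_error(evaluate(p, rep(1L, 20)), class = "nucleograde_parameter_error")
})

test_that("SFFS recovers a strong predictor and respects the cap", {
  set.seed(30)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  X <- tibble::as_tibble(matrix(rnorm(n * 6), n,
                                dimnames = list(NULL, paste0("noise", 1:6))))
  X$signal <- y * 2 + rnorm(n, sd = 0.7)
  sel <- sffs_select(X, y, model = "lr", iterations = 20L, folds = 5L,
                     cap = 3L, seed = 1L)
  hits <- vapply(strsplit(sel$runs$subset, "|", fixed = TRUE),
                 function(s) "signal" %in% s, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_true("signal" %in% sel$modal_subset)
  expect_true(all(sel$runs$size <= 3))
  expect_error(sffs_select(X, y, cap = 0L), class = "nucleograde_parameter_error")
})

test_that("SFFS on pure noise stays near chance on held-out data", {
  set.seed(31)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  X <- tibble::as_tibble(matrix(rnorm(n * 8), n,
                                dimnames = list(NULL, paste0("n", 1:8))))
  sel <- sffs_select(X, y, model = "lr", iterations = 10L, folds = 5L,
                     cap = 5L, seed = 2L)
  expect_lt(max(sel$runs$cv_auc), 0.75) # CV AUC stays unimpressive
  # held-out: train on half with the modal subset, test the other half
  set.seed(32)
  Xte <- tibble::as_tibble(matrix(rnorm(n * 8), n,
                                  dimnames = list(NULL, paste0("n", 1:8))))
  mod <- train_model(X[, sel$modal_subset, drop = FALSE], y, "lr")
  auc <- auc_rank(predict(mod, Xte[, sel$modal_subset, drop = FALSE]), y)
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})

test_that("SFFS is deterministic for a fixed seed", {
  set.seed(33)
  X <- tibble::as_tibble(matrix(rnorm(60 * 4), 60,
                                dimnames = list(NULL, paste0("f", 1:4))))
  y <- rbinom(60, 1, 0.5)
  s1 <- sffs_select(X, y, iterations = 5L, folds = 4L, seed = 7L)
  s2 <- sffs_select(X, y, iterations = 5L, folds = 4L, seed = 7L)
  expect_identical(s1$runs, s2$runs)
})

test_that("randomized search selects within the space and is deterministic", {
  set.seed(40)
  n <- 100
  y <- rep(c(0L, 1L), each = n / 2)
  X <- tibble::tibble(f1 = y + rnorm(n), f2 = rnorm(n))
  # single-point space: that point returned
  rs1 <- random_search(X, y, model = "knn", space = list(k = 7L),
                       iterations = 5L, folds = 4L, seed = 1L)
  expect_equal(rs1$best_params$k, 7L)
  # empty space: defaults with warning
  expect_warning(rs0 <- random_search(X, y, model = "lr", iterations = 3L),
                 "Empty search space")
  expect_equal(rs0$best_params, list())
  # determinism
  rs2 <- random_search(X, y, model = "knn", iterations = 10L, folds = 4L,
                       seed = 3L)
  rs3 <- random_search(X, y, model = "knn", iterations = 10L, folds = 4L,
                       seed = 3L)
  expect_identical(rs2$best_params, rs3$best_params)
  # tuned configuration beats or matches a deliberately poor default
  expect_gte(rs2$best_auc, 0.5)
})

test_that("all six classifiers emit probabilities and honour exclusions", {
  set.seed(50)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  X <- tibble::tibble(f1 = y * 3 + rnorm(n), f2 = rnorm(n))
  for (m in c("knn", "lr", "nb", "svm", "rf", "xgb")) {
    mod <- train_model(X, y, model = m, feature_set = "spatial")
    p <- predict(mod, X)
    expect_length(p, n)
    expect_true(all(p >= 0 & p <= 1), info = m)
    expect_gt(auc_rank(p, y), 0.8) # strongly separable training data
  }
  expect_error(train_model(X, y, model = "nb", feature_set = "clinical"),
               "clinical")
  expect_error(train_model(X, y, model = "mystery"),
               class = "nucleograde_parameter_error")
})

test_that("logistic regression degenerates to the class prior on constant input", {
  y <- rep(c(0L, 1L), c(30, 70))
  X <- tibble::tibble(f1 = rep(1, 100))
  mod <- train_model(X, y, model = "lr")
  p <- predict(mod, X)
  expect_equal(unique(round(p, 10)), 0.7)
})

test_that("perfectly separable data is fit perfectly by logistic regression", {
  X <- tibble::tibble(f1 = c(1:10, 21:30))
  y <- rep(c(0L, 1L), each = 10)
  mod <- train_model(X, y, model = "lr")
  expect_equal(as.integer(predict(mod, X) >= 0.5), y)
})

test_that("grouped CV folds never split a patient across folds", {
  set.seed(60)
  groups <- rep(sprintf("P%02d", 1:20), each = 3)
  labels <- rep(rbinom(20, 1, 0.5), each = 3)
  fold <- nucleograde:::make_folds(labels, 5L, groups)
  expect_true(all(tapply(fold, groups, function(f) length(unique(f))) == 1))
})
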