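test_that("subject half-splits are disjoint and balanced", {
  tab <- toy_feature_table(n_subjects = 4)
  sp <- subject_half_split(tab, seed = 1)
  expect_length(sp$train, 2)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)

  tab32 <- toy_feature_table(n_subjects = 64)
  sp32 <- subject_half_split(tab32, seed = 2)
  expect_length(sp32$train, 32)
  expect_length(sp32$test, 32)
  lab <- tab32$label[match(sp32$train, tab32$subject_id)]
  expect_equal(sum(lab == "anesthesia"), 16)

  # odd subject counts put the extra subject in training
  tab10 <- toy_feature_table(n_subjects = 10)
  tab10 <- tab10[tab10$subject_id != "S01", ]
  expect_message(sp10 <- subject_half_split(tab10, seed = 3), "odd")
  expect_length(sp10$train, 5)
  expect_length(sp10$test, 4)
})

test_that("grouped cross-validation never mixes a subject across folds", {
  tab <- toy_feature_table(n_subjects = 20)
  cv <- grouped_kfold_cv(tab, c("f1", "f2"), "knn",
                         list(k = 3), folds = 5, seed = 4)
  expect_length(cv$fold_assign, 20)
  # each subject maps to exactly one fold by construction; check the
  # row-level partition explicitly
  fold_of_row <- cv$fold_assign[tab$subject_id]
  for (s in unique(tab$subject_id)) {
    expect_length(unique(fold_of_row[tab$subject_id == s]), 1)
  }
})

test_that("cross-validation error reflects separability", {
  sep <- toy_feature_table(n_subjects = 20, spread = 8, seed = 6)
  cv <- grouped_kfold_cv(sep, c("f1", "f2"), "knn", list(k = 1),
                         folds = 5, seed = 5)
  expect_equal(cv$error, 0)

  # label-permuted data scores at chance
  null_tab <- toy_feature_table(n_subjects = 20, spread = 0, seed = 7)
  cv0 <- grouped_kfold_cv(null_tab, c("f1", "f2"), "knn", list(k = 5),
                          folds = 5, seed = 8)
  expect_gt(cv0$error, 0.4)
  expect_lt(cv0$error, 0.6)

  cv_rep <- grouped_kfold_cv(sep, c("f1", "f2"), "knn", list(k = 1),
                             folds = 5, seed = 5)
  expect_identical(cv$fold_assign, cv_rep$fold_assign)
  expect_identical(cv$error, cv_rep$error)

  expect_error(grouped_kfold_cv(toy_feature_table(n_subjects = 4),
                                c("f1"), "knn", list(k = 1), folds = 10,
                                seed = 1),
               "fewer folds")
})

test_that("confusion metrics match hand-computed values", {
  perfect <- confusion_metrics(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5))
  expect_equal(perfect$error_rate, 0)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$cohen_kappa, 1)

  m <- confusion_metrics(rep(c(1, 0), c(10, 10)),
                         rep(c(1, 0, 1, 0), c(8, 2, 1, 9)))
  expect_equal(m$tp, 8); expect_equal(m$fn, 2)
  expect_equal(m$fp, 1); expect_equal(m$tn, 9)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$error_rate, 0.15)
  expect_equal(m$cohen_kappa, 0.7)
  expect_equal(m$false_positive_rate, 0.1)
  expect_equal(m$error_rate + m$accuracy, 1)
  expect_equal(m$false_positive_rate + m$specificity, 1)

  # all-one-class predictions on balanced truth agree only by chance
  chance <- confusion_metrics(rep(c(1, 0), each = 10), rep(1, 20))
  expect_equal(chance$cohen_kappa, 0)
  # no positive predictions: precision is missing, not zero
  nopos <- confusion_metrics(rep(c(1, 0), each = 5), rep(0, 10))
  expect_true(is.na(nopos$precision))
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
})

test_that("ROC/AUC matches closed-form and Mann-Whitney values", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  flat <- roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(flat$auc, 0.5)
  hand <- roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(hand$auc, 0.75)
  expect_true(all(diff(hand$roc$fpr) >= 0))
  expect_true(all(diff(hand$roc$tpr) >= 0))
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("the optimizer handles degenerate and mock objectives", {
  single <- list(k = list(type = "cat", values = "only"))
  res <- optimize_hyperparams(space = single, family = "knn",
                              iterations = 1, seed = 1,
                              objective = function(cfg) 0.25)
  expect_equal(res$best_params$k, "only")
  expect_equal(res$best_error, 0.25)
  expect_equal(nrow(res$trace), 1)
  expect_error(optimize_hyperparams(space = single, family = "knn",
                                    iterations = 0, seed = 1,
                                    objective = function(cfg) 0),
               "budget")

  # U-shaped error curve over k: the incumbent lands within 1 of the
  # true minimizer at k = 12
  space <- list(k = list(type = "int", lower = 1, upper = 30))
  curve <- function(cfg) ((cfg$k - 12) / 30)^2
  for (method in c("gp", "random")) {
    res <- optimize_hyperparams(space = space, family = "knn",
                                iterations = 30, seed = 9,
                                method = method, objective = curve)
    expect_lte(abs(res$best_params$k - 12), 1)
  }

  # deterministic trace for a fixed seed
  r1 <- optimize_hyperparams(space = space, family = "knn",
                             iterations = 10, seed = 11, objective = curve)
  r2 <- optimize_hyperparams(space = space, family = "knn",
                             iterations = 10, seed = 11, objective = curve)
  expect_identical(r1$trace, r2$trace)
})

test_that("evaluate_classifier assembles metrics, ROC and predictions", {
  tab <- toy_feature_table(n_subjects = 16, spread = 4, seed = 10)
  sp <- subject_half_split(tab, seed = 12)
  train <- tab[tab$subject_id %in% sp$train, ]
  test <- tab[tab$subject_id %in% sp$test, ]
  m <- knn_fit(as.matrix(train[, c("f1", "f2")]), train$label, k = 3,
               weighting = "inverse")
  ev <- evaluate_classifier(m, test, c("f1", "f2"))
  expect_gte(ev$accuracy, 0.9)
  expect_gte(ev$auc, 0.9)
  expect_equal(ev$n_test, nrow(test))
  expect_equal(nrow(ev$predictions), nrow(test))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(61, {
    for (i in 1:20) {
      y <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(40), 1)
      ours <- roc_auc(s, y)$auc
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, direction = "<",
                                            quiet = TRUE)))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})
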