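#' Split subjects into training and testing halves
#'
#' Subjects (never segments) are split 50/50 within each class, so the
#' two halves share no individual.  With an odd subject count the extra
#' subject goes to the training side.
#'
#' @param table feature table with `subject_id` and `label` columns.
#' @param seed integer seed for the shuffle.
#' @return an object of class `ppg_split` with `train` and `test`
#'   subject-id vectors and a per-class count table.
#' @export
subject_half_split <- function(table, seed = 1L) {
  stopifnot(all(c("subject_id", "label") %in% names(table)))
  subj <- unique(table[, c("subject_id", "label")])
  y <- as_anes_label(subj$label)
  if (any(table(y) < 2)) stop("need at least 2 subjects per class")
  withr::with_seed(derive_seed(seed, "half_split"), {
    train <- character(0); test <- character(0)
    for (cl in levels(y)) {
      ids <- sample(subj$subject_id[y == cl])
      n_train <- ceiling(length(ids) / 2)
      if (length(ids) %% 2 == 1) {
        message("odd subject count in class ", cl,
                "; extra subject assigned to training")
      }
      train <- c(train, ids[seq_len(n_train)])
      test <- c(test, ids[-seq_len(n_train)])
    }
    counts <- table(subject = c(rep("train", length(train)),
                                rep("test", length(test))))
    structure(list(train = train, test = test, counts = counts),
              class = "ppg_split")
  })
}

# Assign subjects to folds, balancing classes: subjects of each class are
# shuffled and dealt round-robin.
.subject_folds <- function(table, folds, seed) {
  subj <- unique(table[, c("subject_id", "label")])
  if (nrow(subj) < folds) {
    stop("fewer subjects (", nrow(subj), ") than folds (", folds,
         "); use fewer folds")
  }
  y <- as_anes_label(subj$label)
  withr::with_seed(derive_seed(seed, "folds"), {
    assign <- integer(nrow(subj))
    offset <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- offset + length(idx)
    }
    setNames(assign, subj$subject_id)
  })
}

# Fit/predict dispatch shared by cross-validation, optimization and the
# pipeline.  `params` is a named list of hyperparameters for the family.
fit_classifier <- function(family, params, X, y) {
  if (family == "knn" && !is.null(params$k)) {
    # a search domain may exceed a small training fold; k saturates at
    # the training size (where KNN degenerates to the global majority)
    params$k <- min(params$k, nrow(X))
  }
  switch(family,
    knn = do.call(knn_fit, c(list(X = X, y = y), params)),
    discriminant = do.call(discriminant_fit, c(list(X = X, y = y), params)),
    svm = do.call(svm_fit, c(list(X = X, y = y), params)),
    stop("unknown classifier family: ", family)
  )
}

#' Subject-grouped k-fold cross-validation error
#'
#' Folds partition subjects, not segments, so no individual contributes
#' to both the training and validation side of any fold.
#'
#' @param table feature table.
#' @param features feature (marker) columns to use.
#' @param family `"knn"`, `"discriminant"`, or `"svm"`.
#' @param params named list of hyperparameters for the family.
#' @param folds number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return list with `error` (mean per-fold misclassification rate),
#'   `fold_errors`, and `fold_assign`.
#' @export
grouped_kfold_cv <- function(table, features, family, params,
                             folds = 10, seed = 1L) {
  stopifnot(all(features %in% names(table)))
  assign <- .subject_folds(table, folds, seed)
  fold_of_row <- assign[table$subject_id]
  y <- as_anes_label(table$label)
  X <- as.matrix(table[, features, drop = FALSE])
  fold_errors <- vapply(seq_len(folds), function(f) {
    tr <- fold_of_row != f; te <- !tr
    if (!any(te)) return(NA_real_)
    if (length(unique(y[tr])) < 2) return(NA_real_)
    model <- fit_classifier(family, params, X[tr, , drop = FALSE], y[tr])
    pred <- predict(model, X[te, , drop = FALSE])
    mean(pred$label != y[te])
  }, numeric(1))
  list(error = mean(fold_errors, na.rm = TRUE),
       fold_errors = fold_errors, fold_assign = assign)
}

#' Confusion matrix and derived metrics
#'
#' Anesthesia is the positive class: TP are anesthesia segments
#' classified as anesthesia.  Precision is reported as `NA` when no
#' positive prediction was made (rather than 0).
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return an object of class `ppg_metrics` with the four cell counts and
#'   `error_rate`, `accuracy`, `sensitivity`, `false_positive_rate`,
#'   `specificity`, `precision`, `cohen_kappa`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as_anes_label(y_true)
  y_pred <- as_anes_label(y_pred)
  if (length(y_true) == 0) stop("empty inputs")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  pos <- "anesthesia"
  tp <- sum(y_true == pos & y_pred == pos)
  fn <- sum(y_true == pos & y_pred != pos)
  fp <- sum(y_true != pos & y_pred == pos)
  tn <- sum(y_true != pos & y_pred != pos)
  n <- tp + fn + fp + tn
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) / n) * ((tp + fn) / n) +
    ((fn + tn) / n) * ((fp + tn) / n)
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn,
         error_rate = (fp + fn) / n, accuracy = p_o,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         false_positive_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         cohen_kappa = kappa),
    class = "ppg_metrics"
  )
}

#' @export
print.ppg_metrics <- function(x, ...) {
  cat(sprintf("confusion (anesthesia positive): TP=%d FN=%d FP=%d TN=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  cat(sprintf(paste0("accuracy=%.3f error=%.3f sensitivity=%.3f FPR=%.3f ",
                     "specificity=%.3f precision=%s kappa=%.3f\n"),
              x$accuracy, x$error_rate, x$sensitivity,
              x$false_positive_rate, x$specificity,
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              x$cohen_kappa))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (predicting
#' positive at score >= threshold) and integrates the resulting
#' (FPR, TPR) staircase by the trapezoid rule.  Tied scores move both
#' rates simultaneously, which makes the trapezoid AUC identical to the
#' normalized Mann-Whitney U statistic with 1/2 credit for ties.
#'
#' @param scores numeric classifier scores (higher = more anesthesia-like).
#' @param y_true true labels.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  y <- as_anes_label(y_true)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- y == "anesthesia"
  n1 <- sum(pos); n0 <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Evaluate a fitted classifier on a test set
#'
#' @param model fitted classifier (`ppg_knn`, `ppg_discriminant`, or
#'   `ppg_svm`).
#' @param table feature table of test segments.
#' @param features feature columns the model was trained on.
#' @return an object of class `ppg_evaluation`: confusion metrics plus
#'   `roc`, `auc`, and the per-segment predictions.
#' @export
evaluate_classifier <- function(model, table, features) {
  X <- as.matrix(table[, features, drop = FALSE])
  y <- as_anes_label(table$label)
  pred <- predict(model, X)
  metrics <- confusion_metrics(y, pred$label)
  roc <- roc_auc(pred$score, y)
  structure(c(unclass(metrics),
              list(auc = roc$auc, roc = roc$roc, predictions = pred,
                   n_test = nrow(table))),
            class = c("ppg_evaluation", "ppg_metrics"))
}

#' @export
print.ppg_evaluation <- function(x, ...) {
  print.ppg_metrics(x)
  cat(sprintf("AUC=%.3f (n=%d segments)\n", x$auc, x$n_test))
  invisible(x)
}
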