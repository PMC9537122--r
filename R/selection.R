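#' Point-biserial correlation
#'
#' Correlation between a continuous variable and a binary one:
#' `r = (M1 - M0) / s_x * sqrt(n1 * n0 / n^2)` with the population
#' standard deviation `s_x`, which is algebraically identical to the
#' Pearson correlation of `x` with the 0/1-coded group variable.
#'
#' @param x numeric vector.
#' @param y binary vector (0/1, logical, or a two-level factor whose
#'   second level is coded 1).
#' @return correlation in `[-1, 1]`.
#' @export
point_biserial <- function(x, y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0); n <- n1 + n0
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  s_x <- sqrt(mean((x - mean(x))^2))
  if (s_x == 0) stop("undefined correlation: x has zero variance")
  (mean(x[y == 1]) - mean(x[y == 0])) / s_x * sqrt(n1 * n0 / n^2)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (delegates to [stats::t.test()]).
#'
#' @param x0,x1 numeric group samples (each of length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x0, x1) {
  if (length(x0) < 2 || length(x1) < 2) {
    stop("each group needs at least 2 observations")
  }
  ht <- t.test(x0, x1, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Select markers by point-biserial correlation
#'
#' Scores every marker column of a feature table against the binary class
#' label; markers with `|r|` above the threshold are selected.  Welch
#' t-tests are reported alongside (no multiple-testing correction is
#' applied).  The default classifier feature set additionally drops any
#' selected marker whose Welch test is non-significant at `p_cut`.
#'
#' @param table a feature table from [extract_features()] (data.frame
#'   with a `label` column and the 13 marker columns).
#' @param threshold selection threshold on `|r|` (default 0.6).
#' @param p_cut Welch-test significance cut for the default classifier
#'   feature set (default 0.05).
#' @return an object of class `ppg_selection` with components `scores`
#'   (data.frame: marker, r, t, df, p), `selected` (|r| > threshold), and
#'   `classifier_features` (selected minus t-test failures).
#' @export
select_features <- function(table, threshold = 0.6, p_cut = 0.05) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  markers <- intersect(marker_names(), names(table))
  if (length(markers) < 2) stop("need at least 2 marker columns")
  y <- as_anes_label(table$label)
  if (length(unique(y)) < 2) stop("both classes must be present")
  y01 <- as.integer(y) - 1L
  scores <- do.call(rbind, lapply(markers, function(m) {
    r <- point_biserial(table[[m]], y01)
    wt <- welch_t(table[[m]][y01 == 0], table[[m]][y01 == 1])
    data.frame(marker = m, r = r, t = wt$t, df = wt$df, p = wt$p)
  }))
  selected <- scores$marker[abs(scores$r) > threshold]
  if (length(selected) == 0) {
    warning("no marker exceeds |r| > ", threshold)
  }
  keep <- scores$p[match(selected, scores$marker)] < p_cut
  structure(
    list(scores = scores, threshold = threshold,
         selected = selected, classifier_features = selected[keep]),
    class = "ppg_selection"
  )
}

#' @export
print.ppg_selection <- function(x, ...) {
  cat("<ppg_selection> |r| threshold:", x$threshold, "\n")
  df <- x$scores
  df$r <- round(df$r, 3); df$t <- round(df$t, 2)
  df$p <- signif(df$p, 3)
  df$selected <- ifelse(df$marker %in% x$selected, "*", "")
  print(df, row.names = FALSE)
  cat("classifier features:", paste(x$classifier_features, collapse = ", "),
      "\n")
  invisible(x)
}
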