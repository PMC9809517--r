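# Ordinal and classical evaluation metrics.
#
# The per-class mean absolute error penalizes misclassification by its
# ordinal distance; the macro average over classes present in the truth
# additionally corrects for class imbalance. Precision/recall/F1 are
# class-size-weighted; R-squared treats grades as numeric scores.

check_pair <- function(y_true, y_pred, k = 4L) {
  if (length(y_true) == 0) stop_input("empty label pair")
  if (length(y_true) != length(y_pred))
    stop_input("y_true and y_pred lengths differ")
  if (any(!y_true %in% 0:(k - 1)) || any(!y_pred %in% 0:(k - 1)))
    stop_input("labels must lie in 0..", k - 1)
  invisible(TRUE)
}

#' Macro-averaged mean absolute error over ordinal grades
#'
#' `MAE_c` is the mean absolute deviation of the predicted from the true
#' grade over the samples whose true grade is `c`; the macro value
#' averages `MAE_c` over classes. By default only classes present in
#' `y_true` enter the average; `strict_k = TRUE` divides by the full class
#' count `k` instead (the literal printed definition).
#'
#' @param y_true,y_pred integer grades in `0..k-1`.
#' @param k number of classes.
#' @param strict_k divide by `k` rather than the number of present classes.
#' @return list of `per_class` (named numeric, `NA` for absent classes),
#'   `macro`, and per-class counts `n_c`.
#' @export
macro_mae <- function(y_true, y_pred, k = 4L, strict_k = FALSE) {
  check_pair(y_true, y_pred, k)
  per <- rep(NA_real_, k)
  n_c <- integer(k)
  for (c in 0:(k - 1)) {
    ix <- y_true == c
    n_c[c + 1] <- sum(ix)
    if (any(ix)) per[c + 1] <- mean(abs(y_true[ix] - y_pred[ix]))
  }
  names(per) <- paste0("class", 0:(k - 1))
  macro <- if (strict_k) sum(per, na.rm = TRUE) / k
           else mean(per, na.rm = TRUE)
  list(per_class = per, macro = macro, n_c = n_c)
}

#' Weighted precision, recall and F1
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their
#' harmonic mean; zero denominators yield 0. Overall values are weighted
#' by the true class sizes `n_c`.
#'
#' @inheritParams macro_mae
#' @return list of per-class vectors `precision`, `recall`, `f1`, counts
#'   `n_c`, and `precision_overall`, `recall_overall`, `f1_overall`
#'   (fractions in \[0,1\]).
#' @export
weighted_prf <- function(y_true, y_pred, k = 4L) {
  check_pair(y_true, y_pred, k)
  P <- R <- F1 <- numeric(k)
  n_c <- integer(k)
  for (c in 0:(k - 1)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    n_c[c + 1] <- sum(y_true == c)
    P[c + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    R[c + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    F1[c + 1] <- if (P[c + 1] + R[c + 1] > 0)
      2 * P[c + 1] * R[c + 1] / (P[c + 1] + R[c + 1]) else 0
  }
  w <- n_c / sum(n_c)
  list(precision = P, recall = R, f1 = F1, n_c = n_c,
       precision_overall = sum(P * w), recall_overall = sum(R * w),
       f1_overall = sum(F1 * w))
}

#' Coefficient of determination on numeric grades
#'
#' `1 - SS_res / SS_tot` with grades treated as numeric scores. Constant
#' truth has no defined value and raises an error.
#'
#' @inheritParams macro_mae
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0)
    stop_input("invalid label pair")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop_input("zero-variance truth: R-squared undefined")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Collapse ordinal grades to a binary task
#'
#' Grade `>= threshold` maps to 1 (the higher-opacity group is the
#' positive class). Thresholds 1, 2, 3 give the three collapses: any
#' opacity vs none, moderate-or-worse vs none/mild, severe vs not severe.
#'
#' @inheritParams macro_mae
#' @param threshold integer in 1..3.
#' @return list of binary `y_true`, `y_pred`.
#' @export
binarize <- function(y_true, y_pred, threshold) {
  if (!threshold %in% 1:3) stop_input("threshold must be 1, 2 or 3")
  check_pair(y_true, y_pred, 4L)
  list(y_true = as.integer(y_true >= threshold),
       y_pred = as.integer(y_pred >= threshold))
}

#' Full metric report for a label pair
#'
#' Bundles macro-MAE, weighted precision/recall/F1 and R-squared; rates
#' are stored as fractions and printed as percentages, matching the usual
#' tabulation.
#'
#' @inheritParams macro_mae
#' @param r2 include R-squared (needs non-constant truth).
#' @return a `metric_report` list.
#' @export
metric_report <- function(y_true, y_pred, k = 4L, strict_k = FALSE,
                          r2 = TRUE) {
  mm <- macro_mae(y_true, y_pred, k, strict_k)
  pr <- weighted_prf(y_true, y_pred, k)
  structure(list(macro_mae = mm$macro, per_class_mae = mm$per_class,
                 precision = pr$precision_overall,
                 recall = pr$recall_overall, f1 = pr$f1_overall,
                 per_class = list(precision = pr$precision,
                                  recall = pr$recall, f1 = pr$f1,
                                  n_c = pr$n_c),
                 r_squared = if (r2 && var(y_true) > 0)
                   r_squared(y_true, y_pred) else NA_real_,
                 n = length(y_true), k = k),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Metrics (n = %d, K = %d): P %.2f%% | R %.2f%% | F1 %.2f%% | MAE %.4f",
    x$n, x$k, 100 * x$precision, 100 * x$recall, 100 * x$f1, x$macro_mae))
  if (!is.na(x$r_squared)) cat(sprintf(" | R2 %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Metric report as a one-row table (Precision, Recall, F1, MAE)
#' @param report a `metric_report`.
#' @export
metric_row <- function(report) {
  data.frame(precision = 100 * report$precision,
             recall = 100 * report$recall, f1 = 100 * report$f1,
             macro_mae = report$macro_mae)
}
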