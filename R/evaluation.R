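#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred equal-length 0/1 vectors; 1 is the positive class.
#' @return list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    validation_error("y_true and y_pred lengths differ")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    validation_error("values must be 0/1")
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0)
  ), class = "confusion_counts")
}

#' Geometric mean of sensitivity and specificity
#'
#' The balanced summary metric for imbalanced classification:
#' `sqrt(sensitivity * specificity)`.
#'
#' @param sensitivity,specificity reals in `[0, 1]`.
#' @return real in `[0, 1]`.
#' @export
g_mean <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    validation_error("sensitivity and specificity must be in [0, 1]")
  sqrt(sensitivity * specificity)
}

#' Threshold metrics plus threshold-free AUROC / AUPRC
#'
#' Thresholds the scores at `threshold` (scores strictly greater predict
#' positive) and reports sensitivity/recall, specificity, precision, F1 and
#' G-mean, alongside AUROC (trapezoid over the ROC step function, with tied
#' scores grouped) and AUPRC (step integral, average-precision form). With
#' zero predicted positives, precision and F1 are reported as 0 and
#' `zero_positive_flag` is set. With a single-class truth vector AUROC and
#' AUPRC are `NA` and `auc_undefined_flag` is set.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision threshold, default 0.5.
#' @return list of class `metrics_report`.
#' @export
metrics_report <- function(y_true, scores, threshold = 0.5) {
  if (length(y_true) != length(scores))
    validation_error("y_true and scores lengths differ")
  if (any(scores < 0 | scores > 1))
    validation_error("scores must be in [0, 1]")
  cc <- confusion(y_true, as.integer(scores > threshold))
  sens <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_
  spec <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA_real_
  zero_pos <- (cc$TP + cc$FP) == 0
  prec <- if (zero_pos) 0 else cc$TP / (cc$TP + cc$FP)
  f1 <- if (zero_pos || is.na(sens) || prec + sens == 0) 0
        else 2 * prec * sens / (prec + sens)
  gm <- if (is.na(sens) || is.na(spec)) NA_real_ else g_mean(sens, spec)
  single_class <- length(unique(y_true)) < 2L
  if (single_class) {
    auroc <- NA_real_
    auprc <- NA_real_
  } else {
    pts <- roc_pr_points(y_true, scores)
    auroc <- trapezoid_auc(pts$roc$fpr, pts$roc$tpr)
    auprc <- step_auprc(pts$pr$recall, pts$pr$precision)
  }
  structure(list(
    sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    g_mean = gm, auroc = auroc, auprc = auprc,
    threshold = threshold, confusion = cc,
    zero_positive_flag = zero_pos, auc_undefined_flag = single_class
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf(
    "<metrics_report> threshold %.3g\n  sensitivity %s  specificity %s  G-mean %s\n  precision %s  F1 %s  AUROC %s  AUPRC %s\n",
    x$threshold, fmt(x$sensitivity), fmt(x$specificity), fmt(x$g_mean),
    fmt(x$precision), fmt(x$f1), fmt(x$auroc), fmt(x$auprc)))
  invisible(x)
}

trapezoid_auc <- function(x, y) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

step_auprc <- function(recall, precision) {
  o <- order(recall)
  r <- recall[o]; p <- precision[o]
  sum(diff(c(0, r)) * p)
}

#' ROC and precision-recall curve points
#'
#' One operating point per distinct score threshold (tied scores grouped),
#' plus the (0, 0) / (1, 1) ROC endpoints. Points are ordered by increasing
#' FPR (ROC) and increasing recall (PR).
#'
#' @param y_true 0/1 labels, both classes present.
#' @param scores numeric scores.
#' @return list with data frames `roc` (`threshold`, `fpr`, `tpr`) and `pr`
#'   (`threshold`, `recall`, `precision`).
#' @export
roc_pr_points <- function(y_true, scores) {
  if (length(unique(y_true)) < 2L)
    fadel_error("both classes must be present for curve points",
                "fadel_degenerate_labels_error")
  P <- sum(y_true == 1)
  N <- sum(y_true == 0)
  o <- order(scores, decreasing = TRUE)
  ys <- y_true[o]; ss <- scores[o]
  grp_last <- which(c(ss[-1] != ss[-length(ss)], TRUE)) # last index per tie group
  tp <- cumsum(ys)[grp_last]
  fp <- cumsum(1 - ys)[grp_last]
  thr <- ss[grp_last]
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / N), tpr = c(0, tp / P))
  precision <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
  pr <- data.frame(threshold = thr, recall = tp / P, precision = precision)
  list(roc = roc, pr = pr)
}

#' Fisher-Pearson skewness
#'
#' The third standardized central moment `g1 = m3 / m2^(3/2)` with population
#' central moments (no small-sample bias correction); set
#' `bias_correction = TRUE` for the adjusted coefficient
#' `G1 = g1 * sqrt(n(n-1))/(n-2)`. Features with `|g1| > 1` are conventionally
#' called highly skewed.
#'
#' @param x numeric sample, `n >= 3`, non-constant.
#' @param bias_correction use the adjusted (sample) variant.
#' @param feature_name used in error messages.
#' @return real.
#' @export
fisher_pearson_skewness <- function(x, bias_correction = FALSE,
                                    feature_name = "x") {
  n <- length(x)
  if (n < 3L)
    validation_error(sprintf("skewness of '%s' needs n >= 3", feature_name))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    fadel_error(sprintf("skewness of constant feature '%s' is undefined",
                        feature_name), "fadel_degenerate_feature_error")
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  if (bias_correction) g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Per-feature skewness before and after discretization
#'
#' For every flagged feature with a fitted discretizer, reports the
#' Fisher-Pearson skewness of the raw values and of the 1-based interval
#' indices, mirroring the direction check that supervised discretization
#' compresses heavy right tails. Features whose indices are constant
#' (`K = 1`) get `NA` with a flag, and constant raw columns are flagged and
#' excluded from the skewness columns.
#'
#' @param ds a [tabular_dataset()].
#' @param discretizers named list of fitted `feature_discretizer`s.
#' @return data frame with columns `feature`, `k`, `skew_raw`,
#'   `skew_discretized`, `high_skew_raw`, `flagged`.
#' @export
skewness_report <- function(ds, discretizers) {
  feats <- names(discretizers)
  rows <- lapply(feats, function(nm) {
    x <- ds$X[, nm]
    d <- discretizers[[nm]]
    z <- assign_interval(d, x)
    sr <- tryCatch(fisher_pearson_skewness(x, feature_name = nm),
                   fadel_degenerate_feature_error = function(e) NA_real_)
    sd_ <- tryCatch(fisher_pearson_skewness(z, feature_name = nm),
                    fadel_degenerate_feature_error = function(e) NA_real_)
    data.frame(feature = nm, k = d$n_intervals, skew_raw = sr,
               skew_discretized = sd_,
               high_skew_raw = !is.na(sr) && abs(sr) > 1,
               flagged = is.na(sr) || is.na(sd_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
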