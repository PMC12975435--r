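#' Prevalence-weighted efficiency
#'
#' `EFF = P * Se + (1 - P) * Sp`: the probability-of-correct-classification
#' at prevalence `P`, used to pick the operating threshold.
#'
#' @param se,sp,p sensitivity, specificity and prevalence, all in [0, 1].
#' @return EFF in [0, 1].
#' @export
efficiency <- function(se, sp, p) {
  stop_if_not(all(c(se, sp, p) >= 0 & c(se, sp, p) <= 1),
              "Se, Sp and P must lie in [0, 1]")
  p * se + (1 - p) * sp
}

#' Area under the ROC curve via the Mann-Whitney identity
#'
#' Fraction of (positive, negative) pairs where the positive scores higher,
#' counting ties as one half.
#'
#' @param prob predicted probabilities (scores).
#' @param labels binary 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(prob, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  stop_if_not(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(prob)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Performance report from confusion counts
#'
#' Derives Se, Sp, PPV, NPV, prevalence, EFF and the thresholded C-statistic
#' `(Se + Sp) / 2` from a 2x2 confusion table. Undefined ratios (empty
#' margins) are reported as `NA` rather than silently 0.
#'
#' @param tp,fp,tn,fn confusion counts (non-negative integers).
#' @param threshold the probability threshold the counts were taken at
#'   (`NA` if not applicable).
#' @param auc optional AUC to carry along.
#' @return object of class `performance_report`.
#' @export
performance_from_counts <- function(tp, fp, tn, fn, threshold = NA_real_,
                                    auc = NA_real_) {
  stop_if_not(all(c(tp, fp, tn, fn) >= 0), "counts must be >= 0")
  n <- tp + fp + tn + fn
  stop_if_not(n > 0, "empty confusion table")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  se <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  prev <- (tp + fn) / n
  eff <- if (!is.na(se) && !is.na(sp)) efficiency(se, sp, prev) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 sensitivity = se, specificity = sp,
                 ppv = safe_div(tp, tp + fp), npv = safe_div(tn, tn + fn),
                 prevalence = prev, efficiency = eff,
                 c_statistic = if (!is.na(se) && !is.na(sp)) (se + sp) / 2
                 else NA_real_,
                 auc = auc, threshold = threshold),
            class = "performance_report")
}

#' Evaluate probabilities against labels at a threshold
#'
#' A case is called positive iff its probability is strictly greater than
#' the threshold (the "MEL-RAD > 55%" convention). AUC is computed with the
#' Mann-Whitney identity.
#'
#' @param prob predicted probabilities of the positive (progression) class.
#' @param labels binary 0/1 labels.
#' @param threshold probability threshold in [0, 1].
#' @return a [performance_from_counts()] report.
#' @export
evaluate <- function(prob, labels, threshold) {
  stop_if_not(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  labels <- as.integer(labels)
  stop_if_not(all(labels %in% c(0L, 1L)), "labels must be 0/1")
  pos <- prob > threshold
  tp <- sum(pos & labels == 1L)
  fp <- sum(pos & labels == 0L)
  tn <- sum(!pos & labels == 0L)
  fn <- sum(!pos & labels == 1L)
  auc <- if (any(labels == 1L) && any(labels == 0L)) auc_mw(prob, labels)
  else NA_real_
  performance_from_counts(tp, fp, tn, fn, threshold = threshold, auc = auc)
}

#' Efficiency-maximizing probability threshold
#'
#' Scans thresholds on a fixed grid over [0, 1] (default step 0.005), with
#' prevalence taken from the observed labels, and returns the smallest
#' threshold attaining the maximum EFF together with its full report.
#'
#' @param prob,labels as in [evaluate()]; both classes present.
#' @param step grid step (default 0.005, i.e. 0.5%).
#' @return list with `threshold`, `eff`, `report`, and `grid` (data.frame of
#'   threshold/EFF pairs).
#' @export
select_threshold <- function(prob, labels, step = 0.005) {
  labels <- as.integer(labels)
  stop_if_not(any(labels == 1L) && any(labels == 0L),
              "both classes must be present")
  grid <- seq(0, 1, by = step)
  effs <- vapply(grid, function(t) {
    pos <- prob > t
    se <- sum(pos & labels == 1L) / sum(labels == 1L)
    sp <- sum(!pos & labels == 0L) / sum(labels == 0L)
    mean(labels) * se + (1 - mean(labels)) * sp
  }, numeric(1))
  best <- grid[which.max(effs)]  # which.max takes the first (smallest) max
  list(threshold = best, eff = max(effs),
       report = evaluate(prob, labels, best),
       grid = data.frame(threshold = grid, eff = effs))
}

#' @export
print.performance_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("Performance (n = %d%s):\n", x$n,
              if (!is.na(x$threshold))
                sprintf(", threshold = %.1f%%", 100 * x$threshold) else ""))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  Se %s  Sp %s  PPV %s  NPV %s\n", pct(x$sensitivity),
              pct(x$specificity), pct(x$ppv), pct(x$npv)))
  cat(sprintf("  prevalence %s  EFF %s  C-statistic %.2f%s\n",
              pct(x$prevalence), pct(x$efficiency), x$c_statistic,
              if (!is.na(x$auc)) sprintf("  AUC %.2f", x$auc) else ""))
  invisible(x)
}

#' @export
as.data.frame.performance_report <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, n = x$n,
             sensitivity = x$sensitivity, specificity = x$specificity,
             ppv = x$ppv, npv = x$npv, prevalence = x$prevalence,
             efficiency = x$efficiency, c_statistic = x$c_statistic,
             auc = x$auc, threshold = x$threshold)
}
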