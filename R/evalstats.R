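#' @title Evaluation metrics and classifier-comparison statistics
#' @name evalstats
#' @description
#' Confusion-matrix metrics (accuracy, sensitivity, specificity), ROC-AUC
#' in the Mann-Whitney formulation (ties counted 0.5), per-fold summaries
#' with both standard-deviation conventions, the paired-sample t test used
#' to compare per-fold AUCs of two models, and the two-classifier
#' error-rate significance statistic
#' \deqn{Ps = |e_1 - e_2| / \sqrt{q(1-q)(1/n_1 + 1/n_2)}, \quad
#'       q = (e_1 + e_2)/2,}
#' where `Ps >= 1.96` declares a significant difference at 95% confidence.
NULL

#' Confusion matrix at a decision threshold
#'
#' Scores at or above the threshold are predicted positive (ties positive).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `confusion_matrix` with counts `tp, fp, fn, tn`
#'   and `total`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- scores >= threshold
  pos <- labels == 1
  structure(list(tp = sum(pred & pos), fp = sum(pred & !pos),
                 fn = sum(!pred & pos), tn = sum(!pred & !pos),
                 total = length(scores), threshold = threshold),
            class = "confusion_matrix")
}

#' Metrics derived from a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return Named vector: accuracy, sensitivity (TPR), specificity (TNR).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  c(accuracy = (cm$tp + cm$tn) / cm$total,
    sensitivity = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_,
    specificity = if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_)
}

#' ROC area under the curve (Mann-Whitney formulation)
#'
#' Equals the probability that a random positive outscores a random
#' negative, with ties counted 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: both classes must be present")
  r <- rank(scores)   # midranks handle ties as 0.5
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summary of a per-fold metric
#'
#' Reports the mean and both standard-deviation conventions: `sample_sd`
#' (n-1 denominator) and `population_sd` (n denominator). Published fold
#' tables in this field use either; downstream reporting states which.
#'
#' @param values Per-fold metric values (length >= 2).
#' @return Object of class `fold_summary` with `values`, `mean`,
#'   `sample_sd`, `population_sd`, `n`.
#' @export
fold_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need >= 2 fold values for a summary")
  m <- mean(values)
  ssd <- stats::sd(values)
  psd <- sqrt(mean((values - m)^2))
  structure(list(values = values, mean = m, sample_sd = ssd,
                 population_sd = psd, n = length(values)),
            class = "fold_summary")
}

#' Paired-sample t test on per-fold differences
#'
#' For differences `d_i` (e.g. per-fold AUC of model A minus model B):
#' `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1`, two-sided p, and the
#' 95% confidence interval `mean(d) +/- t_{0.975, df} * sd(d)/sqrt(n)`.
#'
#' @param differences Numeric per-fold differences (n >= 2, not all equal).
#' @return Object of class `paired_t_result`: `mean_diff`, `t_statistic`,
#'   `df`, `p_two_sided`, `ci95` (length-2 vector).
#' @export
paired_t <- function(differences) {
  differences <- as.numeric(differences)
  if (length(differences) < 2L) stop("need >= 2 differences")
  if (stats::sd(differences) == 0) {
    stop("degenerate test: all differences are equal (zero variance)")
  }
  tt <- stats::t.test(differences)
  structure(list(mean_diff = unname(tt$estimate),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_two_sided = tt$p.value,
                 ci95 = as.numeric(tt$conf.int)),
            class = "paired_t_result")
}

#' Two-classifier error-rate significance statistic
#'
#' `ps_test(e1, e2, n1, n2)` computes
#' `Ps = |e1 - e2| / sqrt(q (1 - q) (1/n1 + 1/n2))` with
#' `q = (e1 + e2)/2`; `Ps >= 1.96` declares a significant performance
#' difference at 95% confidence. The statistic is symmetric in the two
#' models and zero iff the error rates are equal.
#'
#' @param e1,e2 Error rates of the two models in `[0, 1]`.
#' @param n1,n2 Test-set sizes (>= 1).
#' @return Object of class `ps_result`: `e1, e2, q, n1, n2, ps,
#'   significant`.
#' @export
ps_test <- function(e1, e2, n1, n2) {
  if (e1 < 0 || e1 > 1 || e2 < 0 || e2 > 1) stop("error rates must lie in [0, 1]")
  if (n1 < 1 || n2 < 1) stop("test-set sizes must be >= 1")
  q <- (e1 + e2) / 2
  if (q <= 0 || q >= 1) {
    stop("zero-variance comparison: pooled error rate q = ", q)
  }
  ps <- abs(e1 - e2) / sqrt(q * (1 - q) * (1 / n1 + 1 / n2))
  structure(list(e1 = e1, e2 = e2, q = q, n1 = n1, n2 = n2,
                 ps = ps, significant = ps >= 1.96),
            class = "ps_result")
}

#' Evaluate a model on a labeled test set
#'
#' Deterministic inference followed by per-label metrics. The per-sample
#' table mirrors the actual-vs-predicted layout used for case review: one
#' row per nodule with actual label, predicted label and score for each of
#' the six features.
#'
#' @param model An `hsnet_model`.
#' @param test_set List of `volume_sample`s or a `list(X, Y, ids)` triple.
#' @param threshold Decision threshold (ties predicted positive).
#' @return Object of class `metric_report`: `$metrics` (data.frame with
#'   accuracy, sensitivity, specificity, auc, counts per label),
#'   `$confusion` (named list of `confusion_matrix`), `$predictions`
#'   (per-sample data.frame), `$threshold`.
#' @export
evaluate_model <- function(model, test_set, threshold = 0.5) {
  te <- if (is.list(test_set) && !is.null(test_set$X)) test_set else stack_volumes(test_set)
  scores <- .predict_scores(model, te$X)
  ids <- if (!is.null(te$ids)) te$ids else paste0("s", seq_len(ncol(te$X)))
  cms <- list()
  rows <- vector("list", 6L)
  for (i in seq_along(ALL_FEATURES)) {
    fname <- ALL_FEATURES[i]
    s <- scores[fname, ]
    y <- te$Y[fname, ]
    cm <- confusion(s, y, threshold)
    cms[[fname]] <- cm
    mets <- confusion_metrics(cm)
    auc <- tryCatch(roc_auc(s, y), error = function(e) NA_real_)
    rows[[i]] <- data.frame(label = fname, accuracy = mets[["accuracy"]],
                            sensitivity = mets[["sensitivity"]],
                            specificity = mets[["specificity"]],
                            auc = auc, n = cm$total,
                            n_positive = cm$tp + cm$fn)
  }
  pred_tab <- data.frame(id = ids)
  for (fname in ALL_FEATURES) {
    pred_tab[[paste0("actual_", fname)]] <- te$Y[fname, ]
    pred_tab[[paste0("predicted_", fname)]] <-
      as.integer(scores[fname, ] >= threshold)
    pred_tab[[paste0("score_", fname)]] <- scores[fname, ]
  }
  structure(list(metrics = do.call(rbind, rows), confusion = cms,
                 predictions = pred_tab, threshold = threshold),
            class = "metric_report")
}

#' ROC curve points
#'
#' All distinct thresholds with their false-positive and true-positive
#' rates, suitable for CSV export and plotting; the trapezoidal area over
#' these points equals [roc_auc()] up to floating error.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   the most conservative threshold to the most permissive.
#' @export
roc_points <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("ROC undefined: both classes must be present")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- vapply(th, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / n0, tpr = sum(pred & labels == 1) / n1)
  }, numeric(2))
  data.frame(threshold = th, fpr = pts["fpr", ], tpr = pts["tpr", ])
}

#' @export
print.ps_result <- function(x, ...) {
  cat(sprintf("Two-classifier significance test: Ps = %.3f (%ssignificant at 95%%)\n",
              x$ps, if (x$significant) "" else "not "))
  cat(sprintf("  error rates %.4f vs %.4f (q = %.4f), n1 = %d, n2 = %d\n",
              x$e1, x$e2, x$q, x$n1, x$n2))
  invisible(x)
}

#' @export
print.fold_summary <- function(x, ...) {
  cat(sprintf("Fold summary over %d folds: mean %.4f (sample SD %.4f, population SD %.4f)\n",
              x$n, x$mean, x$sample_sd, x$population_sd))
  invisible(x)
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t test: mean difference %.4f, t = %.3f (df = %d), p = %.4f\n",
              x$mean_diff, x$t_statistic, x$df, x$p_two_sided))
  cat(sprintf("  95%% CI [%.4f, %.4f]\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Per-label evaluation (threshold ", x$threshold, ", ties positive):\n",
      sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (threshold %.3g): tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$threshold, x$tp, x$fp, x$fn, x$tn, x$total))
  invisible(x)
}
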