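#' @title Four-fold cross-validation harness
#' @name cvharness
#' @description
#' Splits a nodule dataset into four equal folds, builds the standard
#' rotation plan (two training folds, one validation fold, one test fold,
#' each fold serving as test exactly once), trains per rotation with
#' augmentation applied to the training folds only, and aggregates
#' per-label fold summaries plus model-comparison statistics (paired t
#' tests and the Ps significance statistic) against an optional baseline
#' architecture.
NULL

#' Assign samples to k folds
#'
#' Seeded shuffle then (optionally stratified) cyclic assignment; fold
#' sizes differ by at most one.
#'
#' @param ids Character or integer sample identifiers.
#' @param k Number of folds (>= 2; the rotation plan requires 4).
#' @param seed RNG seed.
#' @param stratify_on Optional binary vector aligned with `ids`; when
#'   given, assignment balances the two classes across folds.
#' @return Object of class `fold_split`: `$fold` (named integer fold 1..k
#'   per id), `$k`, `$seed`.
#' @export
make_folds <- function(ids, k = 4L, seed = 1L, stratify_on = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  n <- length(ids)
  if (n < k) stop("need at least k samples")
  if (anyDuplicated(ids)) stop("ids must be unique")
  set.seed(seed)
  fold <- integer(n)
  if (is.null(stratify_on)) {
    ord <- sample.int(n)
    fold[ord] <- rep_len(seq_len(k), n)
  } else {
    if (length(stratify_on) != n) stop("stratify_on must align with ids")
    counter <- 0L
    for (cls in unique(stratify_on)) {
      w <- which(stratify_on == cls)
      w <- w[sample.int(length(w))]
      fold[w] <- ((counter + seq_along(w) - 1L) %% k) + 1L
      counter <- counter + length(w)
    }
  }
  names(fold) <- as.character(ids)
  structure(list(fold = fold, k = k, seed = seed,
                 stratified = !is.null(stratify_on)),
            class = "fold_split")
}

#' The four-fold rotation plan
#'
#' Exactly the standard rotation: (train 2+3, val 4, test 1),
#' (train 3+4, val 1, test 2), (train 4+1, val 2, test 3),
#' (train 1+2, val 3, test 4). In each rotation the four folds are
#' disjoint and exhaustive, and each fold is the test fold exactly once.
#'
#' @param split A `fold_split` with `k = 4`.
#' @return Object of class `experiment_plan`: list of four rotations, each
#'   with `train` (two fold numbers), `val`, `test`.
#' @export
plan_rotations <- function(split) {
  stopifnot(inherits(split, "fold_split"))
  if (split$k != 4L) stop("the rotation plan requires k = 4 folds")
  rot <- list(
    list(train = c(2L, 3L), val = 4L, test = 1L),
    list(train = c(3L, 4L), val = 1L, test = 2L),
    list(train = c(4L, 1L), val = 2L, test = 3L),
    list(train = c(1L, 2L), val = 3L, test = 4L))
  structure(rot, class = "experiment_plan")
}

#' Run k-fold cross-validation (optionally against a baseline architecture)
#'
#' Per rotation: the two training folds are expanded by random cube
#' symmetries ([expand_training_set()]); the validation fold is used only
#' for early-stopping checkpoint selection; the untouched test fold is
#' evaluated. Training/test id disjointness is asserted on every rotation.
#' With a `baseline_cfg`, the baseline is trained on identical data and
#' seeds, and per-label paired t tests on fold AUC differences plus the
#' Ps statistic (from mean AUC error rates and the test-fold sizes) are
#' reported.
#'
#' @param samples List of `volume_sample`s.
#' @param arch_cfg [arch_config()] of the model under evaluation.
#' @param train_cfg [train_config()] shared by all rotations.
#' @param baseline_cfg Optional [arch_config()] of a comparison model.
#' @param augment_factor Training-set expansion factor (1 disables).
#' @param stratify Stratify folds on binarized malignancy (default TRUE).
#' @param rotations Subset of 1:4 to run (all four by default).
#' @param seed Seed for fold assignment and augmentation.
#' @return Object of class `crossval_result`: `$folds`, `$rotations`
#'   (per-rotation `metric_report`s, and baseline reports if requested),
#'   `$summary` (per-label fold summaries of accuracy and AUC),
#'   `$comparison` (paired t and Ps tables, when a baseline is given).
#' @export
run_crossval <- function(samples, arch_cfg, train_cfg, baseline_cfg = NULL,
                         augment_factor = 6L, stratify = TRUE,
                         rotations = 1:4, seed = 1L) {
  ids <- vapply(samples, function(s) s$id, character(1))
  strat <- if (stratify) {
    vapply(samples, function(s) s$labels[["malignancy"]], integer(1))
  } else NULL
  split <- make_folds(ids, k = 4L, seed = seed, stratify_on = strat)
  plan <- plan_rotations(split)
  rot_out <- list()
  for (r in rotations) {
    ro <- plan[[r]]
    tr_idx <- which(split$fold %in% ro$train)
    va_idx <- which(split$fold == ro$val)
    te_idx <- which(split$fold == ro$test)
    tr <- expand_training_set(samples[tr_idx], factor = augment_factor,
                              seed = seed + r)
    # leakage guard: augmented training ids must never reach val/test
    tr_origin <- vapply(tr, function(s) {
      if (!is.null(s$origin_id)) s$origin_id else s$id
    }, character(1))
    if (length(intersect(tr_origin, ids[c(va_idx, te_idx)]))) {
      stop("fold leakage: training-derived sample present in val/test")
    }
    if (any(vapply(samples[te_idx], function(s) !is.null(s$origin_id) ||
                     identical(s$provenance, "augmented"), logical(1)))) {
      stop("test set contains augmented samples")
    }
    model <- build_model(arch_cfg, seed = train_cfg$seed + r)
    fit <- train_model(model, tr, samples[va_idx], train_cfg)
    report <- evaluate_model(fit$model, samples[te_idx])
    entry <- list(rotation = r, test_fold = ro$test, report = report,
                  n_test = length(te_idx), history = fit$history)
    if (!is.null(baseline_cfg)) {
      bmodel <- build_model(baseline_cfg, seed = train_cfg$seed + r)
      bfit <- train_model(bmodel, tr, samples[va_idx], train_cfg)
      entry$baseline_report <- evaluate_model(bfit$model, samples[te_idx])
    }
    rot_out[[as.character(r)]] <- entry
  }
  summary <- .crossval_summary(rot_out)
  comparison <- if (!is.null(baseline_cfg)) .crossval_comparison(rot_out) else NULL
  structure(list(folds = split, rotations = rot_out, summary = summary,
                 comparison = comparison, seed = seed),
            class = "crossval_result")
}

.metric_by_label <- function(rot_out, field, baseline = FALSE) {
  sapply(rot_out, function(e) {
    rep <- if (baseline) e$baseline_report else e$report
    stats::setNames(rep$metrics[[field]], rep$metrics$label)[ALL_FEATURES]
  })
}

.crossval_summary <- function(rot_out) {
  if (length(rot_out) < 2L) return(NULL)
  acc <- .metric_by_label(rot_out, "accuracy")
  auc <- .metric_by_label(rot_out, "auc")
  list(accuracy = apply(acc, 1, fold_summary, simplify = FALSE),
       auc = apply(auc, 1, fold_summary, simplify = FALSE))
}

.crossval_comparison <- function(rot_out) {
  auc_m <- .metric_by_label(rot_out, "auc")
  auc_b <- .metric_by_label(rot_out, "auc", baseline = TRUE)
  n_test <- vapply(rot_out, function(e) e$n_test, integer(1))
  paired <- list()
  ps <- list()
  for (fname in ALL_FEATURES) {
    d <- auc_m[fname, ] - auc_b[fname, ]
    # a degenerate test yields NULL; single-bracket assignment keeps the
    # element (and its name) in place instead of deleting it
    paired[fname] <- list(tryCatch(paired_t(d), error = function(e) NULL))
    e1 <- 1 - mean(auc_b[fname, ])     # baseline error rate
    e2 <- 1 - mean(auc_m[fname, ])
    ps[fname] <- list(tryCatch(ps_test(e1, e2, round(mean(n_test)),
                                       round(mean(n_test))),
                               error = function(e) NULL))
  }
  list(paired_t = paired, ps = ps,
       auc_model = auc_m, auc_baseline = auc_b)
}
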