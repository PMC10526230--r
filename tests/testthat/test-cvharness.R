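test_that("fold assignment partitions samples into near-equal seeded folds", {
  f <- make_folds(paste0("s", 1:8), k = 4, seed = 1)
  expect_equal(as.integer(table(f$fold)), rep(2L, 4))
  expect_setequal(names(f$fold), paste0("s", 1:8))
  # the published cohort size: 4252 nodules split into four folds of 1063
  f2 <- make_folds(seq_len(4252), k = 4, seed = 2)
  expect_equal(as.integer(table(f2$fold)), rep(1063L, 4))
  # determinism and remainder handling
  expect_identical(make_folds(paste0("s", 1:8), k = 4, seed = 1)$fold, f$fold)
  f3 <- make_folds(1:10, k = 4, seed = 3)
  expect_true(max(table(f3$fold)) - min(table(f3$fold)) <= 1)
  expect_error(make_folds(1:10, k = 1), "k must be")
  expect_error(make_folds(c(1, 1, 2, 3), k = 2), "unique")
})

test_that("stratified folds balance a binary label across folds", {
  y <- rep(c(0, 1), times = c(80, 20))
  f <- make_folds(seq_along(y), k = 4, seed = 5, stratify_on = y)
  pos_per_fold <- table(f$fold[as.character(which(y == 1))])
  expect_true(all(pos_per_fold == 5))
  expect_true(max(table(f$fold)) - min(table(f$fold)) <= 1)
})

test_that("the rotation plan is the standard 2+1+1 rotation over four folds", {
  f <- make_folds(1:12, k = 4, seed = 1)
  plan <- plan_rotations(f)
  expect_length(plan, 4L)
  expect_equal(plan[[1]], list(train = c(2L, 3L), val = 4L, test = 1L))
  expect_equal(plan[[2]], list(train = c(3L, 4L), val = 1L, test = 2L))
  expect_equal(plan[[3]], list(train = c(4L, 1L), val = 2L, test = 3L))
  expect_equal(plan[[4]], list(train = c(1L, 2L), val = 3L, test = 4L))
  for (ro in plan) expect_setequal(c(ro$train, ro$val, ro$test), 1:4)
  expect_equal(sort(vapply(plan, `[[`, integer(1), "test")), 1:4)
  f3 <- make_folds(1:12, k = 3, seed = 1)
  expect_error(plan_rotations(f3), "k = 4")
})

test_that("cross-validation keeps test folds pure and aggregates fold summaries", {
  cfg <- phantom_config(grid_size = 16L)
  samples <- generate_samples(48, cfg, seed = 13)
  acfg <- arch_config("hsnet", patch_size = 16L, filters = c(3L, 4L, 5L),
                      branch_feature_dim = 6L, malignancy_head_dim = 8L,
                      dropout_rate = 0.1)
  tcfg <- train_config(optimizer = "sgd", base_lr = 5e-3, epochs = 1L,
                       batch_size = 12L, seed = 2)
  res <- run_crossval(samples, acfg, tcfg, augment_factor = 2L,
                      rotations = 1:2, seed = 9)
  expect_named(res$rotations, c("1", "2"))
  ids <- vapply(samples, `[[`, "", "id")
  for (e in res$rotations) {
    # disjointness of train-origin ids and test ids per rotation
    ro <- plan_rotations(res$folds)[[e$rotation]]
    test_ids <- names(res$folds$fold)[res$folds$fold == ro$test]
    train_ids <- names(res$folds$fold)[res$folds$fold %in% ro$train]
    expect_length(intersect(test_ids, train_ids), 0L)
    expect_equal(e$n_test, length(test_ids))
    expect_s3_class(e$report$metrics, "data.frame")
  }
  # aggregate summary equals fold_summary of the per-rotation values
  acc <- vapply(res$rotations, function(e) {
    e$report$metrics$accuracy[e$report$metrics$label == "malignancy"]
  }, numeric(1))
  expect_equal(res$summary$accuracy$malignancy$mean, mean(acc))
  # full determinism of the end-to-end run
  res2 <- run_crossval(samples, acfg, tcfg, augment_factor = 2L,
                       rotations = 1:2, seed = 9)
  expect_identical(res2$summary, res$summary)
  expect_identical(res2$rotations[["1"]]$report$predictions,
                   res$rotations[["1"]]$report$predictions)
})

test_that("baseline comparisons produce paired-t and Ps rows per label", {
  cfg <- phantom_config(grid_size = 16L)
  samples <- generate_samples(40, cfg, seed = 17)
  acfg <- arch_config("hsnet", patch_size = 16L, filters = c(3L, 4L),
                      conv_blocks = 2L, branch_feature_dim = 6L,
                      malignancy_head_dim = 8L, dropout_rate = 0.1)
  bcfg <- arch_config("hscnn", patch_size = 16L, filters = c(3L,  4L),
                      conv_blocks = 1L, branch_feature_dim = 6L,
                      malignancy_head_dim = 8L, dropout_rate = 0.1)
  tcfg <- train_config(optimizer = "sgd", base_lr = 5e-3, epochs = 1L,
                       batch_size = 10L, seed = 3)
  res <- run_crossval(samples, acfg, tcfg, baseline_cfg = bcfg,
                      augment_factor = 1L, rotations = 1:4, seed = 4)
  cmp <- res$comparison
  expect_named(cmp$paired_t, c("calcification", "margin", "sphericity",
                               "subtlety", "texture", "malignancy"))
  expect_named(cmp$ps, names(cmp$paired_t))
  expect_equal(dim(cmp$auc_model), c(6L, 4L))
  ok_pt <- !vapply(cmp$paired_t, is.null, logical(1))
  expect_true(any(ok_pt))
  for (fname in names(cmp$paired_t)[ok_pt]) {
    pt <- cmp$paired_t[[fname]]
    expect_equal(pt$df, 3)
    expect_equal(pt$mean_diff,
                 mean(cmp$auc_model[fname, ] - cmp$auc_baseline[fname, ]))
  }
})

test_that("evaluation reports are internally consistent with their confusion matrices", {
  cfg <- phantom_config(grid_size = 16L)
  samples <- generate_samples(30, cfg, seed = 23)
  acfg <- arch_config("hsnet", patch_size = 16L, filters = c(3L, 4L),
                      conv_blocks = 2L, branch_feature_dim = 6L,
                      malignancy_head_dim = 8L, dropout_rate = 0.1)
  m <- build_model(acfg, seed = 1)
  rep <- evaluate_model(m, samples)
  for (i in seq_len(nrow(rep$metrics))) {
    lab <- rep$metrics$label[i]
    cm <- rep$confusion[[lab]]
    expect_equal(rep$metrics$accuracy[i], (cm$tp + cm$tn) / cm$total)
    expect_equal(cm$total, 30L)
    # AUC recomputed from the per-sample table matches the report
    sc <- rep$predictions[[paste0("score_", lab)]]
    y <- rep$predictions[[paste0("actual_", lab)]]
    auc <- tryCatch(roc_auc(sc, y), error = function(e) NA_real_)
    expect_equal(rep$metrics$auc[i], auc)
    # predicted column is the thresholded score
    expect_equal(rep$predictions[[paste0("predicted_", lab)]],
                 as.integer(sc >= 0.5))
  }
})
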