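tiny_cfg <- arch_config("hsnet", patch_size = 8L, filters = c(3L, 4L, 5L),
                        branch_feature_dim = 6L, malignancy_head_dim = 8L,
                        dropout_rate = 0.1)

tiny_samples <- function(n = 24, seed = 1) {
  cfg <- phantom_config(grid_size = 16L)
  smp <- generate_samples(n, cfg, seed = seed)
  # downsample 16^3 -> 8^3 by 2x mean pooling to keep training tests fast
  down2 <- function(a) {
    D <- dim(a)[1]
    o <- seq(1, D, 2)
    e <- seq(2, D, 2)
    a <- a[o, , ] + a[e, , ]
    a <- a[, o, ] + a[, e, ]
    (a[, , o] + a[, , e]) / 8
  }
  lapply(smp, function(v) {
    v$intensities <- down2(v$intensities)
    v
  })
}

test_that("the multi-task loss matches binary cross-entropy closed forms", {
  Y <- matrix(c(1, 0, 1, 0, 1, 0), 6, 2)
  rownames(Y) <- c("calcification", "margin", "sphericity", "subtlety",
                   "texture", "malignancy")
  # all predictions 0.5 with unit weights: 6 * ln 2 per sample
  expect_equal(multitask_loss(matrix(0.5, 6, 2), Y), 6 * log(2))
  # perfect predictions: ~0 up to clipping
  expect_lt(multitask_loss(Y, Y), 1e-5)
  # zero weights: 0
  expect_equal(multitask_loss(matrix(0.2, 6, 2), Y, weights = rep(0, 6)), 0)
  # weighted: only the malignancy head contributes
  w <- c(0, 0, 0, 0, 0, 2)
  expect_equal(multitask_loss(matrix(0.5, 6, 2), Y, weights = w), 2 * log(2))
  expect_error(multitask_loss(matrix(0.5, 6, 2), Y, weights = 1:5), "6 entries")
})

test_that("the cyclical learning rate is the closed-form triangular wave", {
  expect_equal(clr_schedule(0, 1e-3, 6e-3, 100), 1e-3)
  expect_equal(clr_schedule(100, 1e-3, 6e-3, 100), 6e-3)
  expect_equal(clr_schedule(200, 1e-3, 6e-3, 100), 1e-3)
  expect_equal(clr_schedule(50, 1e-3, 6e-3, 100), 3.5e-3)
  # periodicity and symmetry across several cycles
  it <- 0:1000
  lr <- clr_schedule(it, 2e-4, 1e-3, 50)
  expect_equal(lr[it %% 100 == 0], rep(2e-4, 11))
  expect_equal(lr[(it - 50) %% 100 == 0], rep(1e-3, 10))
  expect_true(all(lr >= 2e-4 & lr <= 1e-3))
  expect_error(clr_schedule(0, 2e-3, 1e-3, 10), "base_lr")
  expect_error(clr_schedule(0, 1e-3, 2e-3, 0), "step_size")
})

test_that("SWA updates implement the running mean of weight snapshots", {
  w1 <- list(a = matrix(1, 2, 2), b = 1)
  w2 <- list(a = matrix(2, 2, 2), b = 2)
  w3 <- list(a = matrix(3, 2, 2), b = 3)
  # n = 0 returns the new weights exactly
  expect_identical(swa_update(w1, 0, w2), w2)
  # folding identical snapshots is a fixed point
  expect_equal(swa_update(w1, 5, w1), w1)
  # sequential folding of 1, 2, 3 equals the arithmetic mean 2
  avg <- swa_update(w1, 0, w1)
  avg <- swa_update(avg, 1, w2)
  avg <- swa_update(avg, 2, w3)
  expect_equal(avg$a, matrix(2, 2, 2))
  expect_equal(avg$b, 2)
  # general case: running mean equals direct averaging of stored snapshots
  set.seed(8)
  snaps <- lapply(1:6, function(i) list(a = matrix(rnorm(4), 2), b = rnorm(1)))
  run <- snaps[[1]]
  for (i in 2:6) run <- swa_update(run, i - 1, snaps[[i]])
  expect_equal(run$a, Reduce(`+`, lapply(snaps, `[[`, "a")) / 6)
  expect_error(swa_update(w1, 1, list(c = 1)), "name sets")
})

test_that("training runs, records complete history, and is seed-reproducible", {
  smp <- tiny_samples(24)
  tc <- train_config(optimizer = "sgd", base_lr = 5e-3, max_lr = 2e-2,
                     use_clr = TRUE, epochs = 3L, batch_size = 8L, seed = 7)
  m <- build_model(tiny_cfg, seed = 7)
  res <- train_model(m, smp, cfg = tc)
  expect_equal(nrow(res$history), 3L)
  expect_true(all(is.finite(res$history$train_loss)))
  expect_true(all(diff(res$history$train_loss) < 0.5))  # no divergence
  # per-iteration learning rates follow the schedule
  expect_equal(res$lr, clr_schedule(seq_along(res$lr) - 1, 5e-3, 2e-2, 6),
               tolerance = 1e-12)
  # same seed, same data: identical history and weights
  res2 <- train_model(build_model(tiny_cfg, seed = 7), smp, cfg = tc)
  expect_identical(res2$history, res$history)
  expect_identical(res2$model$params, res$model$params)
  # epochs = 0: initial weights, empty history
  m0 <- build_model(tiny_cfg, seed = 7)
  res0 <- train_model(m0, smp, cfg = train_config(epochs = 0L, seed = 1))
  expect_identical(res0$model$params, m0$params)
  expect_equal(nrow(res0$history), 0L)
})

test_that("the initial loss is optimizer-agnostic and SWA folding of one epoch matches", {
  smp <- tiny_samples(16)
  first_loss <- sapply(c("sgd", "adam", "rmsprop"), function(opt) {
    tc <- train_config(optimizer = opt, epochs = 1L, batch_size = 16L, seed = 3)
    res <- train_model(build_model(tiny_cfg, seed = 3), smp, cfg = tc)
    res$history$train_loss[1]
  })
  expect_equal(first_loss[["sgd"]], first_loss[["adam"]])
  expect_equal(first_loss[["sgd"]], first_loss[["rmsprop"]])
  # SWA over the final single epoch returns those weights (up to BN stats)
  tc_swa <- train_config(optimizer = "sgd", use_swa = TRUE, swa_start_epoch = 2L,
                         epochs = 2L, batch_size = 8L, seed = 3)
  res <- train_model(build_model(tiny_cfg, seed = 3), smp, cfg = tc_swa)
  expect_identical(res$model$params, res$final_params)
})

test_that("early stopping returns the best-validation-accuracy checkpoint", {
  smp <- tiny_samples(32, seed = 2)
  tc <- train_config(optimizer = "sgd", base_lr = 1e-2, max_lr = 1e-2,
                     epochs = 4L, batch_size = 8L, early_stop = TRUE, seed = 5)
  res <- train_model(build_model(tiny_cfg, seed = 5), smp[1:24], smp[25:32], tc)
  expect_true(res$checkpoint_epoch %in% 1:4)
  best_acc <- max(res$history$val_acc_malignancy)
  expect_equal(res$history$val_acc_malignancy[res$checkpoint_epoch], best_acc)
  # returned weights dominate the final epoch on validation malignancy accuracy
  va <- stack_volumes(smp[25:32])
  acc_of <- function(params) {
    mm <- res$model
    mm$params <- params
    sc <- model_forward(mm, va$X)
    mean((sc["malignancy", ] >= 0.5) == (va$Y["malignancy", ] == 1))
  }
  expect_gte(acc_of(res$model$params), acc_of(res$final_params))
})

test_that("comparison grids cover the published run configurations deterministically", {
  smp <- tiny_samples(20, seed = 3)
  # the five run specs: SGD, Adam, SGD-CLR, SGD-CLR+SWA, RMSProp-CLR+SWA
  runs <- list(
    Run1 = list(optimizer = "sgd"),
    Run2 = list(optimizer = "adam"),
    Run3 = list(optimizer = "sgd", use_clr = TRUE),
    Run4 = list(optimizer = "sgd", use_clr = TRUE, use_swa = TRUE),
    Run5 = list(optimizer = "rmsprop", use_clr = TRUE, use_swa = TRUE))
  base <- train_config(epochs = 2L, batch_size = 10L, seed = 4,
                       swa_start_epoch = 2L)
  tab <- run_comparison_grid(smp[1:16], NULL, smp[17:20], runs, tiny_cfg,
                             base_cfg = base, model_seed = 4)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$run, paste0("Run", 1:5))
  expect_equal(tab$optimizer, c("sgd", "adam", "sgd", "sgd", "rmsprop"))
  expect_equal(tab$swa, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(tab$test_accuracy >= 0 & tab$test_accuracy <= 1))
  # a single-run grid equals a direct train + evaluate
  tab1 <- run_comparison_grid(smp[1:16], NULL, smp[17:20], runs[1], tiny_cfg,
                              base_cfg = base, model_seed = 4)
  expect_equal(tab1$test_accuracy, tab$test_accuracy[1])
})
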