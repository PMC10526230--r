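#' @title Training loop: multi-task loss, CLR, SWA, early stopping
#' @name train
#' @description
#' Trains the six-head network with a weighted multi-task binary
#' cross-entropy, SGD / Adam / RMSProp optimizers, an optional triangular
#' cyclical learning rate (CLR) oscillating between `base_lr` and `max_lr`,
#' optional stochastic weight averaging (SWA, a running arithmetic mean of
#' end-of-epoch weight snapshots with batch-norm statistics recomputed over
#' the training set afterwards), and optional early-stopping checkpoint
#' selection on validation main-head (malignancy) accuracy.
NULL

#' Training configuration
#'
#' @param optimizer One of `"sgd"` (momentum 0.9), `"adam"`, `"rmsprop"`.
#' @param base_lr,max_lr Learning-rate bounds. Without CLR the fixed rate
#'   is `base_lr`; with CLR the rate follows a triangular wave between the
#'   two bounds.
#' @param clr_step_size Iterations per CLR half-cycle; default two epochs'
#'   worth of iterations (resolved when training starts).
#' @param use_clr,use_swa Enable cyclical learning rate / stochastic weight
#'   averaging.
#' @param swa_start_epoch First epoch (1-based) whose end-of-epoch weights
#'   enter the SWA average; default `ceiling(0.75 * epochs)`.
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param loss_weights Six non-negative per-task loss weights in canonical
#'   feature order (five semantic tasks then malignancy).
#' @param early_stop If `TRUE` (and a validation set is given), the
#'   returned non-SWA weights are the epoch checkpoint with the highest
#'   validation malignancy accuracy.
#' @param seed RNG seed covering shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(optimizer = c("sgd", "adam", "rmsprop"),
                         base_lr = 1e-3, max_lr = 6e-3,
                         clr_step_size = NULL,
                         use_clr = FALSE, use_swa = FALSE,
                         swa_start_epoch = NULL,
                         epochs = 300L, batch_size = 32L,
                         loss_weights = rep(1, 6),
                         early_stop = FALSE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (base_lr > max_lr) stop("base_lr must not exceed max_lr")
  if (length(loss_weights) != 6L) stop("loss_weights must have 6 entries")
  if (any(!is.finite(loss_weights)) || any(loss_weights < 0)) {
    stop("loss_weights must be finite and non-negative")
  }
  epochs <- as.integer(epochs)
  if (is.null(swa_start_epoch)) swa_start_epoch <- max(1L, ceiling(0.75 * epochs))
  if (swa_start_epoch > epochs && epochs > 0L) {
    stop("swa_start_epoch must not exceed epochs")
  }
  structure(list(optimizer = optimizer, base_lr = base_lr, max_lr = max_lr,
                 clr_step_size = clr_step_size, use_clr = use_clr,
                 use_swa = use_swa, swa_start_epoch = as.integer(swa_start_epoch),
                 epochs = epochs, batch_size = as.integer(batch_size),
                 loss_weights = loss_weights, early_stop = early_stop,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Weighted multi-task binary cross-entropy
#'
#' Mean over samples of the weighted sum over the six heads of the binary
#' cross-entropy, with probabilities clipped to `(eps, 1 - eps)`.
#'
#' @param predictions `6 x n` probability matrix (canonical feature order).
#' @param labels `6 x n` binary label matrix.
#' @param weights Six non-negative head weights.
#' @param eps Clipping constant.
#' @return Non-negative scalar; zero (up to clipping) iff every positively
#'   weighted head predicts its label exactly.
#' @export
multitask_loss <- function(predictions, labels, weights = rep(1, 6),
                           eps = 1e-7) {
  if (length(weights) != 6L) stop("weights must have 6 entries")
  predictions <- as.matrix(predictions)
  labels <- as.matrix(labels)
  stopifnot(nrow(predictions) == 6L, all(dim(predictions) == dim(labels)))
  p <- pmin(pmax(predictions, eps), 1 - eps)
  bce <- -(labels * log(p) + (1 - labels) * log(1 - p))
  mean(colSums(bce * weights))
}

#' Triangular cyclical learning rate
#'
#' A triangular wave with period `2 * step_size`: `base_lr` at iteration 0,
#' rising linearly to `max_lr` at `step_size`, falling back to `base_lr` at
#' `2 * step_size` (no amplitude decay).
#'
#' @param iteration Zero-based iteration counter (vectorized).
#' @param base_lr,max_lr Bounds.
#' @param step_size Iterations per half-cycle (>= 1).
#' @return Learning rate(s).
#' @export
clr_schedule <- function(iteration, base_lr, max_lr, step_size) {
  if (step_size < 1) stop("step_size must be >= 1")
  if (base_lr > max_lr) stop("base_lr must not exceed max_lr")
  cycle <- floor(1 + iteration / (2 * step_size))
  x <- abs(iteration / step_size - 2 * cycle + 1)
  base_lr + (max_lr - base_lr) * pmax(0, 1 - x)
}

#' Stochastic weight averaging update
#'
#' Folds a new weight snapshot `w` into the running average `w_swa` over
#' `n_models` snapshots: every tensor becomes
#' `(w_swa * n_models + w) / (n_models + 1)`. With `n_models = 0` the
#' result is `w` exactly.
#'
#' @param w_swa Named list of weight tensors (the running average).
#' @param n_models Number of snapshots already averaged.
#' @param w Named list of new weight tensors (same name set).
#' @return Named list of averaged tensors.
#' @export
swa_update <- function(w_swa, n_models, w) {
  if (!setequal(names(w_swa), names(w))) {
    stop("weight name sets differ; cannot average")
  }
  out <- w
  if (n_models > 0) {
    for (nm in names(w)) out[[nm]] <- (w_swa[[nm]] * n_models + w[[nm]]) / (n_models + 1)
  }
  out
}

# optimizer state + update step over a named parameter list
.make_optimizer <- function(kind, params) {
  st <- list(kind = kind, t = 0L)
  zeros <- lapply(params, function(x) x * 0)
  if (kind == "sgd") st$v <- zeros
  if (kind == "adam") { st$m <- zeros; st$v <- zeros }
  if (kind == "rmsprop") st$s <- zeros
  st
}

.opt_step <- function(st, params, grads, lr) {
  eps <- 1e-8
  # compiled kernels return vector gradients as n x 1 matrices; keep every
  # gradient in the exact shape of its parameter
  for (nm in names(grads)) {
    if (is.null(dim(params[[nm]]))) grads[[nm]] <- as.vector(grads[[nm]])
  }
  if (st$kind == "sgd") {
    for (nm in names(grads)) {
      st$v[[nm]] <- 0.9 * st$v[[nm]] - lr * grads[[nm]]
      params[[nm]] <- params[[nm]] + st$v[[nm]]
    }
  } else if (st$kind == "adam") {
    st$t <- st$t + 1L
    b1 <- 0.9; b2 <- 0.999
    c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
    for (nm in names(grads)) {
      g <- grads[[nm]]
      st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
      st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
      params[[nm]] <- params[[nm]] -
        lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
    }
  } else {
    for (nm in names(grads)) {
      g <- grads[[nm]]
      st$s[[nm]] <- 0.9 * st$s[[nm]] + 0.1 * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(st$s[[nm]]) + eps)
    }
  }
  list(state = st, params = params)
}

# batched inference scores (6 x n), deterministic
.predict_scores <- function(model, X, batch_size = 64L) {
  n <- ncol(X)
  out <- matrix(0, 6L, n, dimnames = list(ALL_FEATURES, NULL))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    out[, i:j] <- model_forward(model, X[, i:j, drop = FALSE], training = FALSE)
    i <- j + 1L
  }
  out
}

.head_accuracy <- function(scores, Y) {
  pred <- scores >= 0.5   # ties predicted positive
  acc <- rowMeans(pred == (Y == 1))
  names(acc) <- rownames(scores)
  acc
}

# cumulative-average batch-norm statistics recomputation over the training
# set (standard SWA practice); dropout disabled for determinism
.recompute_bn <- function(model, X, batch_size) {
  nb <- names(model$buffers)
  model$buffers[nb] <- lapply(model$buffers[nb], function(x) x * 0)
  rate <- model$cfg$dropout_rate
  model$cfg$dropout_rate <- 0
  n <- ncol(X)
  t <- 0L
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    t <- t + 1L
    model$bn_momentum <- 1 / t
    fw <- model_forward(model, X[, i:j, drop = FALSE], training = TRUE,
                        keep_cache = FALSE)
    model$buffers[names(fw$buffers)] <- fw$buffers
    i <- j + 1L
  }
  model$bn_momentum <- NULL
  model$cfg$dropout_rate <- rate
  model
}

#' Train a model
#'
#' Runs `cfg$epochs` epochs of mini-batch training. With `use_clr` the
#' per-iteration learning rate follows [clr_schedule()]; with `use_swa`,
#' end-of-epoch weights from `swa_start_epoch` onward are folded into a
#' running average ([swa_update()]) and batch-norm statistics are
#' recomputed over the training set before the SWA model is returned; with
#' `early_stop` (and a validation set) the returned non-SWA weights are the
#' checkpoint with the highest validation malignancy accuracy. Reproducible
#' given the seed on a fixed platform.
#'
#' @param model An `hsnet_model` from [build_model()].
#' @param train_set List of `volume_sample`s (or a `list(X, Y)` pair).
#' @param val_set Optional validation set in the same form.
#' @param cfg A [train_config()].
#' @return Object of class `train_result`: `$model` (trained model —
#'   SWA-averaged if `use_swa`, best checkpoint if `early_stop`, else final
#'   weights), `$history` (per-epoch data.frame), `$lr` (per-iteration
#'   learning rates), `$checkpoint_epoch`, `$final_params`.
#' @export
train_model <- function(model, train_set, val_set = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "hsnet_model"), inherits(cfg, "train_config"))
  tr <- if (is.list(train_set) && !is.null(train_set$X)) train_set else stack_volumes(train_set)
  va <- if (is.null(val_set)) NULL else {
    if (is.list(val_set) && !is.null(val_set$X)) val_set else stack_volumes(val_set)
  }
  n <- ncol(tr$X)
  if (n < 1) stop("empty training set")
  set.seed(cfg$seed)
  iters_per_epoch <- ceiling(n / cfg$batch_size)
  step_size <- if (is.null(cfg$clr_step_size)) 2L * iters_per_epoch else cfg$clr_step_size
  opt <- .make_optimizer(cfg$optimizer, model$params)
  hist_rows <- vector("list", cfg$epochs)
  lrs <- numeric(0)
  iter <- 0L
  swa_params <- NULL
  swa_n <- 0L
  best_acc <- -Inf
  best_params <- NULL
  best_buffers <- NULL
  checkpoint_epoch <- NA_integer_
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- numeric(6)
    ep_count <- 0L
    for (bstart in seq(1L, n, by = cfg$batch_size)) {
      bi <- ord[bstart:min(bstart + cfg$batch_size - 1L, n)]
      lr <- if (cfg$use_clr) {
        clr_schedule(iter, cfg$base_lr, cfg$max_lr, step_size)
      } else cfg$base_lr
      lrs <- c(lrs, lr)
      fw <- model_forward(model, tr$X[, bi, drop = FALSE], training = TRUE,
                          keep_cache = TRUE)
      model$buffers[names(fw$buffers)] <- fw$buffers
      Yb <- tr$Y[, bi, drop = FALSE]
      loss <- multitask_loss(fw$probs, Yb, cfg$loss_weights)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep)
      }
      grads <- model_backward(model, fw, Yb, cfg$loss_weights)
      stepped <- .opt_step(opt, model$params, grads, lr)
      opt <- stepped$state
      model$params <- stepped$params
      ep_loss <- ep_loss + loss * length(bi)
      ep_correct <- ep_correct + rowSums((fw$probs >= 0.5) == (Yb == 1))
      ep_count <- ep_count + length(bi)
      iter <- iter + 1L
    }
    train_acc <- ep_correct / ep_count
    names(train_acc) <- ALL_FEATURES
    val_loss <- NA_real_
    val_acc <- rep(NA_real_, 6)
    names(val_acc) <- ALL_FEATURES
    if (!is.null(va)) {
      vs <- .predict_scores(model, va$X, cfg$batch_size)
      val_loss <- multitask_loss(vs, va$Y, cfg$loss_weights)
      val_acc <- .head_accuracy(vs, va$Y)
      if (cfg$early_stop && val_acc[["malignancy"]] > best_acc) {
        best_acc <- val_acc[["malignancy"]]
        best_params <- model$params
        best_buffers <- model$buffers
        checkpoint_epoch <- ep
      }
    }
    if (cfg$use_swa && ep >= cfg$swa_start_epoch) {
      swa_params <- if (is.null(swa_params)) model$params else {
        swa_update(swa_params, swa_n, model$params)
      }
      swa_n <- swa_n + 1L
    }
    hist_rows[[ep]] <- data.frame(
      epoch = ep, train_loss = ep_loss / ep_count, val_loss = val_loss,
      t(stats::setNames(train_acc, paste0("train_acc_", names(train_acc)))),
      t(stats::setNames(val_acc, paste0("val_acc_", names(val_acc)))))
  }
  history <- if (cfg$epochs > 0) do.call(rbind, hist_rows) else
    data.frame(epoch = integer(0))
  final_params <- model$params
  if (cfg$use_swa && !is.null(swa_params)) {
    model$params <- swa_params
    model <- .recompute_bn(model, tr$X, cfg$batch_size)
  } else if (cfg$early_stop && !is.null(best_params)) {
    model$params <- best_params
    model$buffers <- best_buffers
  }
  structure(list(model = model, history = history, lr = lrs,
                 checkpoint_epoch = checkpoint_epoch,
                 final_params = final_params, config = cfg),
            class = "train_result")
}

#' Run a grid of optimizer-strategy comparisons
#'
#' Trains one model per run specification (e.g. plain SGD, Adam, SGD-CLR,
#' SGD-CLR+SWA, RMSProp-CLR+SWA) on the same data, seeds and architecture,
#' and reports the test malignancy accuracy of each.
#'
#' @param train_set,val_set,test_set Sample lists (val may be `NULL`).
#' @param runs Named list; each element a list of [train_config()] override
#'   fields (e.g. `list(optimizer = "sgd", use_clr = TRUE, use_swa = TRUE)`).
#' @param arch_cfg An [arch_config()].
#' @param base_cfg A [train_config()] providing shared defaults.
#' @param model_seed Weight-initialization seed shared by all runs.
#' @return data.frame with one row per run: optimizer, CLR/SWA flags, test
#'   accuracy and test AUC of the malignancy head.
#' @export
run_comparison_grid <- function(train_set, val_set = NULL, test_set,
                                runs, arch_cfg, base_cfg = train_config(),
                                model_seed = 1L) {
  te <- if (is.list(test_set) && !is.null(test_set$X)) test_set else stack_volumes(test_set)
  out <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    cfg <- base_cfg
    for (nm in names(runs[[i]])) cfg[[nm]] <- runs[[i]][[nm]]
    class(cfg) <- "train_config"
    model <- build_model(arch_cfg, seed = model_seed)
    res <- train_model(model, train_set, val_set, cfg)
    sc <- .predict_scores(res$model, te$X)
    acc <- .head_accuracy(sc, te$Y)
    auc <- tryCatch(roc_auc(sc["malignancy", ], te$Y["malignancy", ]),
                    error = function(e) NA_real_)
    out[[i]] <- data.frame(
      run = if (is.null(names(runs)[i]) || names(runs)[i] == "") paste0("Run", i)
            else names(runs)[i],
      optimizer = cfg$optimizer, clr = cfg$use_clr, swa = cfg$use_swa,
      test_accuracy = acc[["malignancy"]], test_auc = auc)
  }
  do.call(rbind, out)
}
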