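#' @title Hierarchical multi-task network architectures
#' @name hsnet
#' @description
#' Two hierarchical architectures for nodule volumes. The HSCNN baseline
#' uses a single shared 3D convolutional feature extractor feeding five
#' semantic binary tasks; HSNet uses five per-attribute extractors with
#' deeper convolutional stacks. In both, a malignancy head consumes the
#' concatenation of the five branch feature vectors (tapped at the
#' activation output, before dropout) and the five semantic probabilities,
#' so the semantic predictions are produced before, and independently of,
#' the malignancy prediction.
NULL

#' Architecture configuration
#'
#' Each convolutional block is convolution (3x3x3, same padding) -> batch
#' normalization -> ReLU -> dropout -> max-pool (2, stride 2). Branch
#' features are tapped at the activation output of the branch dense layer,
#' before dropout.
#'
#' @param arch `"hsnet"` (five separate extractors, 3 blocks) or `"hscnn"`
#'   (one shared extractor, 2 blocks). Individual fields below override.
#' @param patch_size Input cube edge in voxels.
#' @param conv_blocks Number of conv blocks per branch extractor.
#' @param filters Filters for each block (first `conv_blocks` entries used).
#' @param branch_feature_dim Width of the branch dense feature vector.
#' @param dropout_rate Dropout fraction.
#' @param shared_extractor If `TRUE`, all five branches share one extractor.
#' @param malignancy_head_dim Hidden width of the fused malignancy head.
#' @param input_center,input_scale Input normalization `(x - center)/scale`
#'   applied before the first convolution (HU-like units).
#' @return Object of class `arch_config`.
#' @export
arch_config <- function(arch = c("hsnet", "hscnn"),
                        patch_size = 32L,
                        conv_blocks = NULL,
                        filters = c(16L, 32L, 64L),
                        branch_feature_dim = 128L,
                        dropout_rate = 0.3,
                        shared_extractor = NULL,
                        malignancy_head_dim = 256L,
                        input_center = -400,
                        input_scale = 400) {
  arch <- match.arg(arch)
  if (is.null(conv_blocks)) conv_blocks <- if (arch == "hsnet") 3L else 2L
  if (is.null(shared_extractor)) shared_extractor <- arch == "hscnn"
  conv_blocks <- as.integer(conv_blocks)
  patch_size <- as.integer(patch_size)
  if (conv_blocks < 1L) stop("conv_blocks must be >= 1")
  if (length(filters) < conv_blocks) stop("need a filter count per conv block")
  sz <- patch_size
  for (b in seq_len(conv_blocks)) {
    if (sz < 2L) {
      stop("patch_size ", patch_size, " too small for the pooling pyramid: ",
           "block ", b, " would pool a ", sz, "-voxel edge")
    }
    sz <- sz %/% 2L
  }
  structure(list(arch = arch, patch_size = patch_size,
                 n_branches = 5L, conv_blocks = conv_blocks,
                 filters = as.integer(filters[seq_len(conv_blocks)]),
                 branch_feature_dim = as.integer(branch_feature_dim),
                 dropout_rate = dropout_rate,
                 shared_extractor = isTRUE(shared_extractor),
                 malignancy_head_dim = as.integer(malignancy_head_dim),
                 input_center = input_center, input_scale = input_scale),
            class = "arch_config")
}

.branch_names <- function() SEMANTIC_FEATURES

#' Build a model (initialized parameters + layer plans)
#'
#' @param cfg An [arch_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `hsnet_model`: `$cfg`, `$params` (named weight
#'   tensors, stable names across runs for a fixed config), `$buffers`
#'   (batch-norm running statistics), `$plans` (gather index plans).
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "arch_config"))
  set.seed(seed)
  D <- cfg$patch_size
  nb <- cfg$conv_blocks
  n_ext <- if (cfg$shared_extractor) 1L else 5L
  params <- list()
  buffers <- list()
  plans <- list(conv = vector("list", nb), pool = vector("list", nb))
  sz <- D
  in_ch <- 1L
  for (b in seq_len(nb)) {
    out_ch <- cfg$filters[b]
    plans$conv[[b]] <- conv_plan(sz, in_ch)
    plans$pool[[b]] <- pool_plan(sz, out_ch)
    sz <- sz %/% 2L
    in_ch <- out_ch
  }
  flat_dim <- in_ch * sz^3
  for (e in seq_len(n_ext)) {
    pe <- paste0("ext", e)
    in_ch <- 1L
    for (b in seq_len(nb)) {
      out_ch <- cfg$filters[b]
      fan_in <- in_ch * 27L
      params[[paste0(pe, ".block", b, ".conv.W")]] <- he_init(out_ch, fan_in, fan_in)
      params[[paste0(pe, ".block", b, ".conv.b")]] <- numeric(out_ch)
      params[[paste0(pe, ".block", b, ".bn.gamma")]] <- rep(1, out_ch)
      params[[paste0(pe, ".block", b, ".bn.beta")]] <- numeric(out_ch)
      buffers[[paste0(pe, ".block", b, ".bn.mean")]] <- numeric(out_ch)
      buffers[[paste0(pe, ".block", b, ".bn.var")]] <- rep(1, out_ch)
      in_ch <- out_ch
    }
    params[[paste0(pe, ".dense.W")]] <- he_init(cfg$branch_feature_dim, flat_dim, flat_dim)
    params[[paste0(pe, ".dense.b")]] <- numeric(cfg$branch_feature_dim)
  }
  for (s in .branch_names()) {
    params[[paste0("head.", s, ".W")]] <-
      he_init(1L, cfg$branch_feature_dim, cfg$branch_feature_dim)
    params[[paste0("head.", s, ".b")]] <- numeric(1)
  }
  fus_in <- 5L * cfg$branch_feature_dim + 5L
  params[["fusion.dense.W"]] <- he_init(cfg$malignancy_head_dim, fus_in, fus_in)
  params[["fusion.dense.b"]] <- numeric(cfg$malignancy_head_dim)
  params[["fusion.out.W"]] <- he_init(1L, cfg$malignancy_head_dim, cfg$malignancy_head_dim)
  params[["fusion.out.b"]] <- numeric(1)
  structure(list(cfg = cfg, params = params, buffers = buffers,
                 plans = plans, flat_dim = flat_dim),
            class = "hsnet_model")
}

# forward through one extractor (fused compiled conv stack + R dense layer);
# returns feature matrix (f x B) and caches
.extractor_forward <- function(model, pe, X, training, keep_cache, dropout_rate,
                               momentum = 0.1) {
  cfg <- model$cfg
  p <- model$params
  buf <- model$buffers
  nb <- cfg$conv_blocks
  B <- ncol(X)
  blocks <- vector("list", nb)
  for (b in seq_len(nb)) {
    cp <- model$plans$conv[[b]]
    pp <- model$plans$pool[[b]]
    nm <- function(x) paste0(pe, ".block", b, ".", x)
    ch <- cfg$filters[b]
    ds <- numeric(0)
    if (training && dropout_rate > 0) {
      # channelwise (spatial) dropout: whole feature maps per sample
      ds <- as.vector((stats::runif(ch * B) >= dropout_rate) / (1 - dropout_rate))
    }
    blocks[[b]] <- list(W = p[[nm("conv.W")]], b = p[[nm("conv.b")]],
                        gamma = p[[nm("bn.gamma")]], beta = p[[nm("bn.beta")]],
                        run_mean = buf[[nm("bn.mean")]],
                        run_var = buf[[nm("bn.var")]],
                        K = cp$K, ov = cp$ov, n_in = cp$n_in,
                        D = cp$D, in_ch = cp$in_ch,
                        pool_idx = pp$idx, pool_n_out = pp$n_out,
                        drop_scale = ds)
  }
  ext <- .cpp_ext_fw(X, blocks, training, 1e-5)
  new_buf <- list()
  if (training) {
    for (b in seq_len(nb)) {
      nm <- function(x) paste0(pe, ".block", b, ".", x)
      nvox <- model$plans$conv[[b]]$ov * B
      new_buf[[nm("bn.mean")]] <-
        (1 - momentum) * buf[[nm("bn.mean")]] + momentum * ext$mu[[b]]
      new_buf[[nm("bn.var")]] <-
        (1 - momentum) * buf[[nm("bn.var")]] +
        momentum * ext$var[[b]] * nvox / max(nvox - 1, 1)
    }
  }
  A <- ext$out
  pre <- p[[paste0(pe, ".dense.W")]] %*% A + p[[paste0(pe, ".dense.b")]]
  # dense layers use a leaky activation (slope 0.01): unlike the batch-
  # normalized conv blocks they have no mechanism to revive dead units
  feat <- leaky_relu(pre)                  # tap point: activation output
  caches <- NULL
  if (keep_cache) {
    caches <- list(blocks = blocks, cpp = ext$cache,
                   dense_in = A, dense_grad = leaky_grad(pre))
  }
  list(feat = feat, caches = caches, new_buf = new_buf)
}

#' Forward pass: six per-sample probabilities
#'
#' @param model An `hsnet_model`.
#' @param X Either a `(patch_size^3) x batch` matrix, a 4D array
#'   `(D, D, D, batch)`, or a list of `volume_sample`s.
#' @param training Logical; enables batch-statistics batch norm and
#'   dropout. Inference (`FALSE`) is deterministic.
#' @param keep_cache Internal; retain intermediate values for the backward
#'   pass.
#' @return For `keep_cache = FALSE`, a `6 x batch` matrix of probabilities
#'   with rows `calcification, margin, sphericity, subtlety, texture,
#'   malignancy`. Otherwise a list with `probs`, `cache`, `buffers`.
#' @export
model_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  stopifnot(inherits(model, "hsnet_model"))
  cfg <- model$cfg
  X <- .as_batch_matrix(X, cfg$patch_size)
  Xn <- (X - cfg$input_center) / cfg$input_scale
  p <- model$params
  rate <- cfg$dropout_rate
  momentum <- if (is.null(model$bn_momentum)) 0.1 else model$bn_momentum
  branches <- .branch_names()
  feats <- vector("list", 5L)
  head_z <- vector("list", 5L)
  probs_s <- vector("list", 5L)
  caches <- if (keep_cache) list(ext = list(), head_drop = list()) else NULL
  new_buf <- NULL
  shared <- cfg$shared_extractor
  ext_out <- NULL
  for (i in seq_along(branches)) {
    pe <- if (shared) "ext1" else paste0("ext", i)
    if (shared && !is.null(ext_out)) {
      ef <- ext_out
    } else {
      ef <- .extractor_forward(model, pe, Xn, training, keep_cache, rate,
                               momentum = momentum)
      if (shared) ext_out <- ef
      if (is.null(new_buf)) new_buf <- ef$new_buf else new_buf <- c(new_buf, ef$new_buf)
    }
    feats[[i]] <- ef$feat
    hd <- dropout_forward(ef$feat, rate, training)
    z <- p[[paste0("head.", branches[i], ".W")]] %*% hd$out +
      p[[paste0("head.", branches[i], ".b")]]
    head_z[[i]] <- z
    probs_s[[i]] <- sigmoid(z)
    if (keep_cache) {
      caches$ext[[i]] <- ef$caches
      caches$head_drop[[i]] <- list(out = hd$out, mask = hd$mask)
    }
  }
  Fmat <- do.call(rbind, c(feats, probs_s))
  m_pre <- p[["fusion.dense.W"]] %*% Fmat + p[["fusion.dense.b"]]
  m_act <- leaky_relu(m_pre)
  m_dr <- dropout_forward(m_act, rate, training)
  z_m <- p[["fusion.out.W"]] %*% m_dr$out + p[["fusion.out.b"]]
  p_m <- sigmoid(z_m)
  probs <- rbind(do.call(rbind, probs_s), p_m)
  rownames(probs) <- ALL_FEATURES
  if (!keep_cache && !training) return(probs)
  if (!keep_cache) return(list(probs = probs, cache = NULL, buffers = new_buf))
  caches$Xn <- Xn
  caches$feats <- feats
  caches$probs_s <- probs_s
  caches$Fmat <- Fmat
  caches$m_grad <- leaky_grad(m_pre)
  caches$m_drop <- m_dr
  caches$p_m <- p_m
  list(probs = probs, cache = caches, buffers = new_buf)
}

# gradient of the weighted multi-task binary cross-entropy w.r.t. all
# parameters; fw is the output of model_forward(keep_cache = TRUE)
model_backward <- function(model, fw, Y, weights = rep(1, 6)) {
  cfg <- model$cfg
  p <- model$params
  ca <- fw$cache
  B <- ncol(ca$Fmat)
  branches <- .branch_names()
  grads <- list()
  gadd <- function(nm, g) {
    if (is.null(grads[[nm]])) grads[[nm]] <<- g else grads[[nm]] <<- grads[[nm]] + g
  }
  # malignancy head
  dzm <- weights[6] * (fw$cache$p_m - Y["malignancy", , drop = FALSE]) / B
  gadd("fusion.out.W", tcrossprod(dzm, ca$m_drop$out))
  gadd("fusion.out.b", sum(dzm))
  dmd <- crossprod(p[["fusion.out.W"]], dzm)
  if (!is.null(ca$m_drop$mask)) dmd <- dmd * ca$m_drop$mask
  dm_pre <- dmd * ca$m_grad
  gadd("fusion.dense.W", tcrossprod(dm_pre, ca$Fmat))
  gadd("fusion.dense.b", rowSums(dm_pre))
  dF <- crossprod(p[["fusion.dense.W"]], dm_pre)
  f <- cfg$branch_feature_dim
  shared <- cfg$shared_extractor
  dfeats <- vector("list", 5L)
  for (i in seq_along(branches)) {
    s <- branches[i]
    p_s <- ca$probs_s[[i]]
    dp_fusion <- dF[5L * f + i, , drop = FALSE]
    dz_s <- weights[i] * (p_s - Y[s, , drop = FALSE]) / B +
      dp_fusion * p_s * (1 - p_s)
    hd <- ca$head_drop[[i]]
    gadd(paste0("head.", s, ".W"), tcrossprod(dz_s, hd$out))
    gadd(paste0("head.", s, ".b"), sum(dz_s))
    dfeat_head <- crossprod(p[[paste0("head.", s, ".W")]], dz_s)
    if (!is.null(hd$mask)) dfeat_head <- dfeat_head * hd$mask
    dfeats[[i]] <- dfeat_head + dF[((i - 1L) * f + 1L):(i * f), , drop = FALSE]
  }
  if (shared) {
    # one physical extractor: sum the five branch contributions
    .extractor_backward(model, "ext1", ca$ext[[1]], Reduce(`+`, dfeats), gadd, B)
  } else {
    for (i in seq_along(branches)) {
      .extractor_backward(model, paste0("ext", i), ca$ext[[i]], dfeats[[i]],
                          gadd, B)
    }
  }
  # release the native activation caches now: they are invisible to R's
  # allocator, so waiting for garbage collection lets them pile up
  for (cc in ca$ext) {
    if (!is.null(cc$cpp)) .cpp_free_cache(cc$cpp)
  }
  grads
}

.extractor_backward <- function(model, pe, cache, dfeat, gadd, B) {
  p <- model$params
  dpre <- dfeat * cache$dense_grad
  gadd(paste0(pe, ".dense.W"), tcrossprod(dpre, cache$dense_in))
  gadd(paste0(pe, ".dense.b"), rowSums(dpre))
  dA <- crossprod(p[[paste0(pe, ".dense.W")]], dpre)
  bw <- .cpp_ext_bw(cache$cpp, dA, cache$blocks)
  for (b in seq_len(model$cfg$conv_blocks)) {
    nm <- function(x) paste0(pe, ".block", b, ".", x)
    gadd(nm("conv.W"), bw$dW[[b]])
    gadd(nm("conv.b"), bw$db[[b]])
    gadd(nm("bn.gamma"), bw$dgamma[[b]])
    gadd(nm("bn.beta"), bw$dbeta[[b]])
  }
  invisible(bw$dX)
}

#' Count trainable parameters
#'
#' Batch-norm running statistics are buffers, not trainable parameters, and
#' are excluded.
#'
#' @param model An `hsnet_model`.
#' @return Integer total across all weight tensors.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "hsnet_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the named weight tensors,
#' batch-norm buffers and the architecture configuration; reloading is
#' bit-exact.
#'
#' @param model An `hsnet_model`.
#' @param path File path.
#' @param metadata Optional list stored alongside (epoch, notes, ...).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path, metadata = list()) {
  stopifnot(inherits(model, "hsnet_model"))
  saveRDS(list(cfg = model$cfg, params = model$params,
               buffers = model$buffers, metadata = metadata), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  m <- build_model(x$cfg, seed = 0L)
  m$params <- x$params
  m$buffers <- x$buffers
  m$metadata <- x$metadata
  m
}

# coerce list-of-samples / 4D array / matrix into a (D^3 x B) matrix
.as_batch_matrix <- function(X, D) {
  if (is.list(X) && !is.matrix(X)) X <- stack_volumes(X)$X
  if (is.array(X) && length(dim(X)) == 4L) {
    dim(X) <- c(prod(dim(X)[1:3]), dim(X)[4])
  }
  if (is.array(X) && length(dim(X)) == 3L) dim(X) <- c(length(X), 1L)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (nrow(X) != D^3) {
    stop("input voxel count ", nrow(X), " does not match patch_size^3 = ", D^3)
  }
  X
}

#' Stack volume samples into model inputs
#'
#' @param samples List of `volume_sample` objects.
#' @return List with `X` (`D^3 x n` intensity matrix), `Y` (`6 x n` binary
#'   label matrix, rows in canonical feature order) and `ids`.
#' @export
stack_volumes <- function(samples) {
  n <- length(samples)
  stopifnot(n > 0)
  D3 <- length(samples[[1]]$intensities)
  X <- matrix(0, D3, n)
  Y <- matrix(0L, 6L, n, dimnames = list(ALL_FEATURES, NULL))
  for (i in seq_len(n)) {
    X[, i] <- as.vector(samples[[i]]$intensities)
    Y[, i] <- samples[[i]]$labels[ALL_FEATURES]
  }
  list(X = X, Y = Y, ids = vapply(samples, function(s) s$id, character(1)))
}
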