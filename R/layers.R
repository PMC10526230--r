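# Internal CPU neural-network primitives.
#
# Activations are stored as (channels * voxels) x batch matrices with the
# channel index fastest. 3D same-padding convolution is implemented as a
# gather (precomputed im2col indices, with one extra zero row standing in
# for padded positions) followed by a BLAS matrix multiply; max-pooling is
# a gather plus a running elementwise max. Index plans depend only on the
# spatial resolution and channel count, so they are built once per layer at
# model-construction time. The conv-block stack itself (conv -> batch norm
# -> ReLU -> channelwise dropout -> pool, with explicit backward passes)
# runs in fused single-precision compiled code; see src/nnops.cpp.

# layer plan for a 3^3 same-padding convolution at resolution D; the
# compiled kernels derive the unfold addressing from D and the channel
# count (zero-padded volume, offsets enumerated dx fastest, channels
# fastest within offset — the weight-matrix column order)
conv_plan <- function(D, in_ch) {
  list(K = in_ch * 27L, ov = D^3, n_in = in_ch * D^3,
       D = as.integer(D), in_ch = as.integer(in_ch))
}

# 2x2x2 stride-2 max-pool plan; odd trailing voxels are dropped
pool_plan <- function(D, ch) {
  Dp <- D %/% 2L
  Dp3 <- Dp^3
  pv <- arrayInd(seq_len(Dp3), c(Dp, Dp, Dp))
  off <- as.matrix(expand.grid(jx = 0:1, jy = 0:1, jz = 0:1))
  src <- matrix(0L, Dp3, 8L)
  for (j in 1:8) {
    src[, j] <- (2L * pv[, 1] - 1L + off[j, 1]) +
      (2L * pv[, 2] - 2L + off[j, 2]) * D +
      (2L * pv[, 3] - 2L + off[j, 3]) * D * D
  }
  Bm <- t(src)                                  # 8 x Dp3
  idx_arr <- array(0L, c(8L, ch, Dp3))
  for (c in seq_len(ch)) idx_arr[, c, ] <- (Bm - 1L) * ch + c
  list(idx = as.integer(idx_arr), Dp = Dp, n_out = ch * Dp3, n_in = ch * D^3)
}

# elementwise dropout for dense features; channelwise (spatial) dropout for
# conv activations, where `channels` gives the channel count of the
# channel-fastest layout and whole feature maps are dropped per sample
dropout_forward <- function(X, rate, training, channels = NULL) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  if (is.null(channels)) {
    mask <- (matrix(stats::runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  } else {
    mch <- (matrix(stats::runif(channels * ncol(X)), channels) >= rate) / (1 - rate)
    mask <- mch[rep_len(seq_len(channels), nrow(X)), , drop = FALSE]
  }
  list(out = X * mask, mask = mask)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

he_init <- function(nout, nin, fan_in) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / fan_in)), nout, nin)
}

# leaky rectifier for the dense layers (slope keeps gradients alive; the
# batch-normalized conv blocks use plain ReLU inside the compiled path)
leaky_relu <- function(x, alpha = 0.01) {
  neg <- x < 0
  x[neg] <- alpha * x[neg]
  x
}

leaky_grad <- function(x, alpha = 0.01) {
  g <- matrix(1, nrow(x), ncol(x))
  g[x < 0] <- alpha
  g
}
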