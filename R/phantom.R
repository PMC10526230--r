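#' @title Synthetic 3D nodule phantom generator
#' @name phantom
#' @description
#' Generates cubic CT-like intensity volumes containing one synthetic lung
#' nodule whose voxel appearance is monotonically controlled by the ordinal
#' semantic levels: sphericity sets the ellipsoid anisotropy, margin the
#' edge blur, subtlety the rim contrast over background, texture the
#' absolute core density (ground-glass to solid), calcification the
#' presence and pattern of hyperdense inclusions, and malignancy the nodule
#' size and spiculation. The generator stands in for real LIDC-derived
#' crops so every pipeline stage is testable without downloads; volumes in
#' the same NIfTI + CSV format produced here can be replaced by real crops.
NULL

#' Phantom generator configuration
#'
#' All per-level lookup tables are monotone in the stated direction.
#' Intensities are HU-like arbitrary units; normalization is the model's
#' concern, not the generator's.
#'
#' @param grid_size Voxels per cube edge (>= 16). Default 32.
#' @param background_mean,background_sd Background intensity mean / noise SD.
#' @param aspect_ratio Named-by-level ratio of largest to smallest ellipsoid
#'   semi-axis, per sphericity level 1..5 (decreasing to 1 = sphere).
#' @param edge_blur_sigma Gaussian boundary blur in voxels per margin level
#'   1..5 (decreasing: sharper margins at higher levels).
#' @param contrast Rim/shell contrast over background per subtlety level
#'   1..5 (increasing: more conspicuous nodules at higher levels).
#' @param core_density Absolute core intensity per texture level 1..5
#'   (increasing: ground-glass around -600 up to solid around 50).
#' @param radius_frac Nodule equivalent radius as a fraction of the grid
#'   half-width, per malignancy level 1..5 (increasing).
#' @param spike_amplitude Spiculation amplitude as a fraction of the nodule
#'   radius, per malignancy level 1..5 (increasing from 0).
#' @param spike_count Number of radial spikes per malignancy level 1..5.
#' @param calcification_intensity Intensity of hyperdense inclusions.
#' @param jitter Multiplicative jitter half-width applied to continuous
#'   render parameters within a level (levels overlap slightly so the
#'   learning task is non-degenerate).
#' @param level_probs Optional named list of categorical level priors per
#'   attribute (default uniform over each attribute's levels).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = 32L,
                           background_mean = -800,
                           background_sd = 50,
                           aspect_ratio = c(3.0, 2.2, 1.6, 1.25, 1.0),
                           edge_blur_sigma = c(1.8, 1.4, 1.0, 0.7, 0.4),
                           contrast = c(100, 200, 300, 450, 600),
                           core_density = c(-600, -450, -300, -150, 50),
                           radius_frac = c(0.24, 0.27, 0.30, 0.33, 0.36),
                           spike_amplitude = c(0, 0.07, 0.13, 0.21, 0.30),
                           spike_count = c(0L, 2L, 4L, 7L, 10L),
                           calcification_intensity = 800,
                           jitter = 0.10,
                           level_probs = NULL) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 16L) stop("grid_size must be >= 16")
  stopifnot(all(is.finite(c(background_mean, background_sd, aspect_ratio,
                            edge_blur_sigma, contrast, core_density,
                            radius_frac, spike_amplitude,
                            calcification_intensity))))
  chk_mono <- function(x, dir, nm) {
    d <- diff(x)
    ok <- if (dir > 0) all(d > 0) else all(d < 0)
    if (!ok) stop("per-level table '", nm, "' must be strictly monotone")
  }
  chk_mono(aspect_ratio, -1, "aspect_ratio")
  chk_mono(edge_blur_sigma, -1, "edge_blur_sigma")
  chk_mono(contrast, +1, "contrast")
  chk_mono(core_density, +1, "core_density")
  chk_mono(radius_frac, +1, "radius_frac")
  if (any(diff(spike_amplitude) < 0)) stop("spike_amplitude must be non-decreasing")
  lev <- attribute_levels()
  if (is.null(level_probs)) level_probs <- list()
  for (f in names(level_probs)) {
    if (!f %in% ALL_FEATURES) stop("unknown attribute in level_probs: ", f)
    p <- level_probs[[f]]
    if (length(p) != lev[[f]] || any(p < 0) || sum(p) <= 0) {
      stop("level_probs$", f, " must be ", lev[[f]], " non-negative weights")
    }
  }
  structure(list(grid_size = grid_size, background_mean = background_mean,
                 background_sd = background_sd, aspect_ratio = aspect_ratio,
                 edge_blur_sigma = edge_blur_sigma, contrast = contrast,
                 core_density = core_density, radius_frac = radius_frac,
                 spike_amplitude = spike_amplitude,
                 spike_count = as.integer(spike_count),
                 calcification_intensity = calcification_intensity,
                 jitter = jitter, level_probs = level_probs),
            class = "phantom_config")
}

.jit <- function(x, frac) x * stats::runif(length(x), 1 - frac, 1 + frac)

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Draw an attribute set (ordinal levels plus realized render parameters)
#'
#' Ordinal levels are drawn from the configured categorical priors (default
#' uniform). The malignancy level additionally sets the nodule radius and
#' spiculation from their monotone tables. Continuous render parameters get
#' multiplicative jitter within a level. Deterministic given the RNG state.
#'
#' @param config A [phantom_config()].
#' @param seed Optional integer; when given, `set.seed(seed)` first.
#' @return Object of class `attribute_set`: `$ordinal` (named integer
#'   levels), `$labels` (binarized), `$realized` (continuous parameters).
#' @export
sample_attributes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  lev <- attribute_levels()
  ordinal <- vapply(ALL_FEATURES, function(f) {
    p <- config$level_probs[[f]]
    if (is.null(p)) p <- rep(1, lev[[f]])
    sample.int(lev[[f]], 1L, prob = p)
  }, integer(1))
  names(ordinal) <- ALL_FEATURES
  j <- config$jitter
  D <- config$grid_size
  r <- .jit(config$radius_frac[ordinal[["malignancy"]]], j) * D / 2
  aspect <- .jit(config$aspect_ratio[ordinal[["sphericity"]]], j)
  aspect <- max(aspect, 1.0)
  # oblate ellipsoid: two long axes, one short; largest/smallest ratio = aspect
  semi_axes <- r * c(aspect^(1 / 3), aspect^(1 / 3), aspect^(-2 / 3))
  amp <- .jit(config$spike_amplitude[ordinal[["malignancy"]]], j)
  n_spikes <- config$spike_count[ordinal[["malignancy"]]]
  spike_dirs <- NULL
  if (n_spikes > 0L) {
    v <- matrix(stats::rnorm(3 * n_spikes), nrow = 3)
    spike_dirs <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  }
  calc <- .calc_pattern(ordinal[["calcification"]])
  realized <- list(
    semi_axes = semi_axes,
    rotation = .random_rotation(),
    blur_sigma = .jit(config$edge_blur_sigma[ordinal[["margin"]]], j),
    contrast = .jit(config$contrast[ordinal[["subtlety"]]], j),
    core_density = .jit(config$core_density[ordinal[["texture"]]], j),
    spike_amplitude = amp,
    spike_dirs = spike_dirs,
    calc = calc
  )
  structure(list(ordinal = ordinal, labels = binarize(as.list(ordinal)),
                 realized = realized),
            class = "attribute_set")
}

# hyperdense inclusion layout in normalized (unit-radius) nodule coordinates
.calc_pattern <- function(level) {
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  switch(level,
    { # 1: popcorn - several small lumps scattered in the core
      ctr <- t(vapply(1:4, function(i) rand_dir() * stats::runif(1, 0.05, 0.35),
                      numeric(3)))
      list(type = "lumps", centers = ctr, radii = rep(0.13, 4))
    },
    list(type = "shell", inner = 0.40, outer = 0.52),           # 2: laminated
    list(type = "lumps", centers = matrix(0, 1, 3), radii = 0.45), # 3: solid
    list(type = "lumps", centers = matrix(rand_dir() * 0.30, 1, 3),
         radii = 0.20),                                          # 4: non-central
    list(type = "lumps", centers = matrix(0, 1, 3), radii = 0.20), # 5: central
    list(type = "none")                                          # 6: absent
  )
}

#' Separable 3D Gaussian blur
#'
#' @param arr Cubic 3D array.
#' @param sigma Gaussian SD in voxels; `sigma <= 0` returns `arr` unchanged.
#' @return Blurred array of the same shape.
#' @keywords internal
blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  D <- dim(arr)[1]
  i <- seq_len(D)
  K <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  K[abs(outer(i, i, "-")) > ceiling(3 * sigma)] <- 0
  K <- K / rowSums(K)
  for (ax in 1:3) {
    m <- matrix(arr, D, D * D)       # blur along first axis
    arr <- array(K %*% m, dim = c(D, D, D))
    arr <- aperm(arr, c(2, 3, 1))    # cycle axes; 3 cycles = identity
  }
  arr
}

#' Render a nodule volume from an attribute set
#'
#' The nodule is a two-zone ellipsoid over a Gaussian background: an inner
#' core (normalized radius <= 0.55) at the texture-controlled core density
#' and an outer shell at background + subtlety-controlled contrast. Radial
#' spikes perturb the boundary, the boundary field is smoothed with the
#' margin-controlled sigma, and hyperdense inclusions are added unless the
#' calcification level is 6 (absent). Noise is added last.
#'
#' @param attrs An `attribute_set` from [sample_attributes()].
#' @param config The matching [phantom_config()].
#' @param id Sample identifier string.
#' @return Object of class `volume_sample`: `$intensities` (cubic array),
#'   `$attrs`, `$labels`, `$id`, `$provenance` ("original").
#' @export
render_volume <- function(attrs, config, id = "sample") {
  stopifnot(inherits(attrs, "attribute_set"), inherits(config, "phantom_config"))
  D <- config$grid_size
  rl <- attrs$realized
  max_extent <- max(rl$semi_axes) * (1 + rl$spike_amplitude)
  if (max_extent > D / 2 - 1.5) {
    stop("nodule (extent ", round(max_extent, 2),
         " voxels) does not fit in grid of size ", D)
  }
  ctr <- (D + 1) / 2
  g <- seq_len(D) - ctr
  P <- rbind(rep(g, times = D * D),
             rep(rep(g, each = D), times = D),
             rep(g, each = D * D))            # 3 x D^3 voxel offsets
  U <- crossprod(rl$rotation, P)              # ellipsoid frame
  W <- U / rl$semi_axes                       # normalized coordinates
  rho <- sqrt(colSums(W^2))
  boundary <- 1
  if (rl$spike_amplitude > 0 && !is.null(rl$spike_dirs)) {
    uhat <- W / pmax(rho, 1e-9)[col(W)]
    dim(uhat) <- dim(W)
    s <- numeric(length(rho))
    for (k in seq_len(ncol(rl$spike_dirs))) {
      proj <- colSums(uhat * rl$spike_dirs[, k])
      s <- s + pmax(proj, 0)^24
    }
    boundary <- 1 + rl$spike_amplitude * pmin(s, 1)
  }
  core <- rho <= 0.55
  shell <- !core & rho <= boundary
  field <- numeric(D^3)
  field[core] <- rl$core_density - config$background_mean
  field[shell] <- rl$contrast
  field <- blur3d(array(field, dim = c(D, D, D)), rl$blur_sigma)
  img <- config$background_mean + field
  # hyperdense inclusions, rendered after edge blur so calcification peaks
  # are not erased by poorly-defined margins (own mild blur of 0.5 voxels)
  if (attrs$ordinal[["calcification"]] != 6L) {
    cmask <- .calc_mask(attrs, rho, W, D)
    cmask <- blur3d(array(cmask, dim = c(D, D, D)), 0.5)
    tgt <- config$background_mean +
      cmask * (config$calcification_intensity - config$background_mean)
    idx <- which(cmask > 0.02)
    img[idx] <- pmax(img[idx], tgt[idx])
  }
  img <- img + stats::rnorm(D^3, 0, config$background_sd)
  structure(list(intensities = array(img, dim = c(D, D, D)),
                 attrs = attrs, labels = attrs$labels, id = id,
                 provenance = "original"),
            class = "volume_sample")
}

.calc_mask <- function(attrs, rho, W, D) {
  calc <- attrs$realized$calc
  m <- numeric(D^3)
  if (calc$type == "shell") {
    m[rho >= calc$inner & rho <= calc$outer] <- 1
  } else if (calc$type == "lumps") {
    for (k in seq_len(nrow(calc$centers))) {
      d2 <- colSums((W - calc$centers[k, ])^2)
      m[d2 <= calc$radii[k]^2] <- 1
    }
  }
  m
}

#' Generate a phantom dataset on disk (NIfTI volumes + CSV label table)
#'
#' Re-running with the same seed reproduces a byte-identical label table
#' and voxel-identical volumes.
#'
#' @param n Number of samples (>= 1).
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer RNG seed.
#' @return The manifest (invisibly): list with `files`, `labels_csv`,
#'   `manifest_json`, `seed`, `config_hash`, `n`. Also written as JSON.
#' @export
generate_dataset <- function(n, config, out_dir, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ids <- sprintf("nod%04d", seq_len(n))
  files <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- sample_attributes(config)
    v <- render_volume(a, config, id = ids[i])
    f <- file.path(out_dir, paste0(ids[i], ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(v$intensities), f)
    files[i] <- f
    rows[[i]] <- data.frame(id = ids[i], t(a$ordinal))
  }
  labels <- do.call(rbind, rows)
  csv <- file.path(out_dir, "labels.csv")
  write_label_table(labels, csv)
  manifest <- list(n = n, seed = seed, config_hash = config_hash(config),
                   files = basename(files), labels_csv = basename(csv))
  mj <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mj, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest, list(dir = out_dir, manifest_json = mj)))
}

#' Generate an in-memory phantom dataset
#'
#' Convenience form of [generate_dataset()] that skips disk IO; used by the
#' training and cross-validation tests.
#'
#' @inheritParams generate_dataset
#' @return List of `volume_sample` objects.
#' @export
generate_samples <- function(n, config, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  set.seed(seed)
  lapply(seq_len(as.integer(n)), function(i) {
    a <- sample_attributes(config)
    render_volume(a, config, id = sprintf("nod%04d", i))
  })
}

#' Hash of a phantom configuration (for dataset manifests)
#' @param config A [phantom_config()].
#' @return Character MD5 digest.
#' @keywords internal
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Per-attribute diagnostic image statistics
#'
#' Computes, from voxel intensities alone, one scalar statistic per
#' attribute oriented so that larger values correspond to higher ordinal
#' levels:
#' \itemize{
#'   \item sphericity: smallest/largest principal second moment of the
#'     thresholded nodule mask (1 for a sphere);
#'   \item margin: negative edge width, measured as the trimmed mean over
#'     ~500 radial rays of the distance between the 80% and 20% contrast
#'     crossings of the outer boundary profile;
#'   \item subtlety: rim-zone mean intensity minus background;
#'   \item texture: core intensity extrapolated to the nodule centre
#'     (intercept of intensity vs squared normalized radius, hyperdense
#'     voxels excluded), robust against edge-blur bleed and calcification;
#'   \item calcification: negative peak intensity (level 6 = no hyperdense
#'     inclusion, hence the highest statistic);
#'   \item malignancy: thresholded nodule mask volume.
#' }
#' Geometry (centroid, principal axes, normalized radius) is estimated by a
#' second-moment fit of the thresholded mask; nothing uses the stored
#' attribute values. These statistics back the monotone-discriminability
#' checks that guarantee the phantom learning task is solvable.
#'
#' @param vol A `volume_sample` (or plain cubic array).
#' @param config The [phantom_config()] used to generate it (background
#'   mean/SD only).
#' @return Named numeric vector with one statistic per attribute.
#' @export
phantom_statistics <- function(vol, config) {
  img <- if (inherits(vol, "volume_sample")) vol$intensities else vol
  D <- dim(img)[1]
  bg <- config$background_mean
  sm <- blur3d(img, 1.0)
  q97 <- stats::quantile(sm, 0.97, names = FALSE)
  th <- bg + max(50, 0.4 * (q97 - bg))
  mask <- sm > th
  if (sum(mask) < 20) mask <- sm > (bg + 40)
  if (sum(mask) < 8) {
    # degenerate mask (vanishing nodule): fall back to a central ball
    ctr0 <- (D + 1) / 2
    g0 <- seq_len(D) - ctr0
    r2 <- outer(outer(g0^2, g0^2, "+"), g0^2, "+")
    mask <- array(r2 <= (D / 4)^2, dim = dim(img))
  }
  idx <- which(mask)
  co <- arrayInd(idx, dim(img))
  ctr <- colMeans(co)
  Xc <- sweep(co, 2, ctr)
  S <- crossprod(Xc) / nrow(Xc)
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-6)
  axes <- sqrt(5 * lam)              # solid ellipsoid: cov = diag(a_i^2 / 5)
  g <- seq_len(D)
  P <- rbind(rep(g, times = D * D) - ctr[1],
             rep(rep(g, each = D), times = D) - ctr[2],
             rep(g, each = D * D) - ctr[3])
  rho <- sqrt(colSums((crossprod(ev$vectors, P) / axes)^2))
  # texture: calcification-excluded core intensity extrapolated to rho = 0
  sel <- which(rho <= 0.5 & img < 200)
  if (length(sel) < 10) sel <- which(rho <= 0.5)
  if (length(sel) < 10) sel <- order(rho)[1:10]
  fit <- stats::lm.fit(cbind(1, rho[sel]^2), img[sel])
  core_value <- fit$coefficients[1]
  rim <- rho >= 0.55 & rho <= 0.90
  rim_vals <- img[rim]
  rim_vals <- rim_vals[rim_vals < 350]
  rim_mean <- if (length(rim_vals) >= 5) mean(rim_vals) else bg
  c(sphericity = min(lam) / max(lam),
    margin = -.edge_width(sm, D, bg),
    subtlety = rim_mean - bg,
    texture = unname(core_value),
    calcification = -max(img),
    malignancy = sum(mask))
}

# deterministic quasi-uniform unit directions (Fibonacci sphere)
.fib_sphere <- function(nd) {
  i <- seq_len(nd) - 0.5
  phi <- acos(1 - 2 * i / nd)
  theta <- pi * (1 + sqrt(5)) * i
  rbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# outer-boundary edge width in voxels: per radial ray from the grid centre,
# the distance between the interpolated 80% and 20% contrast crossings
# around the outermost 50% crossing; trimmed mean over rays
.edge_width <- function(sm, D, bg, n_rays = 500L) {
  smc <- pmin(sm, 350)               # clamp calcifications
  ctr <- (D + 1) / 2
  dirs <- .fib_sphere(n_rays)
  steps <- seq(1.5, D / 2 - 1, by = 0.25)
  ns <- length(steps)
  cc <- dirs[, rep(seq_len(n_rays), each = ns)] * rep(steps, n_rays)
  cc <- round(cc + ctr)
  cc[cc < 1] <- 1
  cc[cc > D] <- D
  V <- matrix(smc[cbind(cc[1, ], cc[2, ], cc[3, ])], ns, n_rays)
  contrast <- max(stats::quantile(smc, 0.97, names = FALSE) - bg, 50)
  lo <- bg + 0.2 * contrast
  mid <- bg + 0.5 * contrast
  hi <- bg + 0.8 * contrast
  widths <- rep(NA_real_, n_rays)
  xing <- function(v, i1, i2, level) {
    if (v[i2] == v[i1]) return(steps[i1])
    steps[i1] + (level - v[i1]) / (v[i2] - v[i1]) * (steps[i2] - steps[i1])
  }
  for (k in seq_len(n_rays)) {
    v <- V[, k]
    below <- v < mid
    if (all(below) || all(!below)) next
    ci <- max(which(!below))
    if (ci >= ns) next
    hin <- which(v[1:ci] >= hi)
    if (!length(hin) || max(hin) >= ns) next
    hi_i <- max(hin)
    lon <- which(v[ci:ns] <= lo)
    if (!length(lon)) next
    lo_i <- ci + min(lon) - 1L
    if (lo_i <= 1L) next
    widths[k] <- max(xing(v, lo_i - 1L, lo_i, lo) - xing(v, hi_i, hi_i + 1L, hi),
                     0.05)
  }
  if (all(is.na(widths))) return(4)
  mean(widths, na.rm = TRUE, trim = 0.2)
}
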