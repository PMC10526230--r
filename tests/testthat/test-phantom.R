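cfg16 <- phantom_config(grid_size = 16L)

test_that("attribute sampling is seed-deterministic with monotone malignancy tables", {
  a1 <- sample_attributes(cfg16, seed = 5)
  a2 <- sample_attributes(cfg16, seed = 5)
  expect_identical(a1, a2)
  cfg <- phantom_config()
  # malignancy level 5 has strictly larger spiculation amplitude and radius
  # than level 1 under the default monotone tables
  lo <- phantom_config(level_probs = list(
    malignancy = c(1, 0, 0, 0, 0)))
  hi <- phantom_config(level_probs = list(
    malignancy = c(0, 0, 0, 0, 1)))
  set.seed(1)
  for (k in 1:10) {
    al <- sample_attributes(lo)
    ah <- sample_attributes(hi)
    expect_gt(ah$realized$spike_amplitude, al$realized$spike_amplitude)
    expect_gt(prod(ah$realized$semi_axes), prod(al$realized$semi_axes))
  }
  # stored labels equal binarize of stored ordinals
  set.seed(2)
  for (k in 1:20) {
    a <- sample_attributes(cfg16)
    expect_identical(a$labels, binarize(as.list(a$ordinal)))
  }
})

test_that("default-uniform level frequencies stay within 3 binomial SDs", {
  cfg <- cfg16
  set.seed(9)
  n <- 10000
  lev <- replicate(n, sample_attributes(cfg)$ordinal[["sphericity"]])
  freq <- tabulate(lev, 5) / n
  bound <- 3 * sqrt(0.2 * 0.8 / n)
  expect_true(all(abs(freq - 0.2) <= bound))
})

test_that("rendering respects calcification absence, sphericity and core density", {
  # calcification level 6: no hyperdense inclusion anywhere near its intensity
  cfg <- phantom_config()
  a <- sample_attributes(phantom_config(level_probs = list(
    calcification = c(0, 0, 0, 0, 0, 1))), seed = 11)
  v <- render_volume(a, cfg)
  expect_lt(max(v$intensities), cfg$calcification_intensity - 100)
  # a spherical, sharp, solid, benign nodule: thresholded mask second
  # moments are near-isotropic
  sph_cfg <- phantom_config(level_probs = list(
    sphericity = c(0, 0, 0, 0, 1), margin = c(0, 0, 0, 0, 1),
    malignancy = c(1, 0, 0, 0, 0), subtlety = c(0, 0, 0, 0, 1),
    calcification = c(0, 0, 0, 0, 0, 1)))
  set.seed(3)
  a <- sample_attributes(sph_cfg)
  v <- render_volume(a, sph_cfg)
  s <- phantom_statistics(v, sph_cfg)
  expect_gte(s[["sphericity"]], 1 / 1.15)   # max/min moment ratio <= 1.15
  # eroded-core mean is within 3 * background_sd / sqrt(n_core) of the
  # configured core density (sharp margin, large nodule: no blur bleed)
  core_cfg <- phantom_config(level_probs = list(
    margin = c(0, 0, 0, 0, 1), malignancy = c(0, 0, 0, 0, 1),
    calcification = c(0, 0, 0, 0, 0, 1)))
  set.seed(4)
  for (k in 1:5) {
    a <- sample_attributes(core_cfg)
    v <- render_volume(a, core_cfg)
    D <- core_cfg$grid_size
    rl <- a$realized
    g <- seq_len(D) - (D + 1) / 2
    P <- rbind(rep(g, times = D * D), rep(rep(g, each = D), times = D),
               rep(g, each = D * D))
    rho <- sqrt(colSums((crossprod(rl$rotation, P) / rl$semi_axes)^2))
    core <- rho <= 0.35   # eroded interior of the 0.55 core zone
    tol <- 3 * core_cfg$background_sd / sqrt(sum(core))
    expect_lt(abs(mean(v$intensities[core]) - rl$core_density), tol + 6)
  }
})

test_that("higher subtlety gives larger nodule-to-background contrast, same seed", {
  for (seed in c(2, 7)) {
    cfg_lo <- phantom_config(level_probs = list(subtlety = c(1, 0, 0, 0, 0),
                                                calcification = c(0, 0, 0, 0, 0, 1)))
    cfg_hi <- phantom_config(level_probs = list(subtlety = c(0, 0, 0, 0, 1),
                                                calcification = c(0, 0, 0, 0, 0, 1)))
    a_lo <- sample_attributes(cfg_lo, seed = seed)
    a_hi <- sample_attributes(cfg_hi, seed = seed)
    v_lo <- render_volume(a_lo, cfg_lo)
    v_hi <- render_volume(a_hi, cfg_hi)
    nod_mean <- function(v, a, cfg) {
      D <- cfg$grid_size
      g <- seq_len(D) - (D + 1) / 2
      P <- rbind(rep(g, times = D * D), rep(rep(g, each = D), times = D),
                 rep(g, each = D * D))
      rho <- sqrt(colSums((crossprod(a$realized$rotation, P) /
                             a$realized$semi_axes)^2))
      mean(v$intensities[rho <= 1])
    }
    expect_gt(abs(nod_mean(v_hi, a_hi, cfg_hi) - cfg_hi$background_mean),
              abs(nod_mean(v_lo, a_lo, cfg_lo) - cfg_lo$background_mean))
  }
})

test_that("oversized nodules raise a sizing error instead of clipping", {
  tiny <- phantom_config(radius_frac = c(0.5, 0.55, 0.6, 0.65, 0.7),
                         level_probs = list(malignancy = c(0, 0, 0, 0, 1),
                                            sphericity = c(1, 0, 0, 0, 0)))
  set.seed(1)
  a <- sample_attributes(tiny)
  expect_error(render_volume(a, tiny), "does not fit")
})

test_that("dataset generation writes n volumes + labels and reproduces bytewise", {
  d1 <- file.path(tempdir(), "ph1")
  d2 <- file.path(tempdir(), "ph2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  man <- generate_dataset(8, cfg16, d1, seed = 21)
  expect_equal(man$n, 8L)
  expect_length(list.files(d1, pattern = "\\.nii\\.gz$"), 8L)
  labs <- read_label_table(file.path(d1, "labels.csv"))
  expect_equal(nrow(labs), 8L)
  expect_true(all(paste0("nod000", 1:8) == labs$id))
  # stored binary labels equal binarize of stored ordinals (already applied
  # by read_label_table; check against a fresh binarize call)
  fresh <- binarize(labs[, c("id", "malignancy", "margin", "sphericity",
                             "subtlety", "texture", "calcification")])
  expect_equal(labs$malignancy_bin, fresh$malignancy_bin)
  generate_dataset(8, cfg16, d2, seed = 21)
  expect_identical(readLines(file.path(d1, "labels.csv")),
                   readLines(file.path(d2, "labels.csv")))
  v1 <- RNifti::readNifti(file.path(d1, "nod0003.nii.gz"))
  v2 <- RNifti::readNifti(file.path(d2, "nod0003.nii.gz"))
  expect_identical(as.vector(as.array(v1)), as.vector(as.array(v2)))
  expect_error(generate_dataset(0, cfg16, d1), "n must be")
})

test_that("phantom configuration validates monotone tables and grid size", {
  expect_error(phantom_config(grid_size = 8), "grid_size")
  expect_error(phantom_config(contrast = c(100, 90, 300, 450, 600)), "monotone")
  expect_error(phantom_config(edge_blur_sigma = c(1, 2, 3, 4, 5)), "monotone")
  expect_error(phantom_config(level_probs = list(margin = c(1, 1))), "margin")
})
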