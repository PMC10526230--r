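#' @title Axis-symmetry data augmentation for cubic volumes
#' @name augment3d
#' @description
#' Training-set expansion by transposing and flipping the three axes of a
#' cubic volume. The admissible transforms form the 48-element symmetry
#' group of the cube (3! axis permutations times 2^3 flips). Labels and
#' attributes are carried over unchanged; test/validation samples are never
#' expanded.
NULL

#' Enumerate the 48 cube symmetries
#'
#' @return List of `symmetry_op` objects (fields `perm`, an axis
#'   permutation of 1:3, and `flip`, three logicals), identity first.
#' @export
enumerate_symmetries <- function() {
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  ops <- vector("list", 48L)
  i <- 0L
  for (p in perms) {
    for (f1 in c(FALSE, TRUE)) for (f2 in c(FALSE, TRUE)) for (f3 in c(FALSE, TRUE)) {
      i <- i + 1L
      ops[[i]] <- structure(list(perm = p, flip = c(f1, f2, f3)),
                            class = "symmetry_op")
    }
  }
  ops
}

#' Apply a cube symmetry to a volume
#'
#' The voxel array is permuted and flipped; labels, attributes and id are
#' copied unchanged and the voxel value multiset is preserved.
#'
#' @param vol A `volume_sample` or a plain cubic 3D array.
#' @param op A `symmetry_op` from [enumerate_symmetries()].
#' @return Transformed volume of the same type as the input.
#' @export
apply_symmetry <- function(vol, op) {
  stopifnot(inherits(op, "symmetry_op"))
  arr <- if (inherits(vol, "volume_sample")) vol$intensities else vol
  d <- dim(arr)
  if (length(d) != 3L || length(unique(d)) != 1L) {
    stop("apply_symmetry requires a cubic 3D volume")
  }
  arr <- aperm(arr, op$perm)
  D <- d[1]
  ix <- if (op$flip[1]) D:1 else 1:D
  iy <- if (op$flip[2]) D:1 else 1:D
  iz <- if (op$flip[3]) D:1 else 1:D
  arr <- arr[ix, iy, iz]
  if (inherits(vol, "volume_sample")) {
    vol$intensities <- arr
    return(vol)
  }
  arr
}

#' Compose two cube symmetries
#'
#' `compose_symmetries(a, b)` is the op equivalent to applying `b` first,
#' then `a`.
#'
#' @param a,b `symmetry_op` objects.
#' @return A `symmetry_op`.
#' @export
compose_symmetries <- function(a, b) {
  # applying b then a: x -> a(b(x)); track where each output axis reads from
  perm <- b$perm[a$perm]
  flip <- b$flip[a$perm] != a$flip
  structure(list(perm = perm, flip = flip), class = "symmetry_op")
}

#' Invert a cube symmetry
#' @param op A `symmetry_op`.
#' @return Its inverse `symmetry_op`.
#' @export
invert_symmetry <- function(op) {
  inv_perm <- order(op$perm)
  structure(list(perm = inv_perm, flip = op$flip[inv_perm]),
            class = "symmetry_op")
}

#' Expand a training set by random cube symmetries
#'
#' Each input sample yields `factor` outputs: the original plus
#' `factor - 1` distinct non-identity symmetries sampled without
#' replacement. The default factor of 6 gives the standard six-fold
#' training-set expansion. Output ordering is deterministic given the seed.
#' Expanded copies are tagged with `provenance = "augmented"` and keep an
#' `origin_id` so the cross-validation harness can assert that validation
#' and test sets were never expanded.
#'
#' @param samples List of `volume_sample` objects.
#' @param factor Total expansion factor, 1..48.
#' @param seed Integer RNG seed.
#' @return List of `factor * length(samples)` samples.
#' @export
expand_training_set <- function(samples, factor = 6L, seed = 1L) {
  factor <- as.integer(factor)
  if (factor < 1L || factor > 48L) stop("factor must be between 1 and 48")
  if (factor == 1L) return(samples)
  ops <- enumerate_symmetries()
  set.seed(seed)
  out <- vector("list", factor * length(samples))
  k <- 0L
  for (s in samples) {
    k <- k + 1L
    out[[k]] <- s
    chosen <- 1L + sample.int(47L, factor - 1L)  # non-identity, no replacement
    for (ci in chosen) {
      k <- k + 1L
      aug <- apply_symmetry(s, ops[[ci]])
      aug$provenance <- "augmented"
      aug$origin_id <- s$id
      aug$id <- paste0(s$id, "_aug", ci)
      out[[k]] <- aug
    }
  }
  out
}
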