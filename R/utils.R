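`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Linear-congruential mixing keeps derived seeds inside the 32-bit integer
#' range so they are valid arguments to [set.seed()]. Used wherever one master
#' seed must spawn independent per-subject or per-fold streams.
#'
#' @param master_seed Integer master seed.
#' @param index Integer stream index (>= 0).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- (abs(as.numeric(master_seed)) %% m)
  s <- (s * 48271 + as.numeric(index) * 1299721 + 12345) %% m
  as.integer(s %% (m - 2L) + 1)
}

#' Volume of a sphere from its diameter
#'
#' Convenience for relating clinical minimum lesion diameters to volumes:
#' a 3 mm diameter sphere has a volume of about 14 mm^3.
#'
#' @param diameter Sphere diameter (mm).
#' @return Volume in mm^3 (equivalently microlitres).
#' @export
sphere_volume <- function(diameter) {
  pi / 6 * diameter^3
}

#' Volume of the minimum admissible lesion
#'
#' The evaluation protocol discards connected components smaller than
#' `min_voxels` voxels; at a given voxel spacing that corresponds to a
#' physical volume in microlitres (3 uL at 1 mm isotropic, 3.6 uL at
#' 1 x 1 x 1.2 mm).
#'
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param min_voxels Minimum component size in voxels (default 3).
#' @return Volume in microlitres.
#' @export
min_lesion_volume_ul <- function(spacing, min_voxels = 3) {
  stopifnot(length(spacing) == 3, all(spacing > 0), min_voxels >= 1)
  min_voxels * prod(spacing)
}

# Reflection-pad a 3D array by `p` voxels per side along every axis
# (mirror without repeating the edge sample).
pad_reflect3d <- function(a, p) {
  if (p == 0) return(a)
  d <- dim(a)
  if (any(d < p + 1)) stop("array too small for reflection padding of ", p)
  ix <- lapply(d, function(n) c(seq(p + 1, 2), seq_len(n), seq(n - 1, n - p)))
  a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}
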