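# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: flood fill by frontier dilation in pure R,
# detection by pairwise voxel-set intersection, parameter counts by array
# sizes of the built model.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pure-R connected-component labelling by min-label propagation: every
# foreground voxel starts with a unique id; each sweep replaces a voxel's
# label by the minimum over itself and its foreground neighbors, until a
# fixpoint. Array-shift arithmetic only — no queues, nothing shared with the
# package's breadth-first C++ labelling.
flood_components_oracle <- function(mask, connectivity = 18) {
  d <- dim(mask)
  fg <- mask != 0
  lab <- array(0, d)
  lab[fg] <- seq_len(sum(fg))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  deg <- rowSums(abs(offs))
  maxdeg <- c(`6` = 1, `18` = 2, `26` = 3)[[as.character(connectivity)]]
  offs <- offs[deg > 0 & deg <= maxdeg, , drop = FALSE]
  src <- function(n, o) max(1, 1 - o):min(n, n - o)
  dst <- function(n, o) max(1, 1 + o):min(n, n + o)
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      o <- offs[i, ]
      sh <- array(0, d)
      sh[dst(d[1], o[1]), dst(d[2], o[2]), dst(d[3], o[3])] <-
        lab[src(d[1], o[1]), src(d[2], o[2]), src(d[3], o[3])]
      take <- fg & sh > 0 & sh < new
      new[take] <- sh[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # relabel to consecutive component ids
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

# Canonical form of a labelling: list of sorted voxel-index vectors, sorted
# by their first element, so two labelings can be compared exactly.
partition_of <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  parts <- lapply(ids, function(i) sort(which(lab == i)))
  parts[order(vapply(parts, `[`, numeric(1), 1))]
}

components_to_partition <- function(comps, dims) {
  parts <- lapply(comps, function(cm)
    sort(cm$voxels[, 1] + (cm$voxels[, 2] - 1L) * dims[1] +
           (cm$voxels[, 3] - 1L) * dims[1] * dims[2]))
  parts[order(vapply(parts, `[`, numeric(1), 1))]
}

# Detection oracle by joint voxel scan: paint component-id grids for both
# sides, collect the (gt id, pred id) pairs at overlapping voxels, and read
# off detections and false positives — a different route from the package's
# per-component mask lookups.
detection_oracle <- function(gt_comps, pred_comps) {
  dims <- attr(gt_comps, "dims") %||% attr(pred_comps, "dims")
  paint <- function(comps) {
    id <- array(0L, dims)
    for (i in seq_along(comps)) id[comps[[i]]$voxels] <- i
    id
  }
  gid <- paint(gt_comps)
  pid <- paint(pred_comps)
  both <- gid > 0L & pid > 0L
  hit_g <- unique(gid[both])
  hit_p <- unique(pid[both])
  list(detected = seq_along(gt_comps) %in% hit_g,
       false_positive = !(seq_along(pred_comps) %in% hit_p))
}

# Exact signed-rank distribution by enumerating all 2^n sign patterns.
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  all_v <- vapply(0:(2^n - 1), function(m)
    sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0]), numeric(1))
  p_ge <- mean(all_v >= V)
  p_le <- mean(all_v <= V)
  list(V = V, p = min(1, 2 * min(p_ge, p_le)))
}

# Random typed lesion mask on a small grid.
random_typed_mask <- function(dims = c(20, 20, 20), p_fg = 0.10,
                              p_cl = 0.3) {
  arr <- array(0L, dims)
  fg <- runif(prod(dims)) < p_fg
  arr[fg] <- ifelse(runif(sum(fg)) < p_cl, 2L, 1L)
  arr
}

# A minimal handcrafted subject case with known lesion components.
make_toy_case <- function(dims = c(48, 48, 48), lesions = list(),
                          spacing = c(1, 1, 1), subject_id = "toy",
                          site = "site1", base = 0, noise = 0.01,
                          lesion_intensity = 10) {
  lab <- array(0L, dims)
  for (ls in lesions) lab[ls$voxels] <- ls$label
  set.seed(1234)
  fl <- array(base + rnorm(prod(dims), 0, noise), dims)
  fl[lab != 0] <- fl[lab != 0] + lesion_intensity
  mp <- fl + rnorm(prod(dims), 0, noise)
  subject_case(subject_id,
               image_volume(fl, spacing, contrast = "FLAIR"),
               image_volume(mp, spacing, contrast = "MP2RAGE"),
               gt = label_volume(lab, spacing), site = site)
}

# Voxel matrix of an axis-aligned box [x0..x1, y0..y1, z0..z1].
box_voxels <- function(x, y, z) {
  as.matrix(expand.grid(x = x, y = y, z = z))
}

# Small phantom config shared by tests that need realistic cases quickly.
test_phantom_config <- function(dims = c(48, 48, 48), n_wml = 4, n_cl = 2,
                                seed = 1) {
  phantom_config(dims = dims, n_wml = n_wml, n_cl = n_cl,
                 wml_size_meanlog = log(15), cl_size_meanlog = log(8),
                 seed = seed)
}
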