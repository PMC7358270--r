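#' Configuration of the synthetic two-contrast phantom
#'
#' The phantom emulates the statistical structure of a clinical MS cohort
#' without any patient data: a nested-shell "brain" (an ellipsoidal cortex
#' ribbon of configurable thickness wrapped around a white-matter core),
#' ellipsoidal lesions with log-normal volumes truncated below at 3 voxels,
#' WMLs placed inside the core and CLs intersecting the ribbon, and additive
#' Gaussian noise per contrast. Tissue means encode the clinical contrast
#' ordering: WMLs are strongly hyperintense in the FLAIR-like channel while
#' CLs have low FLAIR contrast but a clearly larger contrast in the
#' MP2RAGE-like channel.
#'
#' @param dims Grid dimensions (default `c(96, 96, 96)`; each axis >= 32).
#' @param spacing Voxel size in mm (default 1 mm isotropic).
#' @param n_wml,n_cl Lesion counts (exact when generating a single phantom;
#'   Poisson means across a cohort).
#' @param wml_size_meanlog,wml_size_sdlog,cl_size_meanlog,cl_size_sdlog
#'   Log-normal lesion-volume parameters in voxels, truncated at `min_voxels`.
#' @param min_voxels Hard minimum lesion size (default 3 voxels).
#' @param tissue_intensities Named list with `flair` and `mp2rage` vectors of
#'   means for `background`, `wm`, `cortex`, `wml`, `cl`.
#' @param noise_sigma Additive Gaussian noise sd per contrast
#'   (`c(flair, mp2rage)`).
#' @param cortex_thickness Ribbon thickness in voxels.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(dims = c(96, 96, 96), spacing = c(1, 1, 1),
                           n_wml = 8, n_cl = 3,
                           wml_size_meanlog = log(25), wml_size_sdlog = 1.0,
                           cl_size_meanlog = log(10), cl_size_sdlog = 0.7,
                           min_voxels = 3,
                           tissue_intensities = list(
                             flair = c(background = 10, wm = 100, cortex = 80,
                                       wml = 180, cl = 95),
                             mp2rage = c(background = 10, wm = 120, cortex = 70,
                                         wml = 150, cl = 110)),
                           noise_sigma = c(flair = 5, mp2rage = 5),
                           cortex_thickness = 3, seed = 1) {
  if (any(dims < 32)) stop("each phantom axis must be >= 32 voxels")
  ti <- tissue_intensities
  need <- c("background", "wm", "cortex", "wml", "cl")
  stopifnot(all(need %in% names(ti$flair)), all(need %in% names(ti$mp2rage)))
  cl_fl <- abs(ti$flair["cl"] - ti$flair["cortex"])
  wml_fl <- abs(ti$flair["wml"] - ti$flair["wm"])
  cl_mp <- abs(ti$mp2rage["cl"] - ti$mp2rage["cortex"])
  if (cl_fl >= wml_fl)
    stop("CL contrast in the FLAIR channel must be smaller than WML contrast")
  if (cl_mp <= cl_fl)
    stop("CL contrast must be larger in the MP2RAGE channel than in FLAIR")
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 n_wml = n_wml, n_cl = n_cl,
                 wml_size_meanlog = wml_size_meanlog,
                 wml_size_sdlog = wml_size_sdlog,
                 cl_size_meanlog = cl_size_meanlog,
                 cl_size_sdlog = cl_size_sdlog,
                 min_voxels = as.integer(min_voxels),
                 tissue_intensities = ti, noise_sigma = noise_sigma,
                 cortex_thickness = cortex_thickness,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Normalized squared ellipsoid radius field over the grid.
ellipsoid_field <- function(dims, center, radii) {
  x <- (seq_len(dims[1]) - center[1]) / radii[1]
  y <- (seq_len(dims[2]) - center[2]) / radii[2]
  z <- (seq_len(dims[3]) - center[3]) / radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

# Truncated log-normal lesion volume in voxels (resample below the minimum).
sample_lesion_size <- function(meanlog, sdlog, min_voxels, max_voxels = 2000) {
  for (i in 1:200) {
    v <- rlnorm(1, meanlog, sdlog)
    if (v >= min_voxels && v <= max_voxels) return(v)
  }
  min_voxels
}

#' Sample one lesion's ellipsoid geometry inside a region
#'
#' Draws a center uniformly over the region's voxels and anisotropic
#' ellipsoid radii matched to a target volume, then rasterizes. Candidates
#' are rejected (and resampled by the caller) when the discretized lesion
#' leaves the allowed region or would touch an already placed lesion; radii
#' are inflated until the discretized lesion reaches the 3-voxel minimum.
#'
#' @param region_idx Integer n x 3 matrix of admissible center voxels.
#' @param target_voxels Target lesion volume in voxels.
#' @param dims Grid dimensions.
#' @param min_voxels Minimum discretized size.
#' @param allowed Optional logical mask: every lesion voxel must fall inside
#'   it. Infeasible placement (after `max_attempts` rejection-sampling
#'   attempts) raises an error naming the constraint.
#' @param max_attempts Rejection-sampling bound.
#' @return List with `center`, `radii` and the rasterized `voxels` matrix;
#'   draws from the current RNG stream.
#' @export
sample_lesion_geometry <- function(region_idx, target_voxels, dims,
                                   min_voxels = 3, allowed = NULL,
                                   max_attempts = 50) {
  if (nrow(region_idx) == 0) stop("lesion placement region is empty")
  for (att in seq_len(max_attempts)) {
    center <- region_idx[sample.int(nrow(region_idx), 1), ]
    r0 <- (3 * target_voxels / (4 * pi))^(1 / 3)
    f <- exp(runif(3, -0.35, 0.35))
    f <- f / prod(f)^(1 / 3)
    radii <- pmax(r0 * f, 0.55)
    vox <- rasterize_ellipsoid(center, radii, dims)
    for (infl in 1:12) {
      if (nrow(vox) >= min_voxels) break
      radii <- radii * 1.15
      vox <- rasterize_ellipsoid(center, radii, dims)
    }
    if (nrow(vox) < min_voxels) next
    if (!is.null(allowed) && !all(allowed[vox])) next
    return(list(center = center, radii = radii, voxels = vox))
  }
  stop(sprintf(paste0("infeasible placement: no %d-voxel lesion of target ",
                      "volume %.0f fits the region after %d attempts"),
               min_voxels, target_voxels, max_attempts))
}

rasterize_ellipsoid <- function(center, radii, dims) {
  lo <- pmax(1L, floor(center - radii))
  hi <- pmin(dims, ceiling(center + radii))
  if (any(lo > hi)) return(matrix(integer(0), 0, 3))
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  fx <- ((gx - center[1]) / radii[1])^2
  fy <- ((gy - center[2]) / radii[2])^2
  fz <- ((gz - center[3]) / radii[3])^2
  fld <- outer(outer(fx, fy, `+`), fz, `+`)
  idx <- which(fld <= 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), 0, 3))
  cbind(gx[idx[, 1]], gy[idx[, 2]], gz[idx[, 3]])
}

# TRUE if any candidate voxel is within the 26-neighborhood of an occupied
# voxel (guards against two intended lesions merging into one component).
touches_occupied <- function(vox, occupied, dims) {
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    sh <- sweep(vox, 2, c(dx, dy, dz), `+`)
    keep <- sh[, 1] >= 1 & sh[, 1] <= dims[1] & sh[, 2] >= 1 &
      sh[, 2] <= dims[2] & sh[, 3] >= 1 & sh[, 3] <= dims[3]
    if (any(occupied[sh[keep, , drop = FALSE]])) return(TRUE)
  }
  FALSE
}

#' Generate one synthetic subject
#'
#' Deterministic given `config$seed`. Builds the nested tissue geometry,
#' places the configured numbers of WMLs (inside the white-matter core) and
#' CLs (intersecting the cortex ribbon) by rejection sampling, renders both
#' contrasts with the configured tissue means plus Gaussian noise, and
#' returns the case together with the exact lesion components and a
#' per-lesion geometry log.
#'
#' @param config A [phantom_config()].
#' @param subject_id,site Identifiers for the embedded [subject_case()].
#' @return A `phantom_truth`: list with `case`, `components` (a
#'   `lesion_components` object), `geometry_log` (data frame) and `config`.
#' @export
generate_phantom <- function(config, subject_id = "phantom01", site = "site1") {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$dims
  with_seed(config$seed, {
    center <- (dims + 1) / 2
    brain_r <- 0.44 * dims
    inner_r <- brain_r - config$cortex_thickness
    brain <- ellipsoid_field(dims, center, brain_r) <= 1
    core <- ellipsoid_field(dims, center, inner_r) <= 1
    ribbon <- brain & !core
    # keep WMLs off the core boundary so they stay clear of the ribbon
    core_safe <- ellipsoid_field(dims, center, inner_r - 2) <= 1
    core_idx <- which(core_safe, arr.ind = TRUE)
    ribbon_idx <- which(ribbon, arr.ind = TRUE)
    occupied <- array(FALSE, dims)
    labels <- array(0L, dims)
    comps <- list()
    logs <- list()
    place <- function(type, n, region_idx, meanlog, sdlog, allowed) {
      for (i in seq_len(n)) {
        placed <- FALSE
        for (att in 1:300) {
          size <- sample_lesion_size(meanlog, sdlog, config$min_voxels)
          geo <- tryCatch(
            sample_lesion_geometry(region_idx, size, dims, config$min_voxels,
                                   allowed = allowed, max_attempts = 10),
            error = function(e) NULL)
          if (is.null(geo)) next  # retry with a freshly drawn size
          vox <- geo$voxels
          if (type == "CL" && !any(ribbon[vox])) next
          if (touches_occupied(vox, occupied, dims)) next
          occupied[vox] <<- TRUE
          labels[vox] <<- if (type == "WML") 1L else 2L
          comps[[length(comps) + 1L]] <<- list(
            voxels = vox, size = nrow(vox),
            volume_ul = nrow(vox) * prod(config$spacing), type = type)
          logs[[length(logs) + 1L]] <<- data.frame(
            lesion_id = length(comps), type = type,
            cx = geo$center[1], cy = geo$center[2], cz = geo$center[3],
            rx = geo$radii[1], ry = geo$radii[2], rz = geo$radii[3],
            size_voxels = nrow(vox), stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop(sprintf("infeasible placement: could not place %s %d of %d %s",
                       type, i, n,
                       "without touching existing lesions or leaving its region"))
      }
    }
    place("WML", config$n_wml, core_idx, config$wml_size_meanlog,
          config$wml_size_sdlog, core)
    place("CL", config$n_cl, ribbon_idx, config$cl_size_meanlog,
          config$cl_size_sdlog, brain)
    ti <- config$tissue_intensities
    render <- function(means, sigma) {
      arr <- array(means["background"], dims)
      arr[core] <- means["wm"]
      arr[ribbon] <- means["cortex"]
      arr[labels == 1L] <- means["wml"]
      arr[labels == 2L] <- means["cl"]
      arr + array(rnorm(prod(dims), 0, sigma), dims)
    }
    flair <- image_volume(render(ti$flair, config$noise_sigma[[1]]),
                          spacing = config$spacing, contrast = "FLAIR")
    mp2 <- image_volume(render(ti$mp2rage, config$noise_sigma[[2]]),
                        spacing = config$spacing, contrast = "MP2RAGE")
    gt <- label_volume(labels, spacing = config$spacing)
    case <- subject_case(subject_id, flair, mp2, gt = gt, site = site)
    components <- structure(comps, class = "lesion_components", dims = dims,
                            spacing = config$spacing, connectivity = 18)
    structure(list(case = case, components = components,
                   geometry_log = do.call(rbind, logs), config = config),
              class = "phantom_truth")
  })
}

#' Render a phantom's logged components onto an empty grid
#'
#' Reproduces the ground-truth label volume exactly from the component list;
#' used to assert label-geometry consistency.
#'
#' @param phantom A `phantom_truth`.
#' @return Integer 3D label array.
#' @export
render_components <- function(phantom) {
  labels <- array(0L, attr(phantom$components, "dims"))
  for (cm in phantom$components)
    labels[cm$voxels] <- if (cm$type == "WML") 1L else 2L
  labels
}

#' Generate a phantom cohort
#'
#' Per-subject seeds are derived deterministically from `master_seed`, and
#' per-subject lesion counts are drawn from Poisson distributions with the
#' template's means (at least one lesion per subject), so the lesion burden
#' varies across the cohort as it does across a clinical population.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config_template A [phantom_config()] giving shared parameters.
#' @param master_seed Integer master seed.
#' @param site Site tag applied to all subjects.
#' @return List of `phantom_truth` objects.
#' @export
make_cohort <- function(n_subjects, config_template = phantom_config(),
                        master_seed = 1, site = "site1") {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(i) {
    seed_i <- derive_seed(master_seed, i)
    counts <- with_seed(derive_seed(master_seed, 100000 + i), {
      nw <- rpois(1, config_template$n_wml)
      nc <- rpois(1, config_template$n_cl)
      if (nw + nc == 0) nw <- 1L
      c(nw, nc)
    })
    cfg <- config_template
    cfg$n_wml <- counts[1]
    cfg$n_cl <- counts[2]
    cfg$seed <- seed_i
    generate_phantom(cfg, subject_id = sprintf("%s_sub%02d", site, i),
                     site = site)
  })
}

#' Write a phantom cohort to NIfTI files plus a manifest
#'
#' Writes `<id>_flair.nii.gz`, `<id>_mp2rage.nii.gz`, `<id>_gt.nii.gz` per
#' subject and a `manifest.csv` with subject id, site, lesion counts and
#' total volumes.
#'
#' @param cohort List of `phantom_truth` objects.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ph) {
    case <- ph$case
    id <- case$subject_id
    save_volume(case$flair, file.path(dir, paste0(id, "_flair.nii.gz")))
    save_volume(case$mp2rage, file.path(dir, paste0(id, "_mp2rage.nii.gz")))
    save_mask(case$gt, case$flair, file.path(dir, paste0(id, "_gt.nii.gz")))
    types <- vapply(ph$components, function(cm) cm$type, character(1))
    vols <- vapply(ph$components, function(cm) cm$volume_ul, numeric(1))
    data.frame(subject_id = id, site = case$site,
               n_wml = sum(types == "WML"), n_cl = sum(types == "CL"),
               wml_volume_ul = sum(vols[types == "WML"]),
               cl_volume_ul = sum(vols[types == "CL"]),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
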