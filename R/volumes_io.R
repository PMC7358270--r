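#' Construct an intensity volume
#'
#' A 3D scalar grid with voxel spacing, a voxel-to-world affine and a contrast
#' tag. Voxel indices are 1-based throughout the package; world coordinates
#' enter only through the affine at I/O time.
#'
#' @param data 3D numeric array, all values finite.
#' @param spacing Numeric length-3 voxel size in mm, all positive.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(c(spacing, 1))`.
#' @param contrast `"FLAIR"` or `"MP2RAGE"`.
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         contrast = c("FLAIR", "MP2RAGE")) {
  contrast <- match.arg(contrast)
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (any(dim(data) < 1)) stop("all grid dimensions must be >= 1")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values")
  if (any(!is.finite(data))) stop("volume contains non-finite intensities")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (!is.matrix(affine) || any(dim(affine) != c(4, 4)))
    stop("affine must be a 4x4 matrix")
  structure(list(data = data, spacing = as.numeric(spacing),
                 affine = affine, contrast = contrast),
            class = "image_volume")
}

#' Construct a typed label volume
#'
#' Integer grid with values 0 (background), 1 (white-matter lesion, WML) and
#' 2 (cortical lesion, CL).
#'
#' @param labels 3D array of integers in `{0, 1, 2}`.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3) stop("labels must be a 3D array")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive values")
  vals <- unique(as.vector(labels))
  if (any(!is.finite(vals)) || !all(vals %in% c(0, 1, 2)))
    stop("illegal label value: labels must be in {0, 1, 2}")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' Assemble a subject case from its channels
#'
#' Bundles the two co-registered contrasts and (optionally) the ground-truth
#' label volume. Channels must share grid dimensions and voxel spacing: the
#' package assumes rigid co-registration has already been performed upstream.
#'
#' @param subject_id Character identifier.
#' @param flair,mp2rage `image_volume` objects.
#' @param gt Optional `label_volume` ground truth.
#' @param site Character site tag used for stratification.
#' @return A `subject_case` object.
#' @export
subject_case <- function(subject_id, flair, mp2rage, gt = NULL, site = "site1") {
  stopifnot(inherits(flair, "image_volume"), inherits(mp2rage, "image_volume"))
  if (!identical(dim(flair$data), dim(mp2rage$data)))
    stop("dimension mismatch between FLAIR and MP2RAGE channels")
  if (max(abs(flair$spacing - mp2rage$spacing)) > 1e-6)
    stop("voxel spacing mismatch between channels")
  if (!is.null(gt)) {
    stopifnot(inherits(gt, "label_volume"))
    if (!identical(dim(gt$labels), dim(flair$data)))
      stop("dimension mismatch between ground truth and image channels")
  }
  structure(list(subject_id = as.character(subject_id), flair = flair,
                 mp2rage = mp2rage, gt = gt, site = as.character(site)),
            class = "subject_case")
}

read_nifti_volume <- function(path, contrast) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.double(img), dim(img))  # plain array, no NIfTI attributes
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("expected a 3D volume: ", path)
  if (any(!is.finite(arr))) stop("non-finite intensities in ", path)
  vol <- image_volume(arr, spacing = RNifti::pixdim(img)[1:3],
                      affine = unclass(RNifti::xform(img))[1:4, 1:4],
                      contrast = contrast)
  attr(vol, "nifti_header") <- img
  vol
}

#' Load a subject case from NIfTI files
#'
#' Reads the FLAIR-like and MP2RAGE-like channels (and optionally the
#' ground-truth mask), validating that the grids match, all intensities are
#' finite, and every label lies in `{0, 1, 2}`.
#'
#' @param flair_path,mp2rage_path Paths to NIfTI-1/2 files (`.nii`/`.nii.gz`).
#' @param gt_path Optional path to the label mask.
#' @param subject_id Identifier; defaults to the FLAIR file stem.
#' @param site Site tag.
#' @return A [subject_case()].
#' @export
load_case <- function(flair_path, mp2rage_path, gt_path = NULL,
                      subject_id = NULL, site = "site1") {
  flair <- read_nifti_volume(flair_path, "FLAIR")
  mp2rage <- read_nifti_volume(mp2rage_path, "MP2RAGE")
  gt <- NULL
  if (!is.null(gt_path)) {
    if (!file.exists(gt_path)) stop("file not found: ", gt_path)
    img <- RNifti::readNifti(gt_path)
    arr <- array(as.double(img), dim(img))
    if (length(dim(arr)) != 3) stop("expected a 3D label volume: ", gt_path)
    if (any(!is.finite(arr)) || !all(unique(as.vector(arr)) %in% c(0, 1, 2)))
      stop("illegal label value in ", gt_path, " (labels must be 0, 1 or 2)")
    gt <- label_volume(arr, spacing = RNifti::pixdim(img)[1:3])
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(flair_path))
  subject_case(subject_id, flair, mp2rage, gt = gt, site = site)
}

#' Standardize a volume to zero mean and unit variance
#'
#' Statistics are computed over all voxels of the volume (no brain mask is
#' available because the pipeline performs no skull stripping) using the
#' population (N) standard deviation.
#'
#' @param vol An `image_volume` or a plain 3D array.
#' @return The same type with standardized intensities.
#' @export
zscore_normalize <- function(vol) {
  arr <- if (inherits(vol, "image_volume")) vol$data else vol
  if (length(arr) < 2) stop("volume must have at least 2 voxels")
  m <- mean(arr)
  s <- sqrt(mean((arr - m)^2))
  if (s < 1e-12 * max(1, abs(m)) || s == 0)
    stop("zero-variance volume cannot be normalized")
  out <- (arr - m) / s
  if (inherits(vol, "image_volume")) {
    vol$data <- out
    vol
  } else out
}

#' Write a label mask as NIfTI
#'
#' The mask inherits the reference volume's affine and voxel spacing and is
#' stored as unsigned 8-bit integers; a reload through [load_case()] yields a
#' bit-identical label grid.
#'
#' @param mask A `label_volume` (or integer 3D array).
#' @param reference The `image_volume` whose geometry the mask shares.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, reference, path) {
  arr <- if (inherits(mask, "label_volume")) mask$labels else mask
  stopifnot(inherits(reference, "image_volume"))
  if (!identical(dim(arr), dim(reference$data)))
    stop("dimension mismatch between mask and reference volume")
  storage.mode(arr) <- "integer"
  hdr <- attr(reference, "nifti_header")
  if (!is.null(hdr)) {
    img <- RNifti::asNifti(arr, reference = hdr, datatype = "uint8")
  } else {
    attr(arr, "pixdim") <- reference$spacing
    img <- RNifti::asNifti(arr, datatype = "uint8")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an intensity volume as NIfTI
#'
#' @param vol An `image_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  arr <- vol$data
  attr(arr, "pixdim") <- vol$spacing
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @export
print.subject_case <- function(x, ...) {
  d <- dim(x$flair$data)
  cat(sprintf("subject_case '%s' (site %s): %dx%dx%d, spacing %s mm, gt %s\n",
              x$subject_id, x$site, d[1], d[2], d[3],
              paste(signif(x$flair$spacing, 3), collapse = "x"),
              if (is.null(x$gt)) "absent" else "present"))
  invisible(x)
}
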