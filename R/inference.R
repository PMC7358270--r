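#' Plan a disjoint tiling of a volume with valid patches
#'
#' Output windows of side `output_side` tile the volume exactly once: tiles
#' step by `output_side` and the final tile along each axis is shifted inward
#' so its window ends at the volume edge. Overlaps created by the inward
#' shift are resolved by a deterministic priority (later tiles in
#' lexicographic order overwrite), so the coverage multiplicity after
#' resolution is exactly one everywhere. Each input window extends its output
#' window by `(input_side - output_side) / 2` voxels per side into a
#' reflection-padded volume.
#'
#' @param volume_dims Integer length-3 grid dimensions.
#' @param input_side,output_side Patch geometry; `output_side` must equal
#'   `input_side - 40` for this architecture.
#' @return Data frame of output-window start coordinates (1-based, original
#'   volume frame), with attributes `input_side`, `output_side`, `pad`.
#' @export
tile_plan <- function(volume_dims, input_side = 88,
                      output_side = input_side - 40) {
  if (output_side != input_side - 40)
    stop("output_side must equal input_side - 40")
  if (any(volume_dims < output_side))
    stop("volume smaller than one output tile")
  starts <- lapply(volume_dims, function(n) {
    s <- seq(1L, n - output_side + 1L, by = output_side)
    if (s[length(s)] != n - output_side + 1L) s <- c(s, n - output_side + 1L)
    as.integer(s)
  })
  plan <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  structure(plan, input_side = as.integer(input_side),
            output_side = as.integer(output_side),
            pad = as.integer((input_side - output_side) / 2))
}

#' Predict lesion probabilities and a binary mask for a whole volume
#'
#' The two channels are expected z-scored ([zscore_normalize()]); a channel
#' mean far from zero triggers a warning. The volume is reflection-padded by
#' 20 voxels per side, sigmoid probabilities are assembled tile by tile per
#' [tile_plan()], and the binary mask is `probability >= threshold`.
#'
#' @param model A trained `unet_model`.
#' @param case A [subject_case()].
#' @param threshold Probability threshold in `[0, 1]`.
#' @param input_side Input patch side (default from the training recipe, 88;
#'   smaller feasible sides reduce memory for scaled-down models).
#' @return List with `mask` (a binary [label_volume()]), `prob` (probability
#'   array) and `threshold`.
#' @export
predict_volume <- function(model, case, threshold = 0.5, input_side = 88) {
  stopifnot(inherits(model, "unet_model"), inherits(case, "subject_case"))
  dims <- dim(case$flair$data)
  for (ch in c("flair", "mp2rage"))
    if (abs(mean(case[[ch]]$data)) > 0.5)
      warning(sprintf("channel %s does not look z-score normalized (|mean| > 0.5)",
                      ch))
  plan <- tile_plan(dims, input_side = input_side)
  pad <- attr(plan, "pad")
  out <- attr(plan, "output_side")
  pf <- pad_reflect3d(case$flair$data, pad)
  pm <- pad_reflect3d(case$mp2rage$data, pad)
  prob <- array(0, dims)
  x <- array(0, c(input_side, input_side, input_side, 2L))
  for (i in seq_len(nrow(plan))) {
    s <- as.integer(plan[i, ])
    ix <- s[1]:(s[1] + input_side - 1L)
    iy <- s[2]:(s[2] + input_side - 1L)
    iz <- s[3]:(s[3] + input_side - 1L)
    x[, , , 1] <- pf[ix, iy, iz]
    x[, , , 2] <- pm[ix, iy, iz]
    logits <- unet_forward(model, x)
    prob[s[1]:(s[1] + out - 1L), s[2]:(s[2] + out - 1L),
         s[3]:(s[3] + out - 1L)] <- plogis(logits[, , , 1])
  }
  mask <- array(0L, dims)
  mask[prob >= threshold] <- 1L
  list(mask = label_volume(mask, spacing = case$flair$spacing),
       prob = prob, threshold = threshold)
}

#' Select the probability threshold on a validation set
#'
#' Searches the grid 0.05, 0.10, ..., 0.95 and returns the value maximizing
#' the mean per-subject Dice coefficient after minimum-size filtering
#' (matching the evaluation pipeline); ties are broken towards the lower
#' threshold to favor detection sensitivity.
#'
#' @param prob_volumes List of per-subject probability arrays.
#' @param gts List of matching ground-truth `label_volume`s (or arrays).
#' @param grid Candidate thresholds.
#' @param min_voxels,connectivity Filtering parameters.
#' @return The selected threshold.
#' @export
select_threshold <- function(prob_volumes, gts, grid = seq(0.05, 0.95, 0.05),
                             min_voxels = 3, connectivity = 18) {
  stopifnot(length(prob_volumes) >= 1,
            length(prob_volumes) == length(gts))
  gts_f <- lapply(gts, apply_min_size, min_voxels = min_voxels,
                  connectivity = connectivity)
  mean_dice <- vapply(grid, function(th) {
    d <- vapply(seq_along(prob_volumes), function(i) {
      mask <- (prob_volumes[[i]] >= th) * 1L
      mask <- apply_min_size(mask, min_voxels, connectivity)
      voxel_metrics(mask, gts_f[[i]])$dsc
    }, numeric(1))
    d <- d[!is.na(d)]
    if (length(d) == 0) -Inf else mean(d)
  }, numeric(1))
  grid[which.max(mean_dice)]  # which.max takes the first (lowest) maximizer
}
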