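#' Connected components of a lesion mask
#'
#' Partitions the foreground of a 3D label grid into maximal connected sets
#' under 6-, 18- or 26-connectivity (default 18, the convention of the MS
#' lesion-segmentation challenge metric definitions). Typed grids (labels 1 =
#' WML, 2 = CL) are labelled per class, so a touching WML and CL remain two
#' distinct components; binary grids yield untyped components.
#'
#' @param x A [label_volume()], or a 3D array (binary or `{0,1,2}`-typed).
#' @param connectivity 6, 18 or 26.
#' @param spacing Voxel spacing in mm (taken from `x` when it is a
#'   `label_volume`).
#' @param typed Treat label values as lesion types? Defaults to `TRUE` for
#'   `label_volume` input and for arrays containing a 2, else `FALSE`.
#' @return A `lesion_components` list; each element has `voxels` (n x 3
#'   1-based index matrix), `size` (voxel count), `volume_ul`
#'   (`size * prod(spacing)`) and `type` (`"WML"`, `"CL"` or `NA`).
#' @export
connected_components <- function(x, connectivity = 18, spacing = NULL,
                                 typed = NULL) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (inherits(x, "label_volume")) {
    spacing <- spacing %||% x$spacing
    if (is.null(typed)) typed <- TRUE
    arr <- x$labels
  } else {
    arr <- x
    spacing <- spacing %||% c(1, 1, 1)
  }
  if (length(dim(arr)) != 3) stop("expected a 3D grid")
  storage.mode(arr) <- "integer"
  if (is.null(typed)) typed <- any(arr == 2L)
  vunit <- prod(spacing)
  comps <- list()
  vals <- if (typed) sort(unique(arr[arr != 0L])) else 1L
  mask_for <- function(v) if (typed) (arr == v) * 1L else (arr != 0L) * 1L
  for (v in vals) {
    m <- mask_for(v)
    storage.mode(m) <- "integer"
    lab <- label_components_cpp(m, dim(m), as.integer(connectivity))
    n <- max(lab)
    if (n == 0L) next
    idx <- which(lab > 0L)
    ord <- order(lab[idx])
    idx <- idx[ord]
    sizes <- tabulate(lab[idx], n)
    splits <- rep(seq_len(n), sizes)
    coords <- arrayInd(idx, dim(arr))
    starts <- cumsum(c(1L, sizes[-n]))
    for (i in seq_len(n)) {
      rows <- starts[i]:(starts[i] + sizes[i] - 1L)
      comps[[length(comps) + 1L]] <- list(
        voxels = coords[rows, , drop = FALSE],
        size = sizes[i],
        volume_ul = sizes[i] * vunit,
        type = if (!typed) NA_character_ else if (v == 1L) "WML" else "CL")
    }
  }
  structure(comps, class = "lesion_components", dims = dim(arr),
            spacing = spacing, connectivity = connectivity)
}

#' @export
print.lesion_components <- function(x, ...) {
  ty <- vapply(x, function(c) c$type %||% NA_character_, character(1))
  cat(sprintf("%d lesion component(s) [%d WML, %d CL, %d untyped], sizes %s\n",
              length(x), sum(ty == "WML", na.rm = TRUE),
              sum(ty == "CL", na.rm = TRUE), sum(is.na(ty)),
              paste(vapply(x, function(c) c$size, numeric(1)), collapse = ", ")))
  invisible(x)
}

#' Remove connected components below a minimum size
#'
#' Components smaller than `min_voxels` voxels are re-classified as
#' background. Applied identically to ground truth and predictions before all
#' metrics; at 1 mm isotropic spacing the default of 3 voxels equals 3 uL.
#'
#' @param x A `label_volume` or 3D array (binary or typed).
#' @param min_voxels Minimum surviving component size (default 3).
#' @param connectivity 6, 18 or 26.
#' @return Same type as `x` with small components zeroed; idempotent.
#' @export
apply_min_size <- function(x, min_voxels = 3, connectivity = 18) {
  if (min_voxels < 1) stop("min_voxels must be >= 1")
  arr <- if (inherits(x, "label_volume")) x$labels else x
  comps <- connected_components(arr, connectivity = connectivity,
                                typed = any(arr == 2))
  for (cm in comps) {
    if (cm$size < min_voxels) arr[cm$voxels] <- 0L
  }
  if (inherits(x, "label_volume")) {
    x$labels <- arr
    x
  } else arr
}

as_binary_mask <- function(x) {
  arr <- if (inherits(x, "label_volume")) x$labels else x
  arr != 0
}

#' Voxel-wise overlap metrics
#'
#' Dice similarity coefficient `DSC = 2|P&G| / (|P| + |G|)`, positive
#' predictive value `PPV = |P&G| / |P|` and absolute volume difference
#' `AVD = ||P| - |G|| / |G|` on pooled (binary) lesion masks. Undefined
#' metrics (empty ground truth for DSC/AVD, empty prediction for PPV) are
#' reported as `NA`, never as 0. DSC is symmetric in its arguments; AVD is
#' not (it is normalized by the ground-truth volume).
#'
#' @param pred,gt Binary grids (or `label_volume`s), already min-size
#'   filtered.
#' @return One-row data frame with `dsc`, `ppv`, `avd`.
#' @export
voxel_metrics <- function(pred, gt) {
  p <- as_binary_mask(pred); g <- as_binary_mask(gt)
  if (!identical(dim(p), dim(g))) stop("dimension mismatch")
  np <- sum(p); ng <- sum(g); ni <- sum(p & g)
  data.frame(
    dsc = if (ng + np == 0) NA_real_ else if (ng == 0) NA_real_ else 2 * ni / (np + ng),
    ppv = if (np == 0) NA_real_ else ni / np,
    avd = if (ng == 0) NA_real_ else abs(np - ng) / ng)
}

#' Lesion-wise detection rates
#'
#' A ground-truth component is detected when at least one of its voxels is
#' covered by any predicted component; a predicted component is a false
#' positive when it overlaps no ground-truth component (one overlapping both
#' a WML and a CL detects both and is not a false positive). `ltpr` is the
#' detected fraction of all ground-truth lesions, `ltpr_wm`/`ltpr_cl`
#' restrict the denominator to that type, and `lfpr` is the false-positive
#' fraction of predicted lesions. Empty denominators give `NA`.
#'
#' @param gt_components Typed [connected_components()] of the ground truth.
#' @param pred_components [connected_components()] of the prediction.
#' @return List with `ltpr`, `ltpr_wm`, `ltpr_cl`, `lfpr`, counts, and
#'   per-component `detected` / `false_positive` flags.
#' @export
lesion_detection <- function(gt_components, pred_components) {
  dims <- attr(gt_components, "dims") %||% attr(pred_components, "dims")
  if (is.null(dims)) stop("components carry no grid dimensions")
  pmask <- array(FALSE, dims)
  for (cm in pred_components) pmask[cm$voxels] <- TRUE
  gmask <- array(FALSE, dims)
  for (cm in gt_components) gmask[cm$voxels] <- TRUE
  detected <- vapply(gt_components, function(cm) any(pmask[cm$voxels]),
                     logical(1))
  fp <- vapply(pred_components, function(cm) !any(gmask[cm$voxels]),
               logical(1))
  types <- vapply(gt_components, function(cm) cm$type %||% NA_character_,
                  character(1))
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  is_wm <- !is.na(types) & types == "WML"
  is_cl <- !is.na(types) & types == "CL"
  list(ltpr = rate(sum(detected), length(detected)),
       ltpr_wm = rate(sum(detected[is_wm]), sum(is_wm)),
       ltpr_cl = rate(sum(detected[is_cl]), sum(is_cl)),
       lfpr = rate(sum(fp), length(fp)),
       n_gt = length(gt_components), n_pred = length(pred_components),
       detected = detected, false_positive = fp)
}

#' Detection rate stratified by lesion size
#'
#' Ground-truth components are binned by voxel count into the half-open
#' intervals `[breaks[i], breaks[i+1])` and the detection rate of
#' [lesion_detection()] is reported per bin together with the bin's
#' ground-truth count.
#'
#' @param gt_components,pred_components As in [lesion_detection()].
#' @param breaks Increasing numeric vector of bin edges; the last bin is
#'   `[breaks[n-1], breaks[n])` (use `Inf` for an open top bin).
#' @return Data frame with `bin_lo`, `bin_hi`, `n_gt`, `n_detected`, `rate`.
#' @export
size_stratified_detection <- function(gt_components, pred_components,
                                      breaks = c(3, 11, 51, Inf)) {
  if (length(breaks) < 2 || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing (bins are [lo, hi))")
  det <- lesion_detection(gt_components, pred_components)
  sizes <- vapply(gt_components, function(cm) cm$size, numeric(1))
  nb <- length(breaks) - 1L
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    n_gt = 0L, n_detected = 0L, rate = NA_real_)
  for (i in seq_len(nb)) {
    in_bin <- sizes >= breaks[i] & sizes < breaks[i + 1]
    out$n_gt[i] <- sum(in_bin)
    out$n_detected[i] <- sum(det$detected[in_bin])
    out$rate[i] <- if (out$n_gt[i] == 0) NA_real_ else
      out$n_detected[i] / out$n_gt[i]
  }
  out
}

#' Pearson correlation between manual and automatic lesion volumes
#'
#' @param manual_volumes,automatic_volumes Paired per-subject total lesion
#'   volumes (uL), length >= 3.
#' @return List with `r` (Pearson correlation), `slope`, `intercept` (least
#'   squares automatic ~ manual) and `n`.
#' @export
volume_correlation <- function(manual_volumes, automatic_volumes) {
  if (length(manual_volumes) != length(automatic_volumes))
    stop("volume vectors must be paired")
  if (length(manual_volumes) < 3) stop("need at least 3 subjects")
  if (sd(manual_volumes) == 0 || sd(automatic_volumes) == 0)
    stop("zero variance in a volume vector")
  fit <- lm(automatic_volumes ~ manual_volumes)
  list(r = cor(manual_volumes, automatic_volumes),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(manual_volumes))
}

#' Paired comparison of two methods on a per-subject metric
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences (zero
#' differences dropped), with Bonferroni adjustment
#' `p_adj = min(1, p * n_comparisons)` and a significance flag at 0.05 on the
#' adjusted p-value.
#'
#' @param metric_a,metric_b Paired per-subject metric vectors, length >= 6.
#' @param n_comparisons Number of simultaneous comparisons.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `p_adjusted`, `significant`, `n_effective`.
#' @export
compare_methods <- function(metric_a, metric_b, n_comparisons = 1) {
  if (length(metric_a) != length(metric_b)) stop("samples must be paired")
  if (length(metric_a) < 6) stop("need at least 6 paired samples")
  d <- metric_a - metric_b
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                p_adjusted = NA_real_, significant = NA,
                n_effective = 0L))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided"))
  padj <- min(1, wt$p.value * n_comparisons)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_adjusted = padj, significant = padj < 0.05,
       n_effective = length(d))
}

#' Evaluate one predicted mask against its ground truth
#'
#' Applies the minimum-size rule to both masks, then computes the full metric
#' bundle: DSC, AVD, PPV, LTPR, LTPR_WM, LTPR_CL, LFPR, plus manual and
#' automatic total lesion volumes in uL.
#'
#' @param pred Binary predicted mask (`label_volume` or array).
#' @param gt Typed ground-truth `label_volume` (or array).
#' @param spacing Voxel spacing (mm); from `gt` when it is a `label_volume`.
#' @param min_voxels,connectivity Filtering/labelling parameters.
#' @param subject_id Identifier copied into the output row.
#' @return One-row data frame.
#' @export
evaluate_case <- function(pred, gt, spacing = NULL, min_voxels = 3,
                          connectivity = 18, subject_id = "subject") {
  if (inherits(gt, "label_volume")) spacing <- spacing %||% gt$spacing
  spacing <- spacing %||% c(1, 1, 1)
  predf <- apply_min_size(pred, min_voxels, connectivity)
  gtf <- apply_min_size(gt, min_voxels, connectivity)
  vm <- voxel_metrics(predf, gtf)
  gtc <- connected_components(gtf, connectivity, spacing = spacing)
  prc <- connected_components(predf, connectivity, spacing = spacing,
                              typed = FALSE)
  det <- lesion_detection(gtc, prc)
  vunit <- prod(spacing)
  data.frame(subject_id = subject_id, dsc = vm$dsc, avd = vm$avd,
             ppv = vm$ppv, ltpr = det$ltpr, ltpr_wm = det$ltpr_wm,
             ltpr_cl = det$ltpr_cl, lfpr = det$lfpr,
             manual_volume_ul = sum(as_binary_mask(gtf)) * vunit,
             automatic_volume_ul = sum(as_binary_mask(predf)) * vunit,
             n_gt_lesions = det$n_gt, n_pred_lesions = det$n_pred,
             stringsAsFactors = FALSE)
}

#' Cohort metrics report
#'
#' Stacks per-subject rows from [evaluate_case()] and summarizes each metric
#' with the cohort median and interquartile range, excluding undefined (`NA`)
#' entries.
#'
#' @param per_subject Data frame of [evaluate_case()] rows.
#' @return A `metrics_report`: list with `per_subject` and `summary`.
#' @export
metrics_report <- function(per_subject) {
  metrics <- c("dsc", "avd", "ppv", "ltpr", "ltpr_wm", "ltpr_cl", "lfpr")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_subject[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m,
               median = if (length(v)) median(v) else NA_real_,
               iqr = if (length(v)) unname(diff(quantile(v, c(0.25, 0.75))))
                     else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  structure(list(per_subject = per_subject, summary = summ),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics report: %d subject(s)\n", nrow(x$per_subject)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' One row per subject followed by a cohort-summary block.
#'
#' @param report A [metrics_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(report$per_subject, con, row.names = FALSE)
  writeLines("", con)
  utils::write.csv(report$summary, con, row.names = FALSE)
  invisible(path)
}
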