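test_that("connectivity semantics follow the 6/18/26 neighborhood definitions", {
  face <- array(0L, c(5, 5, 5)); face[2, 2, 2] <- 1L; face[3, 2, 2] <- 1L
  for (conn in c(6, 18, 26))
    expect_length(connected_components(face, conn), 1)
  edge <- array(0L, c(5, 5, 5)); edge[2, 2, 2] <- 1L; edge[3, 3, 2] <- 1L
  expect_length(connected_components(edge, 6), 2)
  expect_length(connected_components(edge, 18), 1)
  corner <- array(0L, c(5, 5, 5)); corner[2, 2, 2] <- 1L; corner[3, 3, 3] <- 1L
  expect_length(connected_components(corner, 6), 2)
  expect_length(connected_components(corner, 18), 2)
  expect_length(connected_components(corner, 26), 1)
  expect_error(connected_components(face, 10), "connectivity")
})

test_that("typed grids keep touching WML and CL as distinct components", {
  arr <- array(0L, c(6, 6, 6))
  arr[2:3, 2, 2] <- 1L
  arr[4:5, 2, 2] <- 2L   # face-adjacent to the WML
  cc <- connected_components(arr, 26)
  expect_length(cc, 2)
  expect_setequal(vapply(cc, function(cm) cm$type, character(1)),
                  c("WML", "CL"))
  # binary view merges them
  expect_length(connected_components((arr != 0) * 1L, 26), 1)
  # volumes follow the voxel spacing exactly
  cc2 <- connected_components(label_volume(arr, spacing = c(1, 1, 1.2)))
  expect_equal(vapply(cc2, function(cm) cm$volume_ul, numeric(1)),
               vapply(cc2, function(cm) cm$size, numeric(1)) * 1.2)
})

test_that("component labelling agrees with a flood-fill oracle on random masks", {
  set.seed(41)
  for (rep in 1:25) {
    conn <- sample(c(6, 18, 26), 1)
    mask <- array(as.integer(runif(8000) < 0.12), c(20, 20, 20))
    cc <- connected_components(mask, conn, typed = FALSE)
    lab <- flood_components_oracle(mask, conn)
    expect_identical(components_to_partition(cc, dim(mask)),
                     partition_of(lab))
  }
})

test_that("minimum-size filtering removes exactly the sub-threshold components", {
  arr <- array(0L, c(20, 20, 20))
  arr[box_voxels(2:3, 2, 2)] <- 1L                 # size 2
  arr[box_voxels(8:10, 8, 8)] <- 1L                # size 3
  arr[box_voxels(14:16, 14, 14)] <- 1L
  arr[box_voxels(14:16, 15, 14)] <- 1L
  arr[14, 16, 14] <- 1L                            # size 7
  filt <- apply_min_size(arr, 3)
  cc <- connected_components(filt, typed = FALSE)
  expect_length(cc, 2)
  expect_setequal(vapply(cc, function(cm) cm$size, numeric(1)), c(3, 7))
  expect_identical(apply_min_size(arr, 1), arr)
  expect_identical(apply_min_size(filt, 3), filt)  # idempotent
  expect_error(apply_min_size(arr, 0), "min_voxels")
  # component count is monotone non-increasing in the size threshold
  set.seed(13)
  mask <- array(as.integer(runif(8000) < 0.15), c(20, 20, 20))
  counts <- vapply(1:6, function(mv)
    length(connected_components(apply_min_size(mask, mv), typed = FALSE)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("voxel metrics match hand arithmetic and flag undefined cases", {
  g <- array(0L, c(4, 4, 4)); p <- g
  p[1, 1, 1] <- 1L; p[1, 1, 2] <- 1L
  g[1, 1, 2] <- 1L; g[1, 1, 3] <- 1L
  vm <- voxel_metrics(p, g)
  expect_equal(vm$dsc, 0.5)
  expect_equal(vm$ppv, 0.5)
  expect_equal(vm$avd, 0)
  ident <- voxel_metrics(g, g)
  expect_equal(unlist(ident), c(dsc = 1, ppv = 1, avd = 0))
  # |P| = 8 inside |G| = 10
  g2 <- array(0L, c(5, 5, 5)); g2[1:10] <- 1L
  p2 <- array(0L, c(5, 5, 5)); p2[1:8] <- 1L
  expect_equal(voxel_metrics(p2, g2)$avd, 0.2)
  # DSC symmetric, AVD not
  expect_equal(voxel_metrics(p, g)$dsc, voxel_metrics(g, p)$dsc)
  expect_false(isTRUE(all.equal(voxel_metrics(p2, g2)$avd,
                                voxel_metrics(g2, p2)$avd)))
  empty <- array(0L, c(4, 4, 4))
  und <- voxel_metrics(p, empty)
  expect_true(is.na(und$dsc) && is.na(und$avd))
  expect_true(is.na(voxel_metrics(empty, g)$ppv))
  expect_equal(voxel_metrics(empty, g)$dsc, 0)
})

test_that("lesion-wise detection matches the enumerated example and edge cases", {
  arr <- array(0L, c(24, 24, 24))
  arr[box_voxels(2:4, 2:4, 2:4)] <- 1L     # WML A
  arr[box_voxels(10:12, 2:4, 2:4)] <- 1L   # WML B
  arr[box_voxels(18:20, 18:20, 18:20)] <- 2L  # CL C
  gtc <- connected_components(arr)
  pred <- array(0L, c(24, 24, 24))
  pred[box_voxels(3:5, 3:5, 3:5)] <- 1L    # hits A
  pred[box_voxels(18:19, 18:19, 18:19)] <- 1L  # hits C
  pred[box_voxels(10:12, 18:20, 2:4)] <- 1L    # hits nothing
  prc <- connected_components(pred, typed = FALSE)
  det <- lesion_detection(gtc, prc)
  expect_equal(det$ltpr, 2 / 3)
  expect_equal(det$ltpr_wm, 1 / 2)
  expect_equal(det$ltpr_cl, 1)
  expect_equal(det$lfpr, 1 / 3)
  # perfect prediction
  perf <- lesion_detection(gtc, connected_components((arr != 0) * 1L,
                                                     typed = FALSE))
  expect_equal(perf$ltpr, 1)
  expect_equal(perf$lfpr, 0)
  # empty prediction: LTPR 0, LFPR undefined
  none <- lesion_detection(gtc, connected_components(array(0L, c(24, 24, 24)),
                                                     typed = FALSE))
  expect_equal(none$ltpr, 0)
  expect_true(is.na(none$lfpr))
})

test_that("detection rates agree with a pairwise-overlap oracle on random masks", {
  set.seed(71)
  for (rep in 1:20) {
    gt <- random_typed_mask(p_fg = 0.08)
    pr <- (random_typed_mask(p_fg = 0.08) != 0) * 1L
    gtc <- connected_components(gt)
    prc <- connected_components(pr, typed = FALSE)
    det <- lesion_detection(gtc, prc)
    orc <- detection_oracle(gtc, prc)
    expect_identical(det$detected, orc$detected)
    expect_identical(det$false_positive, orc$false_positive)
    # LTPR decomposes into the type-wise rates weighted by GT counts
    types <- vapply(gtc, function(cm) cm$type, character(1))
    n_wm <- sum(types == "WML"); n_cl <- sum(types == "CL")
    if (n_wm > 0 && n_cl > 0)
      expect_equal(det$ltpr, (det$ltpr_wm * n_wm + det$ltpr_cl * n_cl) /
                     (n_wm + n_cl))
  }
})

test_that("size-stratified detection bins by [lo, hi) and recovers overall LTPR", {
  arr <- array(0L, c(30, 30, 30))
  arr[box_voxels(2:5, 2, 2)] <- 1L                # size 4, missed
  arr[box_voxels(10:13, 10:12, 10)] <- 1L         # size 12, detected
  arr[box_voxels(20:24, 20:22, 20)] <- 1L         # size 15, detected
  gtc <- connected_components(arr)
  pred <- array(0L, c(30, 30, 30))
  pred[box_voxels(10:13, 10:12, 10)] <- 1L
  pred[box_voxels(20:24, 20:22, 20)] <- 1L
  prc <- connected_components(pred, typed = FALSE)
  tab <- size_stratified_detection(gtc, prc, breaks = c(3, 11, Inf))
  expect_equal(tab$rate, c(0, 1))
  expect_equal(tab$n_gt, c(1L, 2L))
  # boundary convention: a size-10 lesion with breaks (3, 10, Inf) lands high
  b <- array(0L, c(20, 20, 20)); b[box_voxels(2:11, 2, 2)] <- 1L
  bc <- connected_components(b)
  tab2 <- size_stratified_detection(bc, bc, breaks = c(3, 10, Inf))
  expect_equal(tab2$n_gt, c(0L, 1L))
  # single covering bin reproduces the overall rate
  det <- lesion_detection(gtc, prc)
  tab3 <- size_stratified_detection(gtc, prc, breaks = c(3, Inf))
  expect_equal(tab3$rate, det$ltpr)
  expect_error(size_stratified_detection(gtc, prc, breaks = c(10, 3)),
               "increasing")
})

test_that("volume correlation reproduces the textbook Pearson formula", {
  man <- c(120, 340, 90, 800, 410)
  auto <- c(130, 300, 120, 760, 380)
  vc <- volume_correlation(man, auto)
  r_hand <- sum((man - mean(man)) * (auto - mean(auto))) /
    sqrt(sum((man - mean(man))^2) * sum((auto - mean(auto))^2))
  expect_equal(vc$r, r_hand, tolerance = 1e-12)
  ident <- volume_correlation(man, man)
  expect_equal(ident$r, 1)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-9)
  doubled <- volume_correlation(man, 2 * man)
  expect_equal(doubled$r, 1)
  expect_equal(doubled$slope, 2)
  expect_error(volume_correlation(man, rep(1, 5)), "variance")
  expect_error(volume_correlation(1:2, 1:2), "3 subjects")
})

test_that("paired Wilcoxon comparison matches exhaustive signed-rank enumeration", {
  a <- c(0.62, 0.55, 0.71, 0.48, 0.66, 0.59, 0.73, 0.51)
  b <- a - c(0.04, -0.02, 0.11, 0.01, 0.12, 0.09, 0.07, 0.05)
  res <- compare_methods(a, b, n_comparisons = 3)
  orc <- wilcoxon_oracle(a - b)
  expect_equal(res$statistic, orc$V)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  expect_equal(res$p_adjusted, min(1, orc$p * 3))
  # Bonferroni arithmetic on a known raw p
  expect_equal(compare_methods(a, b, 3)$p_adjusted,
               3 * compare_methods(a, b, 1)$p_value)
  # identical samples are undefined, not significant-by-default
  tie <- compare_methods(a, a)
  expect_true(is.na(tie$p_value) && is.na(tie$significant))
  expect_error(compare_methods(a[1:4], b[1:4]), "6")
})

test_that("cohort medians and IQRs are recomputable from the per-subject table", {
  per <- data.frame(subject_id = paste0("s", 1:5),
                    dsc = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    avd = c(0.5, 0.1, NA, 0.3, 0.2),
                    ppv = c(1, 1, 1, 1, 1),
                    ltpr = c(0, 0.5, 1, 0.25, 0.75),
                    ltpr_wm = NA_real_, ltpr_cl = NA_real_,
                    lfpr = c(0, 0, 0.5, 0.25, 1))
  rep <- metrics_report(per)
  s <- rep$summary
  expect_equal(s$median[s$metric == "dsc"], 0.3)
  expect_equal(s$iqr[s$metric == "dsc"], 0.2)
  expect_equal(s$median[s$metric == "avd"], 0.25)  # NA excluded
  expect_identical(s$n[s$metric == "avd"], 4L)
  expect_identical(s$n[s$metric == "ltpr_wm"], 0L)
  dir <- withr::local_tempdir()
  p <- write_metrics_report(rep, file.path(dir, "report.csv"))
  expect_true(file.exists(p))
  back <- read.csv(p, nrows = 5)
  expect_equal(back$dsc, per$dsc)
})

test_that("end-to-end case evaluation applies the 3-voxel rule to both masks", {
  gt <- array(0L, c(20, 20, 20))
  gt[box_voxels(2:4, 2, 2)] <- 1L      # size 3: survives
  gt[box_voxels(10, 10, 10:11)] <- 2L  # size 2: filtered from GT
  pred <- array(0L, c(20, 20, 20))
  pred[box_voxels(2:4, 2, 2)] <- 1L
  pred[15, 15, 15] <- 1L               # size 1: filtered from prediction
  row <- evaluate_case(pred, label_volume(gt), subject_id = "s1")
  expect_equal(row$dsc, 1)
  expect_equal(row$ltpr, 1)
  expect_identical(row$n_gt_lesions, 1L)   # the 2-voxel CL was dropped
  expect_identical(row$n_pred_lesions, 1L) # the 1-voxel FP was dropped
  expect_equal(row$lfpr, 0)
  expect_equal(row$manual_volume_ul, 3)
})
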