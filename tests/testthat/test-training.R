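test_that("learning-rate schedule hits its printed anchors and decays by halving", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 1e-8)
  expect_equal(lr_at(2000, cfg), 1e-4)
  expect_equal(lr_at(12000, cfg), 5e-5)
  expect_equal(lr_at(22000, cfg), 2.5e-5)
  # continuity at the end of warm-up
  expect_equal(lr_at(1999, cfg), lr_at(2000, cfg), tolerance = 1e-2)
  # non-increasing after warm-up, piecewise-constant plateaus of length 10000
  it <- seq(2000, 62000, by = 100)
  lrs <- lr_at(it, cfg)
  expect_true(all(diff(lrs) <= 0))
  runs <- rle(lrs)
  expect_true(all(runs$lengths[-length(runs$lengths)] == 100))
  expect_equal(lr_at(11999, cfg), 1e-4)
  expect_equal(lr_at(12001, cfg), 5e-5)
  # warm-up is monotone between the printed endpoints
  expect_true(all(diff(lr_at(0:2000, cfg)) > 0))
})

test_that("weighted cross-entropy matches closed forms and scalar oracles", {
  z0 <- array(0, c(4, 4, 4))
  tgt <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  ones <- array(1, c(4, 4, 4))
  expect_equal(weighted_cross_entropy(z0, tgt, ones), log(2), tolerance = 1e-12)
  # linear in the weights
  w <- array(sample(c(1, 5), 64, TRUE), c(4, 4, 4))
  z <- array(rnorm(64), c(4, 4, 4))
  expect_equal(weighted_cross_entropy(z, tgt, 2 * w),
               2 * weighted_cross_entropy(z, tgt, w), tolerance = 1e-12)
  # two-voxel toy against the naive -w * log p formulation
  z2 <- c(0.3, -1.1); t2 <- c(1, 0); w2 <- c(1, 5)
  p <- plogis(z2)
  naive <- mean(-w2 * (t2 * log(p) + (1 - t2) * log(1 - p)))
  expect_equal(weighted_cross_entropy(array(z2, c(2, 1, 1)),
                                      array(t2, c(2, 1, 1)),
                                      array(w2, c(2, 1, 1))),
               naive, tolerance = 1e-12)
  expect_error(weighted_cross_entropy(z0, tgt, array(1, c(3, 3, 3))),
               "shape")
  # gradient of the loss against central differences
  g <- cortseg:::weighted_cross_entropy_grad(z, tgt, w)
  eps <- 1e-6
  for (i in c(1, 30, 64)) {
    zp <- z; zp[i] <- z[i] + eps
    zm <- z; zm[i] <- z[i] - eps
    num <- (weighted_cross_entropy(zp, tgt, w) -
              weighted_cross_entropy(zm, tgt, w)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-6)
  }
})

test_that("patch sampling is uniform over components, not voxels", {
  # one 3-voxel and one 300-voxel lesion
  case <- make_toy_case(lesions = list(
    list(voxels = box_voxels(5:7, 5, 5), label = 1L),
    list(voxels = box_voxels(20:29, 20:25, 20:24), label = 1L)))
  comps <- connected_components(case$gt)
  expect_identical(sort(vapply(comps, function(c) c$size, numeric(1))),
                   c(3, 300))
  set.seed(17)
  picks <- replicate(2000, lesion_balanced_sample(
    case, comps, input_side = 44, extract = FALSE)$provenance$component_id)
  expect_lt(abs(mean(picks == 1) - 0.5), 0.05)
  # chi-square uniformity over five components of very different sizes
  case5 <- make_toy_case(lesions = list(
    list(voxels = box_voxels(4:6, 4, 4), label = 1L),
    list(voxels = box_voxels(12:19, 12:15, 12:14), label = 1L),
    list(voxels = box_voxels(30:39, 30:37, 30:35), label = 2L),
    list(voxels = box_voxels(4:5, 30:31, 30:31), label = 1L),
    list(voxels = box_voxels(40:44, 5:8, 40:42), label = 2L)))
  comps5 <- connected_components(case5$gt)
  expect_length(comps5, 5)
  set.seed(23)
  picks5 <- replicate(10000, lesion_balanced_sample(
    case5, comps5, input_side = 44, extract = FALSE)$provenance$component_id)
  gof <- suppressWarnings(chisq.test(tabulate(picks5, 5)))
  expect_gt(gof$p.value, 0.001)
})

test_that("sampled patches carry correct targets and CL weighting", {
  case <- make_toy_case(lesions = list(
    list(voxels = box_voxels(20:24, 20:24, 20:24), label = 1L),
    list(voxels = box_voxels(30:33, 30:33, 30:33), label = 2L)))
  set.seed(9)
  for (i in 1:10) {
    s <- lesion_balanced_sample(case, input_side = 44, jitter = 4)
    expect_identical(dim(s$input), c(44L, 44L, 44L, 2L))
    expect_identical(dim(s$target), c(4L, 4L, 4L))
    expect_true(all(s$weights %in% c(1, 5)))
    lab <- s$gt_patch[21:24, 21:24, 21:24]
    expect_identical(s$target, (lab != 0L) * 1)
    expect_identical(s$weights == 5, lab == 2L, ignore_attr = TRUE)
  }
  # single-component case: every sample is centered on it
  case1 <- make_toy_case(lesions = list(
    list(voxels = box_voxels(22:26, 22:26, 22:26), label = 1L)))
  set.seed(2)
  s <- lesion_balanced_sample(case1, input_side = 44, jitter = 0)
  expect_identical(s$provenance$component_id, 1L)
  expect_gt(sum(s$target), 0)
  # lesion-free cases are rejected
  empty <- make_toy_case(lesions = list())
  expect_error(lesion_balanced_sample(empty, input_side = 44),
               "no lesion")
})

test_that("augmentation preserves labels under exact transforms", {
  case <- make_toy_case(lesions = list(
    list(voxels = box_voxels(18:23, 20:24, 21:27), label = 1L),
    list(voxels = box_voxels(30:32, 30:32, 30:32), label = 2L)))
  set.seed(4)
  s <- lesion_balanced_sample(case, input_side = 44, jitter = 4)
  # identity draw returns the sample unchanged
  expect_identical(augment(s, angle = 0, scale = 1, flips = c(FALSE, FALSE, FALSE)),
                   s)
  # flip along axis 1 is an exact voxel permutation
  f <- augment(s, angle = 0, scale = 1, flips = c(TRUE, FALSE, FALSE))
  n <- 44L
  expect_equal(f$input[, , , 1], s$input[n:1, , , 1], tolerance = 1e-12)
  expect_identical(f$gt_patch, s$gt_patch[n:1, , ])
  expect_identical(f$target, s$target[4:1, , ])
  # 90-degree rotation about z is an exact permutation too
  r <- augment(s, angle = 90, scale = 1, flips = c(FALSE, FALSE, FALSE))
  expected <- array(0L, c(n, n, n))
  for (i in seq_len(n)) expected[i, , ] <- s$gt_patch[, n + 1L - i, ]
  expect_identical(r$gt_patch, expected)
  # weight values survive arbitrary augmentation
  set.seed(6)
  for (i in 1:10) {
    a <- augment(s)
    expect_true(all(a$weights %in% c(1, 5)))
    expect_identical(dim(a$input), dim(s$input))
    lab <- a$gt_patch[21:24, 21:24, 21:24]
    expect_identical(a$target, (lab != 0L) * 1)
  }
})

test_that("training is seeded, stops on patience, and memorizes a fixed patch", {
  micro <- unet_spec(encoder_filters = c(2, 4, 4, 4, 4), bottleneck_expand = 8,
                     decoder_filters = c(4, 4, 4, 4))
  case <- make_toy_case(lesions = list(
    list(voxels = box_voxels(22:27, 22:27, 22:27), label = 1L),
    list(voxels = box_voxels(33:35, 33:35, 33:35), label = 2L)))
  # frozen optimization (vanishingly small lr): validation loss never
  # improves after the first check, so patience 2 stops after exactly
  # 2 more checks
  frozen <- train_config(lr_floor = 1e-300, lr_peak = 1e-300,
                         warmup_iters = 2, halving_period = 10,
                         val_interval = 5, patience = 2, max_iters = 100,
                         input_side = 44, jitter = 2, augment = FALSE,
                         seed = 3)
  m <- build_model(micro, 1)
  fit <- train(m, list(case), list(case), frozen)
  expect_identical(nrow(fit$history), 15L)  # 3 checks x interval 5
  # seeded determinism of the full loop
  cfg <- train_config(lr_peak = 1e-3, warmup_iters = 5, halving_period = 50,
                      val_interval = 5, patience = 10, max_iters = 10,
                      input_side = 44, jitter = 2, seed = 11)
  f1 <- train(build_model(micro, 2), list(case), list(case), cfg)
  f2 <- train(build_model(micro, 2), list(case), list(case), cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  # memorization: a fixed lesion-centered patch is driven below 0.1 loss
  mem_case <- make_toy_case(lesions = list(
    list(voxels = box_voxels(22:27, 22:27, 22:27), label = 1L)))
  mem <- train_config(lr_peak = 3e-3, warmup_iters = 20, halving_period = 500,
                      val_interval = 100, patience = 5, max_iters = 500,
                      input_side = 44, jitter = 0, augment = FALSE,
                      batch_size = 1, seed = 7)
  fmem <- train(build_model(micro, 3), list(mem_case), list(mem_case), mem)
  expect_lt(min(fmem$history$train_loss), 0.1)
})
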