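spec_default <- unet_spec()

test_that("shape trace reproduces the valid-padding arithmetic", {
  tr88 <- trace_shapes(spec_default, 88)
  expect_identical(attr(tr88, "output_side"), 48L)
  expect_identical(attr(tr88, "margin"), 40L)
  # hand-derived trace for a 52-voxel input
  tr52 <- trace_shapes(spec_default, 52)
  expect_identical(attr(tr52, "output_side"), 12L)
  conv_sides <- tr52$output_side[tr52$type %in% c("conv", "pool", "upconv")]
  expect_identical(conv_sides,
                   c(50L, 48L, 24L, 22L, 20L, 10L, 8L, 6L, 12L, 10L, 8L,
                     16L, 14L, 12L, 12L))
  expect_error(trace_shapes(spec_default, 87), "odd side.*pool")
  expect_error(trace_shapes(spec_default, 20), "infeasible")
})

test_that("the input-output margin is the constant 40 for every feasible side", {
  for (s in 44:120) {
    tr <- tryCatch(trace_shapes(spec_default, s), error = function(e) NULL)
    if (is.null(tr)) next
    expect_identical(attr(tr, "margin"), 40L)
  }
})

test_that("receptive field is 41 voxels and consistent across traced inputs", {
  expect_identical(receptive_field(spec_default), 41L)
  tr88 <- trace_shapes(spec_default, 88)
  tr52 <- trace_shapes(spec_default, 52)
  expect_identical(41L, attr(tr88, "input_side") - attr(tr88, "output_side") + 1L)
  expect_identical(41L, attr(tr52, "input_side") - attr(tr52, "output_side") + 1L)
})

test_that("parameter counting matches independent oracles", {
  # closed form for an (almost) all-ones degenerate spec, worked by hand
  deg <- unet_spec(encoder_filters = c(1, 1, 1, 1, 1), bottleneck_expand = 2,
                   decoder_filters = c(1, 2, 1, 1))
  hand <- (27 * 2 + 1) * 1 + (27 + 1) +            # enc1a, enc1b
    (27 + 1) + (27 + 1) +                          # enc2a, enc2b
    (27 + 1) + (27 * 1 + 1) * 2 +                  # bot1, bot2
    (8 * 2 + 1) * 1 +                              # up1 (2 -> 1)
    (27 * 2 + 1) * 1 + (27 * 1 + 1) * 2 +          # dec1a (1+1 in), dec1b
    (8 * 2 + 1) * 1 +                              # up2 (2 -> 1)
    (27 * 2 + 1) * 1 + (27 + 1) +                  # dec2a (1+1 in), dec2b
    (1 * 1 + 1) * 1                                # 1^3 output projection
  expect_identical(count_parameters(deg), hand)
  # built-model array lengths are the strongest independent count
  set.seed(31)
  for (rep in 1:4) {
    enc <- sample(1:6, 5, replace = TRUE)
    spec <- unet_spec(encoder_filters = enc,
                      bottleneck_expand = 2 * sample(1:4, 1),
                      decoder_filters = c(sample(1:6, 1), 2 * sample(1:3, 1),
                                          sample(1:6, 1), sample(1:6, 1)))
    expect_identical(n_parameters(build_model(spec, rep)),
                     count_parameters(spec))
  }
  expect_identical(n_parameters(build_model(spec_default, 1)),
                   count_parameters(spec_default))
})

test_that("model building is seeded and the forward pass honors the shape contract", {
  tiny <- unet_spec(filter_div = 8)
  m1 <- build_model(tiny, init_seed = 5)
  m2 <- build_model(tiny, init_seed = 5)
  expect_identical(m1$params, m2$params)
  x <- array(0, c(88, 88, 88, 2))
  lg1 <- unet_forward(m1, x)
  expect_identical(dim(lg1), c(48L, 48L, 48L, 1L))
  expect_true(all(is.finite(lg1)))
  expect_identical(lg1, unet_forward(m2, x))
  m3 <- build_model(tiny, init_seed = 6)
  expect_false(identical(m1$params, m3$params))
  expect_error(unet_forward(m1, array(0, c(47, 47, 47, 2))), "infeasible")
  expect_error(unet_forward(m1, array(0, c(52, 52, 52, 3))), "in_channels")
})

test_that("direct convolution kernels agree with the im2col/GEMM route", {
  ops <- asNamespace("cortseg")
  set.seed(8)
  for (k in c(1L, 3L)) {
    x <- array(rnorm(10^3 * 3), c(10, 10, 10, 3))
    W <- matrix(rnorm(k^3 * 3 * 4), k^3 * 3, 4)
    b <- rnorm(4)
    y1 <- ops$conv3d_fwd(x, W, b, k)
    y2 <- ops$conv3d_fwd_gemm(x, W, b, k)
    expect_equal(y1, y2, tolerance = 1e-12)
    dy <- array(rnorm(length(y1)), dim(y1))
    g1 <- ops$conv3d_bwd(x, W, k, dy)
    g2 <- ops$conv3d_bwd_gemm(x, W, k, dy)
    expect_equal(g1$dx, g2$dx, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(g1$dW, g2$dW, tolerance = 1e-12)
    expect_equal(g1$db, g2$db, tolerance = 1e-12)
  }
})

test_that("valid convolution stack is translation-consistent at its pooling period", {
  # two pooling levels => equivariance under shifts of 4 voxels
  spec <- unet_spec(filter_div = 16)
  m <- build_model(spec, init_seed = 2)
  set.seed(3)
  v <- array(rnorm(56 * 52 * 52 * 2), c(56, 52, 52, 2))
  y1 <- unet_forward(m, v[1:52, , , , drop = FALSE])
  y2 <- unet_forward(m, v[5:56, , , , drop = FALSE])
  expect_equal(y1[5:12, , , , drop = FALSE], y2[1:8, , , , drop = FALSE],
               tolerance = 1e-10)
})

test_that("spec and weights serialize losslessly", {
  dir <- withr::local_tempdir()
  spec <- unet_spec(filter_div = 8)
  write_unet_spec(spec, file.path(dir, "spec.yaml"))
  expect_identical(read_unet_spec(file.path(dir, "spec.yaml")), spec)
  m <- build_model(spec, 11)
  save_model(m, file.path(dir, "m.rds"))
  m2 <- load_model(file.path(dir, "m.rds"))
  expect_identical(m2$params, m$params)
  x <- array(rnorm(44^3 * 2), c(44, 44, 44, 2))
  expect_identical(unet_forward(m, x), unet_forward(m2, x))
})
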