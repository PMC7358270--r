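#' Declarative 3D U-Net- architecture specification
#'
#' Describes the three-level valid-padding 3D U-Net ("3D U-Net-"): two-channel
#' input (FLAIR + MP2RAGE), unpadded 3^3 convolutions each followed by a ReLU,
#' 2^3 max pooling, 2^3 stride-2 up-convolutions that halve the channel count,
#' center-cropped skip concatenations, and a final 1^3 projection to a single
#' sigmoid lesion-probability channel. The default filter plan is the printed
#' one: encoder 32, 64, 64, 128, 128 (the fifth being the bottleneck's first
#' convolution), decoder 256, 128, 128, 64, 64, 1 (the leading 256 being the
#' bottleneck's second convolution, the trailing 1 the output projection).
#'
#' @param in_channels Number of input contrasts (default 2).
#' @param encoder_filters Five analysis-path convolution widths.
#' @param bottleneck_expand Output channels of the second bottleneck
#'   convolution (default 256).
#' @param decoder_filters Four synthesis-path convolution widths.
#' @param out_channels Output channels (default 1, sigmoid lesion probability).
#' @param conv_kernel Convolution kernel side (default 3, valid padding).
#' @param pool Pooling factor/stride (default 2).
#' @param upconv_kernel Up-convolution kernel/stride (default 2).
#' @param filter_div Integer divisor applied to all filter counts; used to
#'   build scaled-down variants (e.g. `filter_div = 8`) for CPU-sized runs.
#' @return A `unet_spec` object.
#' @export
unet_spec <- function(in_channels = 2,
                      encoder_filters = c(32, 64, 64, 128, 128),
                      bottleneck_expand = 256,
                      decoder_filters = c(128, 128, 64, 64),
                      out_channels = 1,
                      conv_kernel = 3, pool = 2, upconv_kernel = 2,
                      filter_div = 1) {
  stopifnot(length(encoder_filters) == 5, length(decoder_filters) == 4,
            filter_div >= 1)
  enc <- encoder_filters / filter_div
  dec <- decoder_filters / filter_div
  bot <- bottleneck_expand / filter_div
  if (any(c(enc, dec, bot) != round(c(enc, dec, bot))) ||
      any(c(enc, dec, bot) < 1))
    stop("filter_div must divide every filter count")
  if (bot %% 2 != 0 || dec[2] %% 2 != 0)
    stop("up-convolved channel counts must be even (channels are halved)")
  structure(list(in_channels = as.integer(in_channels),
                 resolution_levels = 3L,
                 encoder_filters = as.integer(enc),
                 bottleneck_expand = as.integer(bot),
                 decoder_filters = as.integer(dec),
                 out_channels = as.integer(out_channels),
                 conv_kernel = as.integer(conv_kernel),
                 pool = as.integer(pool),
                 upconv_kernel = as.integer(upconv_kernel)),
            class = "unet_spec")
}

# Ordered layer table derived from a spec: name, type, kernel, cin, cout.
# `skip_from` marks which encoder activation a concat merges in.
unet_layers <- function(spec) {
  e <- spec$encoder_filters; B <- spec$bottleneck_expand
  d <- spec$decoder_filters; k <- spec$conv_kernel
  cin <- spec$in_channels
  L <- list(
    list("enc1a", "conv", k, cin, e[1]),
    list("enc1b", "conv", k, e[1], e[2]),
    list("pool1", "pool", spec$pool, e[2], e[2]),
    list("enc2a", "conv", k, e[2], e[3]),
    list("enc2b", "conv", k, e[3], e[4]),
    list("pool2", "pool", spec$pool, e[4], e[4]),
    list("bot1",  "conv", k, e[4], e[5]),
    list("bot2",  "conv", k, e[5], B),
    list("up1",   "upconv", spec$upconv_kernel, B, B %/% 2L),
    list("cat1",  "concat", 0L, B %/% 2L, B %/% 2L + e[4]),
    list("dec1a", "conv", k, B %/% 2L + e[4], d[1]),
    list("dec1b", "conv", k, d[1], d[2]),
    list("up2",   "upconv", spec$upconv_kernel, d[2], d[2] %/% 2L),
    list("cat2",  "concat", 0L, d[2] %/% 2L, d[2] %/% 2L + e[2]),
    list("dec2a", "conv", k, d[2] %/% 2L + e[2], d[3]),
    list("dec2b", "conv", k, d[3], d[4]),
    list("outp",  "conv", 1L, d[4], spec$out_channels))
  do.call(rbind, lapply(L, function(r)
    data.frame(layer = r[[1]], type = r[[2]], kernel = r[[3]],
               cin = r[[4]], cout = r[[5]], stringsAsFactors = FALSE)))
}

#' Trace spatial side lengths through the network
#'
#' Applies the per-layer arithmetic of the valid-padding architecture (each
#' 3^3 convolution shrinks a side by 2, pooling halves it and requires an even
#' side, up-convolution doubles it) to a cubic input of side `input_side`.
#' For the three-level architecture the margin `input_side - output_side` is
#' the constant 40, so an 88^3 input yields a 48^3 output.
#'
#' @param spec A [unet_spec()].
#' @param input_side Cubic input patch side length in voxels.
#' @return A `shape_trace`: data frame of per-layer records with attributes
#'   `input_side`, `output_side` and `margin`.
#' @export
trace_shapes <- function(spec, input_side) {
  stopifnot(inherits(spec, "unet_spec"), input_side >= 1)
  layers <- unet_layers(spec)
  s <- as.integer(input_side)
  skip_sides <- integer(0)
  rows <- vector("list", nrow(layers))
  for (i in seq_len(nrow(layers))) {
    ly <- layers[i, ]
    s_in <- s
    if (ly$type == "conv") {
      s <- s - (ly$kernel - 1L)
      if (s < 1L)
        stop(sprintf("infeasible input: side %d vanishes at layer '%s'",
                     s_in, ly$layer))
    } else if (ly$type == "pool") {
      if (s %% 2L != 0L)
        stop(sprintf("infeasible input: odd side %d at pooling layer '%s'",
                     s, ly$layer))
      skip_sides <- c(skip_sides, s_in)  # encoder activation feeding the skip
      s <- s %/% 2L
    } else if (ly$type == "upconv") {
      s <- s * 2L
    } else if (ly$type == "concat") {
      skip <- skip_sides[length(skip_sides)]
      skip_sides <- skip_sides[-length(skip_sides)]
      if (skip < s || (skip - s) %% 2L != 0L)
        stop(sprintf("infeasible input: cannot center-crop skip side %d to %d at '%s'",
                     skip, s, ly$layer))
    }
    rows[[i]] <- data.frame(layer = ly$layer, type = ly$type,
                            input_side = s_in, output_side = s,
                            channels_out = ly$cout, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("shape_trace", "data.frame"),
            input_side = as.integer(input_side), output_side = s,
            margin = as.integer(input_side) - s)
}

#' @export
print.shape_trace <- function(x, ...) {
  cat(sprintf("shape trace: input %d -> output %d (margin %d)\n",
              attr(x, "input_side"), attr(x, "output_side"), attr(x, "margin")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

feasible_input_sides <- function(spec, candidates = 8:200) {
  ok <- logical(length(candidates))
  for (i in seq_along(candidates))
    ok[i] <- !inherits(try(trace_shapes(spec, candidates[i]), silent = TRUE),
                       "try-error")
  candidates[ok]
}

#' Receptive field (spatial context) of the network
#'
#' Side length of the input region that influences a single output voxel.
#' The architecture's overall stride is 1 (every pooling is compensated by an
#' up-convolution), so output voxel i is a function of the input window
#' starting at i of width `margin + 1`, with the margin constant across all
#' feasible input sides. For the default spec this is 41 voxels.
#'
#' @param spec A [unet_spec()].
#' @return Integer receptive-field side in voxels.
#' @export
receptive_field <- function(spec) {
  sides <- feasible_input_sides(spec, 8:120)
  if (length(sides) < 2) stop("no feasible input sides found")
  margins <- vapply(sides[1:2], function(s) attr(trace_shapes(spec, s), "margin"),
                    integer(1))
  if (margins[1] != margins[2]) stop("margin is not constant across inputs")
  margins[1] + 1L
}

#' Count trainable parameters of a spec
#'
#' Sums `(kernel_volume * c_in + 1) * c_out` over all convolutions and
#' up-convolutions (kernels plus biases). The default spec has 3,703,777
#' parameters, about 3.7 M, inside the printed 3.8 M budget.
#'
#' @param spec A [unet_spec()].
#' @return Total parameter count (numeric scalar).
#' @export
count_parameters <- function(spec) {
  layers <- unet_layers(spec)
  tot <- 0
  for (i in seq_len(nrow(layers))) {
    ly <- layers[i, ]
    if (ly$type == "conv") tot <- tot + (ly$kernel^3 * ly$cin + 1) * ly$cout
    else if (ly$type == "upconv") tot <- tot + (ly$kernel^3 * ly$cin + 1) * ly$cout
  }
  tot
}

he_uniform <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Instantiate a model from a spec
#'
#' Allocates seeded He-uniform weights (fan-in scaled) and zero biases for
#' every layer. The built model's parameter count equals
#' [count_parameters()] exactly.
#'
#' @param spec A [unet_spec()].
#' @param init_seed Integer seed for weight initialization.
#' @return A `unet_model` object (spec + named parameter list).
#' @export
build_model <- function(spec, init_seed = 1) {
  stopifnot(inherits(spec, "unet_spec"))
  layers <- unet_layers(spec)
  params <- list()
  with_seed(init_seed, {
    for (i in seq_len(nrow(layers))) {
      ly <- layers[i, ]
      if (ly$type == "conv") {
        params[[ly$layer]] <- list(
          W = he_uniform(ly$kernel^3 * ly$cin, ly$cout, ly$kernel^3 * ly$cin),
          b = numeric(ly$cout), kernel = ly$kernel, type = "conv")
      } else if (ly$type == "upconv") {
        params[[ly$layer]] <- list(
          W = he_uniform(ly$cin, 8L * ly$cout, ly$cin),
          b = numeric(ly$cout), kernel = ly$kernel, type = "upconv")
      }
    }
  })
  structure(list(spec = spec, params = params, init_seed = init_seed),
            class = "unet_model")
}

#' Number of trainable parameters of a built model
#' @param model A `unet_model`.
#' @return Numeric parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' Forward pass of the 3D U-Net-
#'
#' Propagates a `(s, s, s, in_channels)` patch through the network and returns
#' the `(s - 40, s - 40, s - 40, out_channels)` logits (apply
#' `stats::plogis()` for probabilities). With `cache = TRUE` all intermediate
#' activations needed by the backward pass are returned as well.
#'
#' @param model A `unet_model`.
#' @param x Input array `(side, side, side, in_channels)`.
#' @param cache Keep intermediates for backpropagation?
#' @return Logits array, or `list(logits, cache)` when `cache = TRUE`.
#' @export
unet_forward <- function(model, x, cache = FALSE) {
  p <- model$params
  d <- dim(x)
  if (length(d) != 4 || d[4] != model$spec$in_channels)
    stop("input must be (side, side, side, in_channels)")
  trace_shapes(model$spec, d[1])  # errors early on infeasible sides
  k <- model$spec$conv_kernel
  a1 <- relu(conv3d_fwd(x, p$enc1a$W, p$enc1a$b, k))
  a2 <- relu(conv3d_fwd(a1, p$enc1b$W, p$enc1b$b, k))
  pl1 <- maxpool_fwd(a2)
  a3 <- relu(conv3d_fwd(pl1$y, p$enc2a$W, p$enc2a$b, k))
  a4 <- relu(conv3d_fwd(a3, p$enc2b$W, p$enc2b$b, k))
  pl2 <- maxpool_fwd(a4)
  b1 <- relu(conv3d_fwd(pl2$y, p$bot1$W, p$bot1$b, k))
  b2 <- relu(conv3d_fwd(b1, p$bot2$W, p$bot2$b, k))
  u1 <- upconv_fwd(b2, p$up1$W, p$up1$b)
  c1 <- concat_channels(u1, crop_center(a4, dim(u1)[1]))
  d1 <- relu(conv3d_fwd(c1, p$dec1a$W, p$dec1a$b, k))
  d2 <- relu(conv3d_fwd(d1, p$dec1b$W, p$dec1b$b, k))
  u2 <- upconv_fwd(d2, p$up2$W, p$up2$b)
  c2 <- concat_channels(u2, crop_center(a2, dim(u2)[1]))
  d3 <- relu(conv3d_fwd(c2, p$dec2a$W, p$dec2a$b, k))
  d4 <- relu(conv3d_fwd(d3, p$dec2b$W, p$dec2b$b, k))
  logits <- conv3d_fwd(d4, p$outp$W, p$outp$b, 1L)
  if (!cache) return(logits)
  list(logits = logits,
       cache = list(x = x, a1 = a1, a2 = a2, pl1 = pl1, a3 = a3, a4 = a4,
                    pl2 = pl2, b1 = b1, b2 = b2, c1 = c1, d1 = d1, d2 = d2,
                    c2 = c2, d3 = d3, d4 = d4))
}

relu_bwd <- function(grad, act) {
  grad[act <= 0] <- 0
  grad
}

# Backward pass: gradient of a scalar loss w.r.t. every weight and bias given
# d(loss)/d(logits). Returns a list mirroring model$params with $dW/$db.
unet_backward <- function(model, cache, dlogits) {
  p <- model$params
  k <- model$spec$conv_kernel
  g <- list()
  bk <- conv3d_bwd(cache$d4, p$outp$W, 1L, dlogits)
  g$outp <- list(dW = bk$dW, db = bk$db)
  gr <- relu_bwd(bk$dx, cache$d4)
  bk <- conv3d_bwd(cache$d3, p$dec2b$W, k, gr)
  g$dec2b <- list(dW = bk$dW, db = bk$db)
  gr <- relu_bwd(bk$dx, cache$d3)
  bk <- conv3d_bwd(cache$c2, p$dec2a$W, k, gr)
  g$dec2a <- list(dW = bk$dW, db = bk$db)
  cu2 <- dim(cache$c2)[4] - dim(cache$a2)[4]  # channels that came from up2
  du2 <- bk$dx[, , , seq_len(cu2), drop = FALSE]
  da2_crop <- bk$dx[, , , (cu2 + 1):dim(cache$c2)[4], drop = FALSE]
  bk <- upconv_bwd(cache$d2, p$up2$W, du2)
  g$up2 <- list(dW = bk$dW, db = bk$db)
  gr <- relu_bwd(bk$dx, cache$d2)
  bk <- conv3d_bwd(cache$d1, p$dec1b$W, k, gr)
  g$dec1b <- list(dW = bk$dW, db = bk$db)
  gr <- relu_bwd(bk$dx, cache$d1)
  bk <- conv3d_bwd(cache$c1, p$dec1a$W, k, gr)
  g$dec1a <- list(dW = bk$dW, db = bk$db)
  cu1 <- dim(cache$c1)[4] - dim(cache$a4)[4]
  du1 <- bk$dx[, , , seq_len(cu1), drop = FALSE]
  da4_crop <- bk$dx[, , , (cu1 + 1):dim(cache$c1)[4], drop = FALSE]
  bk <- upconv_bwd(cache$b2, p$up1$W, du1)
  g$up1 <- list(dW = bk$dW, db = bk$db)
  gr <- relu_bwd(bk$dx, cache$b2)
  bk <- conv3d_bwd(cache$b1, p$bot2$W, k, gr)
  g$bot2 <- list(dW = bk$dW, db = bk$db)
  gr <- relu_bwd(bk$dx, cache$b1)
  bk <- conv3d_bwd(cache$pl2$y, p$bot1$W, k, gr)
  g$bot1 <- list(dW = bk$dW, db = bk$db)
  da4 <- maxpool_bwd(cache$pl2$arg, bk$dx, dim(cache$a4))
  da4 <- add_center(da4, da4_crop)
  gr <- relu_bwd(da4, cache$a4)
  bk <- conv3d_bwd(cache$a3, p$enc2b$W, k, gr)
  g$enc2b <- list(dW = bk$dW, db = bk$db)
  gr <- relu_bwd(bk$dx, cache$a3)
  bk <- conv3d_bwd(cache$pl1$y, p$enc2a$W, k, gr)
  g$enc2a <- list(dW = bk$dW, db = bk$db)
  da2 <- maxpool_bwd(cache$pl1$arg, bk$dx, dim(cache$a2))
  da2 <- add_center(da2, da2_crop)
  gr <- relu_bwd(da2, cache$a2)
  bk <- conv3d_bwd(cache$a1, p$enc1b$W, k, gr)
  g$enc1b <- list(dW = bk$dW, db = bk$db)
  gr <- relu_bwd(bk$dx, cache$a1)
  bk <- conv3d_bwd(cache$x, p$enc1a$W, k, gr)
  g$enc1a <- list(dW = bk$dW, db = bk$db)
  g[names(p)]
}

# Add `small` onto the spatial center of `big` (adjoint of crop_center).
add_center <- function(big, small) {
  db <- dim(big); ds <- dim(small)
  m <- (db[1:3] - ds[1:3]) %/% 2L
  ix <- (m[1] + 1L):(m[1] + ds[1]); iy <- (m[2] + 1L):(m[2] + ds[2])
  iz <- (m[3] + 1L):(m[3] + ds[3])
  big[ix, iy, iz, ] <- big[ix, iy, iz, , drop = FALSE] + small
  big
}

#' @export
print.unet_spec <- function(x, ...) {
  cat(sprintf(paste0("3D U-Net- spec: %d -> encoder %s | bottleneck %d | ",
                     "decoder %s -> %d\n"),
              x$in_channels, paste(x$encoder_filters, collapse = ","),
              x$bottleneck_expand, paste(x$decoder_filters, collapse = ","),
              x$out_channels))
  cat(sprintf("  valid %d^3 convs, %d^3 pool, %d^3 up-conv; %s parameters\n",
              x$conv_kernel, x$pool, x$upconv_kernel,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.unet_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  built model: %s trainable parameters (init seed %d)\n",
              format(n_parameters(x), big.mark = ","), x$init_seed))
  invisible(x)
}

#' Write / read an architecture spec as YAML
#' @param spec A [unet_spec()].
#' @param path File path.
#' @return `path` invisibly; `read_unet_spec()` returns a `unet_spec`.
#' @export
write_unet_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_unet_spec
#' @export
read_unet_spec <- function(path) {
  f <- yaml::read_yaml(path)
  unet_spec(in_channels = f$in_channels, encoder_filters = f$encoder_filters,
            bottleneck_expand = f$bottleneck_expand,
            decoder_filters = f$decoder_filters, out_channels = f$out_channels,
            conv_kernel = f$conv_kernel, pool = f$pool,
            upconv_kernel = f$upconv_kernel)
}

#' Save / load model weights
#'
#' Weights are serialized with R's native RDS format.
#'
#' @param model A `unet_model`.
#' @param path File path (`.rds`).
#' @return `path` invisibly; `load_model()` returns the `unet_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "unet_model"))
  m
}
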