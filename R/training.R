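#' Training configuration
#'
#' Defaults are the reference training recipe: class weights 1 (background), 1 (WML),
#' 5 (CL); L2 factor 1e-5; learning rate warmed up from 1e-8 to 1e-4 over the
#' first 2000 iterations and halved every 10,000 iterations thereafter; batch
#' size 2 with Adam (default moments). Early-stopping patience and the
#' validation interval are the package's own defaults (the recipe monitors
#' validation loss without printing numbers for either).
#'
#' @param class_weights Named vector `c(background, wml, cl)`.
#' @param l2_factor L2 regularization factor on convolution kernels.
#' @param lr_floor,lr_peak,warmup_iters,halving_period Learning-rate schedule.
#' @param batch_size Patches per Adam step.
#' @param patience Non-improving validation checks before stopping.
#' @param val_interval Iterations between validation evaluations.
#' @param max_iters Iteration cap.
#' @param input_side Input patch side in voxels (default 88; the output side
#'   is always `input_side - 40`).
#' @param jitter Patch-centering jitter in voxels per axis.
#' @param background_fraction Fraction of patches sampled at uniform random
#'   positions instead of lesion-centered (default 0, lesion-centered only).
#' @param augment Apply on-the-fly geometric augmentation?
#' @param seed Integer seed for all training randomness.
#' @return A `train_config` object.
#' @export
train_config <- function(class_weights = c(background = 1, wml = 1, cl = 5),
                         l2_factor = 1e-5, lr_floor = 1e-8, lr_peak = 1e-4,
                         warmup_iters = 2000, halving_period = 10000,
                         batch_size = 2, patience = 5, val_interval = 1000,
                         max_iters = 60000, input_side = 88, jitter = 12,
                         background_fraction = 0, augment = TRUE, seed = 1) {
  stopifnot(length(class_weights) == 3, lr_floor > 0, lr_peak >= lr_floor,
            warmup_iters >= 1, halving_period >= 1, batch_size >= 1,
            input_side > 40)
  if (is.null(names(class_weights)))
    names(class_weights) <- c("background", "wml", "cl")
  structure(list(class_weights = class_weights, l2_factor = l2_factor,
                 lr_floor = lr_floor, lr_peak = lr_peak,
                 warmup_iters = warmup_iters,
                 halving_period = halving_period, batch_size = batch_size,
                 patience = patience, val_interval = val_interval,
                 max_iters = max_iters, input_side = as.integer(input_side),
                 jitter = as.integer(jitter),
                 background_fraction = background_fraction,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Read / write a training configuration as YAML
#' @param config A [train_config()]; `path` a file path.
#' @return `read_train_config()` returns a `train_config`.
#' @export
write_train_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  f <- yaml::read_yaml(path)
  f$class_weights <- unlist(f$class_weights)
  do.call(train_config, f)
}

#' Learning rate at a given iteration
#'
#' Log-linear (geometric) warm-up from `lr_floor` (1e-8) at iteration 0 to
#' `lr_peak` (1e-4) at iteration `warmup_iters` (2000), then halving every
#' `halving_period` (10,000) iterations counted from the end of warm-up:
#' `lr_peak * 0.5^floor((it - warmup) / period)`.
#'
#' @param iteration Iteration count (vectorized, >= 0).
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @export
lr_at <- function(iteration, config = train_config()) {
  stopifnot(all(iteration >= 0))
  it <- as.numeric(iteration)
  warm <- config$lr_floor *
    (config$lr_peak / config$lr_floor)^(pmin(it, config$warmup_iters) /
                                          config$warmup_iters)
  decay <- config$lr_peak *
    0.5^floor(pmax(it - config$warmup_iters, 0) / config$halving_period)
  ifelse(it <= config$warmup_iters, warm, decay)
}

# Components of a case's ground truth, cached by callers of the sampler.
case_components <- function(case, connectivity = 18) {
  if (is.null(case$gt)) stop("case has no ground truth")
  connected_components(case$gt, connectivity = connectivity)
}

#' Draw one lesion-balanced training patch
#'
#' A ground-truth connected component is drawn uniformly over components
#' (regardless of size, so small cortical lesions are sampled as often as
#' large white-matter ones), then the input window is centered on a uniformly
#' drawn voxel of that component plus a small per-axis jitter, clipped so the
#' window stays inside the reflection-padded volume. The target is the
#' binarized label map restricted to the central output window; the weight
#' map is `class_weights["cl"]` exactly on CL voxels and
#' `class_weights["wml"]` elsewhere on lesions / background weight elsewhere.
#'
#' Draws from the current RNG stream; seed at the call site for
#' reproducibility.
#'
#' @param case A [subject_case()] with ground truth and >= 1 lesion.
#' @param components Optional precomputed [connected_components()] of the
#'   ground truth (computed on the fly otherwise).
#' @param input_side Input window side (output side is `input_side - 40`).
#' @param jitter Maximum per-axis centering jitter in voxels.
#' @param class_weights As in [train_config()].
#' @param extract Set `FALSE` to return only the sampling decision
#'   (component id and window position) without cutting patch arrays; used
#'   when auditing the sampling distribution.
#' @return A `patch_sample`: list with `input` (in^3 x 2), `gt_patch`
#'   (in^3 labels), `target` and `weights` (out^3), and `provenance`.
#' @export
lesion_balanced_sample <- function(case, components = NULL, input_side = 88,
                                   jitter = 12,
                                   class_weights = c(background = 1, wml = 1,
                                                     cl = 5),
                                   extract = TRUE) {
  if (is.null(components)) components <- case_components(case)
  if (length(components) == 0)
    stop("case has no lesion components; lesion-balanced sampling undefined")
  ci <- sample.int(length(components), 1)
  comp <- components[[ci]]
  vx <- comp$voxels[sample.int(nrow(comp$voxels), 1), ]
  jit <- if (jitter > 0) sample(seq(-jitter, jitter), 3, replace = TRUE)
         else c(0L, 0L, 0L)
  center <- vx + jit
  dims <- dim(case$flair$data)
  margin <- 40L
  pad <- margin %/% 2L
  half <- input_side %/% 2L
  # window start in padded coordinates, clipped to stay inside
  start <- pmin(pmax(center - half + 1L + pad, 1L),
                dims + 2L * pad - input_side + 1L)
  prov <- list(subject_id = case$subject_id, component_id = ci,
               center = center, start = start)
  if (!extract) return(structure(list(provenance = prov),
                                 class = "patch_sample"))
  cut_patch <- function(arr) {
    p <- pad_reflect3d(arr, pad)
    p[start[1]:(start[1] + input_side - 1L),
      start[2]:(start[2] + input_side - 1L),
      start[3]:(start[3] + input_side - 1L)]
  }
  input <- array(0, c(input_side, input_side, input_side, 2L))
  input[, , , 1] <- cut_patch(case$flair$data)
  input[, , , 2] <- cut_patch(case$mp2rage$data)
  gt_patch <- cut_patch(case$gt$labels)
  storage.mode(gt_patch) <- "integer"
  finish_patch_sample(input, gt_patch, class_weights, prov)
}

# Derive target and weight maps from the (input-sized) label patch.
finish_patch_sample <- function(input, gt_patch, class_weights, prov) {
  input_side <- dim(input)[1]
  out_side <- input_side - 40L
  m <- (input_side - out_side) %/% 2L
  sel <- (m + 1L):(m + out_side)
  lab <- gt_patch[sel, sel, sel]
  target <- (lab != 0L) * 1
  weights <- array(class_weights[["wml"]], dim(lab))
  weights[lab == 0L] <- class_weights[["background"]]
  weights[lab == 2L] <- class_weights[["cl"]]
  structure(list(input = input, gt_patch = gt_patch, target = target,
                 weights = weights, provenance = prov),
            class = "patch_sample")
}

#' Per-voxel weighted binary cross-entropy from logits
#'
#' Mean over voxels of `weight * BCE(sigmoid(logit), target)`, computed in
#' the numerically stable logits form. Non-negative; approaches zero only as
#' predictions saturate towards the targets.
#'
#' @param logits,target,weights Arrays of identical shape.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(logits, target, weights) {
  if (!identical(dim(logits)[1:3], dim(target)[1:3]) ||
      !identical(dim(target)[1:3], dim(weights)[1:3]))
    stop("shape mismatch between logits, target and weights")
  z <- as.vector(logits); t <- as.vector(target); w <- as.vector(weights)
  mean(w * (pmax(z, 0) - z * t + log1p(exp(-abs(z)))))
}

# Gradient of weighted_cross_entropy w.r.t. the logits.
weighted_cross_entropy_grad <- function(logits, target, weights) {
  g <- as.vector(weights) * (plogis(as.vector(logits)) - as.vector(target)) /
    length(logits)
  dim(g) <- dim(logits)
  g
}

#' Randomly augment a training patch
#'
#' Rotation about the z axis (uniform in -90..90 degrees), isotropic spatial
#' scaling (uniform in 0.95..1.05) and independent flips along all three axes
#' (probability 1/2 each), all about the patch center. Intensity channels are
#' interpolated trilinearly; the label patch by nearest neighbor, so weight
#' values remain exactly in the configured set. The target/weight maps are
#' re-derived from the transformed label patch. Identity draws return the
#' sample unchanged.
#'
#' @param sample A `patch_sample` from [lesion_balanced_sample()].
#' @param class_weights As in [train_config()].
#' @param angle,scale,flips Override the random draws (degrees, factor,
#'   logical length-3); `NULL` draws from the current RNG stream.
#' @return The augmented `patch_sample`.
#' @export
augment <- function(sample, class_weights = c(background = 1, wml = 1, cl = 5),
                    angle = NULL, scale = NULL, flips = NULL) {
  angle <- angle %||% runif(1, -90, 90)
  scale <- scale %||% runif(1, 0.95, 1.05)
  flips <- flips %||% (runif(3) < 0.5)
  if (angle == 0 && scale == 1 && !any(flips)) return(sample)
  n <- dim(sample$input)[1]
  ctr <- (n + 1) / 2
  th <- angle * pi / 180
  # inverse map: output voxel -> source voxel (rotate by -angle, divide scale)
  g <- as.matrix(expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n)))
  cx <- g[, 1] - ctr; cy <- g[, 2] - ctr; cz <- g[, 3] - ctr
  if (flips[1]) cx <- -cx
  if (flips[2]) cy <- -cy
  if (flips[3]) cz <- -cz
  sx <- (cos(th) * cx + sin(th) * cy) / scale + ctr
  sy <- (-sin(th) * cx + cos(th) * cy) / scale + ctr
  sz <- cz / scale + ctr
  input <- sample$input
  for (ch in seq_len(dim(input)[4]))
    input[, , , ch] <- array(trilinear3d(sample$input[, , , ch], sx, sy, sz),
                             c(n, n, n))
  gt_patch <- array(nearest3d(sample$gt_patch, sx, sy, sz), c(n, n, n))
  storage.mode(gt_patch) <- "integer"
  finish_patch_sample(input, gt_patch, class_weights, sample$provenance)
}

# Trilinear interpolation of 3D array `a` at (possibly fractional)
# coordinates; out-of-range coordinates are clamped to the volume edge.
trilinear3d <- function(a, sx, sy, sz) {
  d <- dim(a)
  sx <- pmin(pmax(sx, 1), d[1]); sy <- pmin(pmax(sy, 1), d[2])
  sz <- pmin(pmax(sz, 1), d[3])
  x0 <- pmin(floor(sx), d[1] - 1); y0 <- pmin(floor(sy), d[2] - 1)
  z0 <- pmin(floor(sz), d[3] - 1)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  at <- function(ix, iy, iz) a[cbind(ix, iy, iz)]
  v000 <- at(x0, y0, z0);     v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0); v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1); v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# Nearest-neighbor lookup; coordinates outside the patch map to background 0.
nearest3d <- function(a, sx, sy, sz) {
  d <- dim(a)
  ix <- round(sx); iy <- round(sy); iz <- round(sz)
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  out <- numeric(length(sx))
  out[ok] <- a[cbind(ix[ok], iy[ok], iz[ok])]
  out
}

# ---- optimizer ------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p)
    list(mW = matrix(0, nrow(p$W), ncol(p$W)), vW = matrix(0, nrow(p$W), ncol(p$W)),
         mb = numeric(length(p$b)), vb = numeric(length(p$b))))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# ---- training loop --------------------------------------------------------

# Deterministic validation patches: one un-augmented patch centered at each
# ground-truth component centroid.
validation_patches <- function(case, components, input_side, class_weights) {
  lapply(seq_along(components), function(ci) {
    comp <- components[[ci]]
    center <- round(colMeans(comp$voxels))
    dims <- dim(case$flair$data)
    pad <- 20L
    start <- pmin(pmax(center - input_side %/% 2L + 1L + pad, 1L),
                  dims + 2L * pad - input_side + 1L)
    cut_patch <- function(arr) {
      p <- pad_reflect3d(arr, pad)
      p[start[1]:(start[1] + input_side - 1L),
        start[2]:(start[2] + input_side - 1L),
        start[3]:(start[3] + input_side - 1L)]
    }
    input <- array(0, c(input_side, input_side, input_side, 2L))
    input[, , , 1] <- cut_patch(case$flair$data)
    input[, , , 2] <- cut_patch(case$mp2rage$data)
    gt_patch <- cut_patch(case$gt$labels)
    storage.mode(gt_patch) <- "integer"
    finish_patch_sample(input, gt_patch, class_weights,
                        list(subject_id = case$subject_id, component_id = ci))
  })
}

#' Train a model
#'
#' Adam steps on batches of lesion-balanced (optionally augmented) patches
#' with the class-weighted cross-entropy loss plus an L2 penalty
#' (`l2_factor / 2 * sum(W^2)`, kernels only) under the warm-up/halving
#' learning-rate schedule. Every `val_interval` iterations the same weighted
#' loss is evaluated on deterministic, un-augmented validation patches;
#' training stops when it fails to improve for `patience` consecutive checks
#' or at `max_iters`, and the weights of the best validation checkpoint are
#' returned.
#'
#' Input channels are z-scored internally ([zscore_normalize()]) before
#' sampling, matching the inference contract.
#'
#' @param model A [build_model()] handle.
#' @param train_cases,val_cases Lists of [subject_case()]s with ground truth
#'   (each with at least one lesion).
#' @param config A [train_config()].
#' @param verbose Print progress lines?
#' @return A `train_result`: `model` (best checkpoint), `history` (data frame
#'   with iteration, lr, train_loss, val_loss), `best_iteration`,
#'   `best_val_loss`.
#' @export
train <- function(model, train_cases, val_cases, config = train_config(),
                  verbose = FALSE) {
  if (inherits(train_cases, "subject_case")) train_cases <- list(train_cases)
  if (inherits(val_cases, "subject_case")) val_cases <- list(val_cases)
  stopifnot(length(train_cases) >= 1, length(val_cases) >= 1)
  norm_case <- function(cs) {
    cs$flair <- zscore_normalize(cs$flair)
    cs$mp2rage <- zscore_normalize(cs$mp2rage)
    cs
  }
  train_cases <- lapply(train_cases, norm_case)
  val_cases <- lapply(val_cases, norm_case)
  tr_comps <- lapply(train_cases, case_components)
  if (any(vapply(tr_comps, length, integer(1)) == 0))
    stop("every training case needs at least one lesion component")
  val_comps <- lapply(val_cases, case_components)
  cw <- config$class_weights
  val_sets <- mapply(validation_patches, val_cases, val_comps,
                     MoreArgs = list(input_side = config$input_side,
                                     class_weights = cw),
                     SIMPLIFY = FALSE)
  val_sets <- do.call(c, val_sets)
  params <- model$params
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, iteration = 0L)
  bad_checks <- 0L
  hist <- list()
  val_loss_of <- function(params) {
    m <- model; m$params <- params
    mean(vapply(val_sets, function(s) {
      weighted_cross_entropy(unet_forward(m, s$input), s$target, s$weights)
    }, numeric(1)))
  }
  with_seed(config$seed, {
    for (it in seq_len(config$max_iters)) {
      lr <- lr_at(it, config)
      grads <- NULL
      data_loss <- 0
      for (bi in seq_len(config$batch_size)) {
        ti <- sample.int(length(train_cases), 1)
        s <- lesion_balanced_sample(train_cases[[ti]], tr_comps[[ti]],
                                    input_side = config$input_side,
                                    jitter = config$jitter,
                                    class_weights = cw)
        if (config$augment) s <- augment(s, class_weights = cw)
        m <- model; m$params <- params
        fw <- unet_forward(m, s$input, cache = TRUE)
        data_loss <- data_loss +
          weighted_cross_entropy(fw$logits, s$target, s$weights)
        dl <- weighted_cross_entropy_grad(fw$logits, s$target, s$weights)
        g <- unet_backward(m, fw$cache, dl)
        grads <- if (is.null(grads)) g else
          mapply(function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db),
                 grads, g, SIMPLIFY = FALSE)
      }
      data_loss <- data_loss / config$batch_size
      if (!is.finite(data_loss))
        stop(sprintf("non-finite training loss at iteration %d", it))
      l2 <- 0
      for (nm in names(params)) {
        grads[[nm]]$dW <- grads[[nm]]$dW / config$batch_size +
          config$l2_factor * params[[nm]]$W
        grads[[nm]]$db <- grads[[nm]]$db / config$batch_size
        l2 <- l2 + sum(params[[nm]]$W^2)
      }
      loss <- data_loss + config$l2_factor / 2 * l2
      up <- adam_step(params, grads, state, lr, it)
      params <- up$params; state <- up$state
      vl <- NA_real_
      if (it %% config$val_interval == 0 || it == config$max_iters) {
        vl <- val_loss_of(params)
        if (verbose)
          message(sprintf("iter %d lr %.3g train %.4f val %.4f", it, lr,
                          loss, vl))
        if (vl < best$loss) {
          best <- list(loss = vl, params = params, iteration = it)
          bad_checks <- 0L
        } else {
          bad_checks <- bad_checks + 1L
        }
      }
      hist[[length(hist) + 1L]] <- data.frame(iteration = it, lr = lr,
                                              train_loss = loss,
                                              val_loss = vl)
      if (bad_checks >= config$patience) break
    }
  })
  out_model <- model
  out_model$params <- best$params
  structure(list(model = out_model, history = do.call(rbind, hist),
                 best_iteration = best$iteration, best_val_loss = best$loss),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(paste0("train_result: %d iterations, best validation loss ",
                     "%.4f at iteration %d\n"),
              n, x$best_val_loss, x$best_iteration))
  invisible(x)
}
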