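# Internal neural-network primitives. All activations are dense arrays of
# shape (x, y, z, channels); convolution weights are stored as matrices of
# shape (k^3 * c_in, c_out) matching the im2col column ordering, transposed
# convolutions as (c_in, 8 * c_out) with column index (co - 1) * 8 + offset.

conv3d_fwd <- function(x, W, b, k) {
  conv3d_direct(x, dim(x), W, b, as.integer(k))
}

conv3d_bwd <- function(x, W, k, dy) {
  conv3d_direct_bwd(x, dim(x), W, dy, as.integer(k))
}

# Reference implementation of the valid convolution via im2col + GEMM.
# Kept as an independent route for cross-checking the direct kernels.
conv3d_fwd_gemm <- function(x, W, b, k) {
  d <- dim(x)
  ox <- d[1] - k + 1
  out <- im2col3d(x, d, k) %*% W
  out <- out + rep(b, each = nrow(out))
  array(out, c(ox, d[2] - k + 1, d[3] - k + 1, ncol(W)))
}

conv3d_bwd_gemm <- function(x, W, k, dy) {
  d <- dim(x)
  cols <- im2col3d(x, d, k)
  dym <- matrix(dy, nrow(cols), ncol(W))
  list(dx = col2im3d(tcrossprod(dym, W), d, k),
       dW = crossprod(cols, dym), db = colSums(dym))
}

# 2x2x2 max pooling, stride 2. Sides must be even. Returns the pooled array
# and the argmax offset (0..7) needed for the backward pass.
maxpool_fwd <- function(x) {
  d <- dim(x)
  if (any(d[1:3] %% 2 != 0)) stop("odd side length at pooling layer")
  od <- c(d[1:3] %/% 2L, d[4])
  best <- array(-Inf, od)
  arg <- array(0L, od)
  sx <- seq(1L, d[1], 2L); sy <- seq(1L, d[2], 2L); sz <- seq(1L, d[3], 2L)
  for (o in 0:7) {
    a <- o %% 2L; bo <- (o %/% 2L) %% 2L; co <- o %/% 4L
    sl <- x[sx + a, sy + bo, sz + co, , drop = FALSE]
    m <- sl > best
    best[m] <- sl[m]
    arg[m] <- o
  }
  list(y = best, arg = arg)
}

maxpool_bwd <- function(arg, dy, in_dims) {
  dx <- array(0, in_dims)
  sx <- seq(1L, in_dims[1], 2L); sy <- seq(1L, in_dims[2], 2L)
  sz <- seq(1L, in_dims[3], 2L)
  for (o in 0:7) {
    a <- o %% 2L; bo <- (o %/% 2L) %% 2L; co <- o %/% 4L
    m <- arg == o
    if (!any(m)) next
    sl <- array(0, dim(dy))
    sl[m] <- dy[m]
    dx[sx + a, sy + bo, sz + co, ] <- sl
  }
  dx
}

# Transposed convolution, kernel 2, stride 2 (blocks do not overlap): each
# input voxel maps linearly onto its 2x2x2 output block.
upconv_fwd <- function(x, W, b) {
  d <- dim(x)
  cin <- d[4]; cout <- ncol(W) %/% 8L
  if (nrow(W) != cin) stop("upconv weight/input channel mismatch")
  n <- prod(d[1:3])
  Y <- matrix(x, n, cin) %*% W
  out <- array(0, c(2L * d[1], 2L * d[2], 2L * d[3], cout))
  sx <- seq(1L, 2L * d[1], 2L); sy <- seq(1L, 2L * d[2], 2L)
  sz <- seq(1L, 2L * d[3], 2L)
  for (o in 0:7) {
    a <- o %% 2L; bo <- (o %/% 2L) %% 2L; co <- o %/% 4L
    cols <- (seq_len(cout) - 1L) * 8L + o + 1L
    out[sx + a, sy + bo, sz + co, ] <-
      array(Y[, cols, drop = FALSE], c(d[1:3], cout)) + rep(b, each = n)
  }
  out
}

upconv_bwd <- function(x, W, dy) {
  d <- dim(x)
  cin <- d[4]; cout <- ncol(W) %/% 8L
  n <- prod(d[1:3])
  dY <- matrix(0, n, ncol(W))
  sx <- seq(1L, 2L * d[1], 2L); sy <- seq(1L, 2L * d[2], 2L)
  sz <- seq(1L, 2L * d[3], 2L)
  for (o in 0:7) {
    a <- o %% 2L; bo <- (o %/% 2L) %% 2L; co <- o %/% 4L
    cols <- (seq_len(cout) - 1L) * 8L + o + 1L
    dY[, cols] <- matrix(dy[sx + a, sy + bo, sz + co, , drop = FALSE], n, cout)
  }
  Xm <- matrix(x, n, cin)
  db <- numeric(cout)
  for (co in seq_len(cout))
    db[co] <- sum(dY[, (co - 1L) * 8L + 1:8])
  dx <- dY %*% t(W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(Xm, dY), db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Center-crop the spatial sides of (x,y,z,c) array `a` to side `side`.
crop_center <- function(a, side) {
  d <- dim(a)
  m <- (d[1:3] - side) %/% 2L
  a[(m[1] + 1L):(m[1] + side), (m[2] + 1L):(m[2] + side),
    (m[3] + 1L):(m[3] + side), , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}
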