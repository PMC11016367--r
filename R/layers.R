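# Building blocks of the network: Mish, causal convolutions, the gated
# convolutional (GLU) block, the branched convolution block with a depthwise
# separable merge, axial positional embeddings, the class token and layer
# normalization. Every primitive comes as a forward pass that records a cache
# and a backward pass consuming it; gradients are exact and checked against
# finite differences in the test suite.

## ---- initializers (draw from the current RNG state) ----

init_linear <- function(c_in, c_out) {
  lim <- sqrt(6 / (c_in + c_out))
  list(W = matrix(stats::runif(c_in * c_out, -lim, lim), c_in, c_out),
       b = numeric(c_out))
}

init_conv <- function(k, c_in, c_out) {
  lim <- sqrt(6 / (k * c_in + c_out))
  list(W = array(stats::runif(k * c_in * c_out, -lim, lim), c(k, c_in, c_out)),
       b = numeric(c_out))
}

init_depthwise <- function(k, channels) {
  lim <- sqrt(6 / (k + 1))
  list(W = matrix(stats::runif(k * channels, -lim, lim), k, channels),
       b = numeric(channels))
}

## ---- pointwise (per-timestep) linear layer ----

pw_fwd <- function(x, p) {
  n <- dim(x)[1]; l <- dim(x)[2]
  y <- mat3(x) %*% p$W
  y <- sweep(y, 2, p$b, `+`)
  list(y = unmat3(y, n, l), cache = list(x = x))
}

pw_bwd <- function(dy, p, cache) {
  n <- dim(dy)[1]; l <- dim(dy)[2]
  dym <- mat3(dy)
  xm <- mat3(cache$x)
  list(dx = unmat3(dym %*% t(p$W), n, l),
       grad = list(W = t(xm) %*% dym, b = colSums(dym)))
}

## ---- causal convolution (left zero-padded by k - 1) ----

conv_fwd <- function(x, p) {
  k <- dim(p$W)[1]
  n <- dim(x)[1]; l <- dim(x)[2]
  y <- matrix(rep(p$b, each = n * l), n * l, dim(p$W)[3])
  for (tau in 0:(k - 1)) {
    kernel <- matrix(p$W[tau + 1, , ], dim(p$W)[2], dim(p$W)[3])
    y <- y + mat3(time_shift(x, tau)) %*% kernel
  }
  list(y = unmat3(y, n, l), cache = list(x = x))
}

conv_bwd <- function(dy, p, cache) {
  k <- dim(p$W)[1]
  n <- dim(dy)[1]; l <- dim(dy)[2]
  dym <- mat3(dy)
  dx <- array(0, dim = dim(cache$x))
  dW <- array(0, dim = dim(p$W))
  for (tau in 0:(k - 1)) {
    kernel <- matrix(p$W[tau + 1, , ], dim(p$W)[2], dim(p$W)[3])
    dx <- dx + time_unshift(unmat3(dym %*% t(kernel), n, l), tau)
    dW[tau + 1, , ] <- t(mat3(time_shift(cache$x, tau))) %*% dym
  }
  list(dx = dx, grad = list(W = dW, b = colSums(dym)))
}

## ---- depthwise causal convolution ----

dw_fwd <- function(x, p) {
  k <- nrow(p$W)
  n <- dim(x)[1]; l <- dim(x)[2]; ch <- dim(x)[3]
  y <- array(rep(p$b, each = n * l), dim = dim(x))
  for (tau in 0:(k - 1)) {
    wrow <- array(rep(p$W[tau + 1, ], each = n * l), dim = dim(x))
    y <- y + time_shift(x, tau) * wrow
  }
  list(y = y, cache = list(x = x))
}

dw_bwd <- function(dy, p, cache) {
  k <- nrow(p$W)
  n <- dim(dy)[1]; l <- dim(dy)[2]
  dx <- array(0, dim = dim(cache$x))
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  for (tau in 0:(k - 1)) {
    wrow <- array(rep(p$W[tau + 1, ], each = n * l), dim = dim(dy))
    dx <- dx + time_unshift(dy * wrow, tau)
    dW[tau + 1, ] <- colSums(mat3(time_shift(cache$x, tau) * dy))
  }
  list(dx = dx, grad = list(W = dW, b = colSums(mat3(dy))))
}

## ---- Mish activation ----

softplus_stable <- function(x) {
  out <- x
  low <- x <= 20
  out[low] <- log1p(exp(x[low]))
  out
}

mish_fwd <- function(x) {
  y <- x * tanh(softplus_stable(x))
  list(y = y, cache = list(x = x))
}

mish_bwd <- function(dy, cache) {
  x <- cache$x
  tsp <- tanh(softplus_stable(x))
  sig <- 1 / (1 + exp(-x))
  dy * (tsp + x * (1 - tsp^2) * sig)
}

#' Mish activation
#'
#' Elementwise `x * tanh(softplus(x))`; smooth, non-monotone, and the
#' activation used throughout the network's gates and head.
#'
#' @param x Numeric vector, matrix or array.
#'
#' @return Same shape as `x`.
#' @export
mish <- function(x) x * tanh(softplus_stable(x))

## ---- layer normalization (over the feature dimension, per position) ----

ln_fwd <- function(x, p, eps = 1e-5) {
  n <- dim(x)[1]; l <- dim(x)[2]; d <- dim(x)[3]
  xm <- mat3(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, p$g, `*`), 2, p$b, `+`)
  list(y = unmat3(y, n, l),
       cache = list(xc = xc, inv = inv, xhat = xhat, n = n, l = l, d = d))
}

ln_bwd <- function(dy, p, cache) {
  d <- cache$d
  dym <- mat3(dy)
  dxhat <- sweep(dym, 2, p$g, `*`)
  dvar <- rowSums(dxhat * cache$xc) * (-0.5) * cache$inv^3
  dmu <- -rowSums(dxhat) * cache$inv
  dx <- dxhat * cache$inv + (2 / d) * dvar * cache$xc + dmu / d
  list(dx = unmat3(dx, cache$n, cache$l),
       grad = list(g = colSums(dym * cache$xhat), b = colSums(dym)))
}

#' Layer normalization
#'
#' Normalizes each sequence position over the feature dimension, then applies
#' a learnable scale and shift. Applied before every block (pre-norm wiring).
#'
#' @param x L x d matrix or N x L x d array.
#' @param gamma,beta Optional length-d scale and shift (default 1 and 0).
#' @param epsilon Variance stabilizer.
#'
#' @return Same shape as `x`.
#' @export
layer_norm <- function(x, gamma = NULL, beta = NULL, epsilon = 1e-5) {
  was_mat <- is.matrix(x)
  xb <- as_batch3(x)
  d <- dim(xb)[3]
  p <- list(g = gamma %||% rep(1, d), b = beta %||% rep(0, d))
  y <- ln_fwd(xb, p, eps = epsilon)$y
  if (was_mat) y[1, , ] else y
}

## ---- gated convolutional (GLU) block ----

#' Parameters for a gated convolutional block
#'
#' Two causal convolutions of shared kernel size map the d-wide input to a
#' narrow bottleneck; one branch is passed through Mish and gates the other
#' by elementwise multiplication; a pointwise projection returns to width d.
#'
#' @param d Model width.
#' @param kernel_size Causal convolution kernel size.
#' @param bottleneck Bottleneck width (default `max(1, round(d/4))`).
#' @param seed Integer seed for initialization.
#'
#' @return Parameter list with fields `conv_a`, `conv_g`, `proj`.
#' @export
glu_block_params <- function(d, kernel_size = 3, bottleneck = NULL, seed = 1L) {
  b <- bottleneck %||% max(1L, round(d / 4))
  if (b > d) config_error("bottleneck width must not exceed model width")
  with_seed(seed, list(
    conv_a = init_conv(kernel_size, d, b),
    conv_g = init_conv(kernel_size, d, b),
    proj = init_linear(b, d)
  ))
}

glu_core_fwd <- function(x, p) {
  a <- conv_fwd(x, p$conv_a)
  g <- conv_fwd(x, p$conv_g)
  m <- mish_fwd(g$y)
  gated <- a$y * m$y
  proj <- pw_fwd(gated, p$proj)
  list(y = proj$y, cache = list(a = a, g = g, m = m, proj = proj))
}

glu_core_bwd <- function(dy, p, cache) {
  bp <- pw_bwd(dy, p$proj, cache$proj$cache)
  da <- bp$dx * cache$m$y
  dm <- bp$dx * cache$a$y
  dg <- mish_bwd(dm, cache$m$cache)
  ba <- conv_bwd(da, p$conv_a, cache$a$cache)
  bg <- conv_bwd(dg, p$conv_g, cache$g$cache)
  list(dx = ba$dx + bg$dx,
       grad = list(conv_a = ba$grad, conv_g = bg$grad, proj = bp$grad))
}

#' Gated convolutional block (with residual)
#'
#' Computes `x + proj((x * W + b) * mish(x * V + c))` where `*` denotes causal
#' convolution at the bottleneck width; output never depends on future
#' timesteps.
#'
#' @param x L x d matrix or N x L x d array.
#' @param params From [glu_block_params()].
#'
#' @return Same shape as `x`.
#' @export
glu_block <- function(x, params) {
  was_mat <- is.matrix(x)
  xb <- as_batch3(x)
  if (dim(xb)[3] != dim(params$conv_a$W)[2]) {
    shape_error("input width %d does not match block width %d",
                dim(xb)[3], dim(params$conv_a$W)[2])
  }
  y <- xb + glu_core_fwd(xb, params)$y
  if (was_mat) y[1, , ] else y
}

## ---- branched convolution block ----

#' Parameters for the branched convolution block
#'
#' Two parallel causal branches (a pointwise kernel-1 branch at the merge
#' width and a kernel-3 branch at a quarter of it, channel-padded before the
#' merge), each through Mish and summed, followed by a kernel-9 depthwise
#' separable causal convolution projecting back to width d. The narrow-branch
#' and merge widths are the budget-pinning choices documented in the methods
#' vignette.
#'
#' @param d Model width (also the merge width).
#' @param branch_kernel Kernel size of the narrow causal branch.
#' @param sep_kernel Kernel size of the depthwise separable merge.
#' @param narrow_width Width of the kernel-3 branch
#'   (default `max(1, round(d/4))`).
#' @param seed Integer seed for initialization.
#'
#' @return Parameter list with fields `branch1`, `branch2`, `dw`, `pw`.
#' @export
branched_block_params <- function(d, branch_kernel = 3, sep_kernel = 9,
                                  narrow_width = NULL, seed = 1L) {
  b2 <- narrow_width %||% max(1L, round(d / 4))
  if (b2 > d) config_error("narrow branch width must not exceed model width")
  with_seed(seed, list(
    branch1 = init_linear(d, d),
    branch2 = init_conv(branch_kernel, d, b2),
    dw = init_depthwise(sep_kernel, d),
    pw = init_linear(d, d)
  ))
}

branched_core_fwd <- function(x, p) {
  b1 <- pw_fwd(x, p$branch1)
  m1 <- mish_fwd(b1$y)
  b2 <- conv_fwd(x, p$branch2)
  m2 <- mish_fwd(b2$y)
  s <- m1$y
  b2w <- dim(m2$y)[3]
  s[, , seq_len(b2w)] <- s[, , seq_len(b2w), drop = FALSE] + m2$y
  dwf <- dw_fwd(s, p$dw)
  out <- pw_fwd(dwf$y, p$pw)
  list(y = out$y,
       cache = list(b1 = b1, m1 = m1, b2 = b2, m2 = m2, dwf = dwf, out = out,
                    b2w = b2w))
}

branched_core_bwd <- function(dy, p, cache) {
  bo <- pw_bwd(dy, p$pw, cache$out$cache)
  bd <- dw_bwd(bo$dx, p$dw, cache$dwf$cache)
  ds <- bd$dx
  dm1 <- ds
  dm2 <- ds[, , seq_len(cache$b2w), drop = FALSE]
  db1y <- mish_bwd(dm1, cache$m1$cache)
  db2y <- mish_bwd(dm2, cache$m2$cache)
  bb1 <- pw_bwd(db1y, p$branch1, cache$b1$cache)
  bb2 <- conv_bwd(db2y, p$branch2, cache$b2$cache)
  list(dx = bb1$dx + bb2$dx,
       grad = list(branch1 = bb1$grad, branch2 = bb2$grad,
                   dw = bd$grad, pw = bo$grad))
}

#' Branched convolution block (with residual)
#'
#' @param x L x d matrix or N x L x d array.
#' @param params From [branched_block_params()].
#'
#' @return Same shape as `x`.
#' @export
branched_conv_block <- function(x, params) {
  was_mat <- is.matrix(x)
  xb <- as_batch3(x)
  y <- xb + branched_core_fwd(xb, params)$y
  if (was_mat) y[1, , ] else y
}

## ---- causal convolution, public single-tensor form ----

#' Causal convolution
#'
#' Convolves a sequence with a kernel after left-padding `k - 1` zeros, so the
#' output at position t depends only on inputs at positions `<= t` and the
#' output length equals the input length.
#'
#' @param x L x C matrix (or numeric vector, treated as L x 1).
#' @param kernel k x C x C' array, or a length-k numeric vector for the
#'   single-channel case.
#' @param bias Optional length-C' bias.
#'
#' @return L x C' matrix (or vector when C' = 1 and `x` was a vector).
#' @export
causal_conv <- function(x, kernel, bias = NULL) {
  was_vec <- is.null(dim(x))
  if (was_vec) x <- matrix(x, ncol = 1)
  if (is.null(dim(kernel))) kernel <- array(kernel, c(length(kernel), 1, 1))
  if (length(dim(kernel)) != 3 || dim(kernel)[2] != ncol(x)) {
    shape_error("kernel must be k x C x C' with C matching the input")
  }
  p <- list(W = kernel, b = bias %||% numeric(dim(kernel)[3]))
  y <- conv_fwd(array(x, c(1, nrow(x), ncol(x))), p)$y[1, , , drop = TRUE]
  if (was_vec && dim(kernel)[3] == 1) as.numeric(y) else matrix(y, nrow = nrow(x))
}

## ---- axial positional embedding ----

#' Parameters for a factorized (axial) positional embedding
#'
#' The length-(N+1) positional table is factorized into axis matrices
#' `A (r x d)` and `B (cols x d)` combined additively: position
#' `p = i*cols + j` receives `A[i] + B[j]`. Parameter count `(r + cols) * d`
#' is strictly sub-linear in sequence length for the near-square default
#' factorization.
#'
#' @param n_positions Number of positions to cover (sequence length + token).
#' @param d Embedding width.
#' @param r,cols Optional factorization; defaults to
#'   `r = ceiling(sqrt(n))`, `cols = ceiling(n / r)`.
#' @param seed Integer seed for initialization.
#'
#' @return Parameter list with fields `A`, `B` and attribute `cols`.
#' @export
axial_embedding_params <- function(n_positions, d, r = NULL, cols = NULL,
                                   seed = 1L) {
  r <- r %||% ceiling(sqrt(n_positions))
  cols <- cols %||% ceiling(n_positions / r)
  if (r * cols < n_positions) {
    config_error("factorization %d x %d cannot cover %d positions",
                 r, cols, n_positions)
  }
  p <- with_seed(seed, list(
    A = matrix(stats::rnorm(r * d, sd = 0.02), r, d),
    B = matrix(stats::rnorm(cols * d, sd = 0.02), cols, d)
  ))
  attr(p, "cols") <- as.integer(cols)
  p
}

#' Materialize an axial positional embedding table
#'
#' @param n_positions Number of rows to materialize.
#' @param params From [axial_embedding_params()].
#'
#' @return `n_positions` x d matrix; row `p + 1` equals
#'   `A[p %/% cols + 1, ] + B[p %% cols + 1, ]`.
#' @export
axial_positional_embedding <- function(n_positions, params) {
  cols <- attr(params, "cols")
  if (nrow(params$A) * cols < n_positions) {
    config_error("factorization too small for %d positions", n_positions)
  }
  p <- seq_len(n_positions) - 1L
  params$A[p %/% cols + 1L, , drop = FALSE] +
    params$B[p %% cols + 1L, , drop = FALSE]
}

## ---- class token ----

#' Prepend a learnable class token to a sequence
#'
#' The token (one timestep of embedding width) becomes row 0 of the sequence;
#' after the network body its state is the sole input to the classifier.
#'
#' @param x L x d matrix or N x L x d array.
#' @param token Length-d numeric vector (broadcast across a batch).
#'
#' @return (L+1) x d matrix or N x (L+1) x d array.
#' @export
prepend_class_token <- function(x, token) {
  was_mat <- is.matrix(x)
  xb <- as_batch3(x)
  if (length(token) != dim(xb)[3]) {
    shape_error("token width %d does not match sequence width %d",
                length(token), dim(xb)[3])
  }
  n <- dim(xb)[1]; l <- dim(xb)[2]; d <- dim(xb)[3]
  out <- array(0, dim = c(n, l + 1, d))
  out[, 1, ] <- matrix(rep(token, each = n), n, d)
  out[, 2:(l + 1), ] <- xb
  if (was_mat) out[1, , ] else out
}
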