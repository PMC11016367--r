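# Multi-head self-attention in two interchangeable flavours: scaled
# dot-product softmax attention and kernelized linear attention with the
# elu(x)+1 feature map. Both share an identical parameter layout (Q/K/V and
# output projections with biases), so swapping one for the other never
# changes the trainable-parameter count. Attention here is non-causal: the
# class token at position 0 must see every timestep.

#' Parameters for a multi-head attention block
#'
#' Projection matrices `W_Q`, `W_K`, `W_V` and the output projection `W_O`,
#' all d x d with biases, split across `heads` heads of width `d / heads`.
#'
#' @param d Model width; must be divisible by `heads`.
#' @param heads Number of attention heads.
#' @param seed Integer seed for initialization.
#'
#' @return Parameter list with fields `Wq`, `Wk`, `Wv`, `Wo` and attribute
#'   `heads`.
#' @export
attention_params <- function(d, heads = 1, seed = 1L) {
  if (d %% heads != 0) {
    config_error("model width %d is not divisible by %d heads", d, heads)
  }
  p <- with_seed(seed, list(
    Wq = init_linear(d, d),
    Wk = init_linear(d, d),
    Wv = init_linear(d, d),
    Wo = init_linear(d, d)
  ))
  attr(p, "heads") <- as.integer(heads)
  p
}

elu1 <- function(x) ifelse(x > 0, x + 1, exp(x))
elu1_grad <- function(x) ifelse(x > 0, 1, exp(x))

head_cols <- function(hh, dk) ((hh - 1) * dk + 1):(hh * dk)

## ---- softmax attention ----

sm_attn_fwd <- function(x, p, heads) {
  qf <- pw_fwd(x, p$Wq); kf <- pw_fwd(x, p$Wk); vf <- pw_fwd(x, p$Wv)
  n <- dim(x)[1]; l <- dim(x)[2]; d <- dim(x)[3]
  dk <- d %/% heads
  ctx <- array(0, dim = c(n, l, d))
  a_mats <- vector("list", n * heads)
  for (i in seq_len(n)) {
    for (hh in seq_len(heads)) {
      cols <- head_cols(hh, dk)
      q <- matrix(qf$y[i, , cols], l, dk)
      k <- matrix(kf$y[i, , cols], l, dk)
      v <- matrix(vf$y[i, , cols], l, dk)
      z <- q %*% t(k) / sqrt(dk)
      z <- z - apply(z, 1, max)
      a <- exp(z)
      a <- a / rowSums(a)
      ctx[i, , cols] <- a %*% v
      a_mats[[(i - 1) * heads + hh]] <- a
    }
  }
  of <- pw_fwd(ctx, p$Wo)
  list(y = of$y,
       cache = list(qf = qf, kf = kf, vf = vf, of = of, a_mats = a_mats,
                    heads = heads, dk = dk))
}

sm_attn_bwd <- function(dy, p, cache) {
  bo <- pw_bwd(dy, p$Wo, cache$of$cache)
  dctx <- bo$dx
  qy <- cache$qf$y; ky <- cache$kf$y; vy <- cache$vf$y
  n <- dim(dctx)[1]; l <- dim(dctx)[2]
  heads <- cache$heads; dk <- cache$dk
  dq <- array(0, dim = dim(qy)); dkk <- array(0, dim = dim(ky))
  dv <- array(0, dim = dim(vy))
  for (i in seq_len(n)) {
    for (hh in seq_len(heads)) {
      cols <- head_cols(hh, dk)
      a <- cache$a_mats[[(i - 1) * heads + hh]]
      q <- matrix(qy[i, , cols], l, dk)
      k <- matrix(ky[i, , cols], l, dk)
      v <- matrix(vy[i, , cols], l, dk)
      dc <- matrix(dctx[i, , cols], l, dk)
      da <- dc %*% t(v)
      dv[i, , cols] <- t(a) %*% dc
      dz <- a * (da - rowSums(da * a))
      dq[i, , cols] <- dz %*% k / sqrt(dk)
      dkk[i, , cols] <- t(dz) %*% q / sqrt(dk)
    }
  }
  bq <- pw_bwd(dq, p$Wq, cache$qf$cache)
  bk <- pw_bwd(dkk, p$Wk, cache$kf$cache)
  bv <- pw_bwd(dv, p$Wv, cache$vf$cache)
  list(dx = bq$dx + bk$dx + bv$dx,
       grad = list(Wq = bq$grad, Wk = bk$grad, Wv = bv$grad, Wo = bo$grad))
}

#' Softmax multi-head self-attention
#'
#' Per head computes `softmax(Q K' / sqrt(d_k)) V` over the full sequence
#' (bidirectional), concatenates heads and applies the output projection.
#'
#' @param x L x d matrix or N x L x d array.
#' @param params From [attention_params()].
#'
#' @return Same shape as `x`.
#' @export
softmax_attention <- function(x, params) {
  was_mat <- is.matrix(x)
  xb <- as_batch3(x)
  if (dim(xb)[3] != nrow(params$Wq$W)) {
    shape_error("input width %d does not match attention width %d",
                dim(xb)[3], nrow(params$Wq$W))
  }
  y <- sm_attn_fwd(xb, params, attr(params, "heads"))$y
  if (was_mat) y[1, , ] else y
}

#' Attention score matrix (diagnostic)
#'
#' Returns the row-stochastic softmax attention matrix for one head: entry
#' (i, j) is the weight position i places on position j.
#'
#' @param x L x d matrix (a single sequence).
#' @param params From [attention_params()].
#' @param head Head index to inspect.
#'
#' @return L x L matrix with non-negative rows summing to 1.
#' @export
attention_matrix <- function(x, params, head = 1) {
  stopifnot(is.matrix(x))
  heads <- attr(params, "heads")
  if (head < 1 || head > heads) config_error("head must lie in 1..%d", heads)
  d <- ncol(x)
  dk <- d %/% heads
  q <- sweep(x %*% params$Wq$W, 2, params$Wq$b, `+`)
  k <- sweep(x %*% params$Wk$W, 2, params$Wk$b, `+`)
  cols <- head_cols(head, dk)
  z <- q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) / sqrt(dk)
  z <- z - apply(z, 1, max)
  a <- exp(z)
  a / rowSums(a)
}

## ---- linear attention ----

lin_attn_fwd <- function(x, p, heads, eps = 1e-6) {
  qf <- pw_fwd(x, p$Wq); kf <- pw_fwd(x, p$Wk); vf <- pw_fwd(x, p$Wv)
  n <- dim(x)[1]; l <- dim(x)[2]; d <- dim(x)[3]
  dk <- d %/% heads
  ctx <- array(0, dim = c(n, l, d))
  hc <- vector("list", n * heads)
  for (i in seq_len(n)) {
    for (hh in seq_len(heads)) {
      cols <- head_cols(hh, dk)
      q <- matrix(qf$y[i, , cols], l, dk)
      k <- matrix(kf$y[i, , cols], l, dk)
      v <- matrix(vf$y[i, , cols], l, dk)
      fq <- elu1(q); fk <- elu1(k)
      s <- t(fk) %*% v          # summed key-value statistics, d_k x d_k
      zv <- colSums(fk)         # summed keys, length d_k
      den <- as.numeric(fq %*% zv) + eps
      num <- fq %*% s
      ctx[i, , cols] <- num / den
      hc[[(i - 1) * heads + hh]] <-
        list(q = q, k = k, v = v, fq = fq, fk = fk, s = s, zv = zv,
             den = den, num = num)
    }
  }
  of <- pw_fwd(ctx, p$Wo)
  list(y = of$y,
       cache = list(qf = qf, kf = kf, vf = vf, of = of, hc = hc,
                    heads = heads, dk = dk))
}

lin_attn_bwd <- function(dy, p, cache) {
  bo <- pw_bwd(dy, p$Wo, cache$of$cache)
  dctx <- bo$dx
  n <- dim(dctx)[1]; l <- dim(dctx)[2]
  heads <- cache$heads; dk <- cache$dk
  dq <- array(0, dim = dim(dctx)); dkk <- array(0, dim = dim(dctx))
  dv <- array(0, dim = dim(dctx))
  for (i in seq_len(n)) {
    for (hh in seq_len(heads)) {
      cols <- head_cols(hh, dk)
      cc <- cache$hc[[(i - 1) * heads + hh]]
      doo <- matrix(dctx[i, , cols], l, dk)
      dnum <- doo / cc$den
      dden <- -rowSums(doo * cc$num) / cc$den^2
      dfq <- dnum %*% t(cc$s) + outer(dden, cc$zv)
      ds <- t(cc$fq) %*% dnum
      dzv <- as.numeric(t(cc$fq) %*% dden)
      dfk <- cc$v %*% t(ds) + matrix(dzv, l, dk, byrow = TRUE)
      dv[i, , cols] <- cc$fk %*% ds
      dq[i, , cols] <- dfq * elu1_grad(cc$q)
      dkk[i, , cols] <- dfk * elu1_grad(cc$k)
    }
  }
  bq <- pw_bwd(dq, p$Wq, cache$qf$cache)
  bk <- pw_bwd(dkk, p$Wk, cache$kf$cache)
  bv <- pw_bwd(dv, p$Wv, cache$vf$cache)
  list(dx = bq$dx + bk$dx + bv$dx,
       grad = list(Wq = bq$grad, Wk = bk$grad, Wv = bv$grad, Wo = bo$grad))
}

#' Kernelized linear self-attention
#'
#' Per head computes
#' `out_i = phi(q_i)' (sum_j phi(k_j) v_j') / (phi(q_i)' sum_j phi(k_j))`
#' with the feature map `phi(x) = elu(x) + 1 > 0`, using the summed key-value
#' statistics so cost is linear in sequence length. Output matches the
#' generalized-attention form with similarity `phi(q)'phi(k)`.
#'
#' @param x L x d matrix or N x L x d array.
#' @param params From [attention_params()].
#' @param epsilon Denominator stabilizer.
#'
#' @return Same shape as `x`.
#' @export
linear_attention <- function(x, params, epsilon = 1e-6) {
  was_mat <- is.matrix(x)
  xb <- as_batch3(x)
  if (dim(xb)[3] != nrow(params$Wq$W)) {
    shape_error("input width %d does not match attention width %d",
                dim(xb)[3], nrow(params$Wq$W))
  }
  y <- lin_attn_fwd(xb, params, attr(params, "heads"), eps = epsilon)$y
  if (was_mat) y[1, , ] else y
}

## ---- analytic operation counts ----

#' Analytic multiply-accumulate counts for attention mechanisms
#'
#' Counts scalar multiplications of the naive algorithm for one sequence:
#' the four d x d projections (`4 N d^2`), plus per head the attention core.
#' For softmax attention the core is `N^2 d_k` score products, `N^2` scalings
#' and `N^2 d_k` score-value products (quadratic in N); for linear attention
#' it is `N d_k^2` for the key-value statistics, `N d_k^2` for the queries
#' against them and `N d_k` for the normalizer (linear in N).
#'
#' @param mechanism `"softmax_attention"` or `"linear_attention"`.
#' @param n Sequence length (including the class token).
#' @param d Model width.
#' @param heads Number of heads.
#'
#' @return Exact count as a numeric scalar.
#' @export
op_count <- function(mechanism = c("softmax_attention", "linear_attention"),
                     n, d, heads = 1) {
  mechanism <- match.arg(mechanism)
  if (d %% heads != 0) config_error("d must be divisible by heads")
  dk <- d / heads
  proj <- 4 * n * d^2
  core <- switch(mechanism,
    softmax_attention = heads * (2 * n^2 * dk + n^2),
    linear_attention = heads * (2 * n * dk^2 + n * dk)
  )
  proj + core
}
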