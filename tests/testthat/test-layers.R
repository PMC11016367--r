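test_that("mish matches its scalar formula and asymptotics", {
  expect_identical(mish(0), 0)
  expect_equal(mish(20), 20, tolerance = 1e-6)
  # direct high-precision evaluation of x * tanh(ln(1 + e^x))
  expect_equal(mish(1), 1 * tanh(log(1 + exp(1))), tolerance = 1e-12)
  xs <- seq(-5, 5, by = 0.25)
  expect_equal(mish(xs), xs * tanh(log1p(exp(xs))), tolerance = 1e-12)
  # shape-preserving
  m <- matrix(rnorm(12), 3, 4)
  expect_equal(dim(mish(m)), c(3, 4))
})

test_that("causal convolution is exact and never looks forward", {
  expect_equal(causal_conv(c(1, 2, 3), 2), c(2, 4, 6))
  expect_equal(causal_conv(c(1, 2, 3, 4), c(1, 1)), c(1, 3, 5, 7))
  # causality: perturbing position t0 leaves outputs before t0 unchanged
  set.seed(1)
  x <- matrix(rnorm(20 * 2), 20, 2)
  kern <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  y0 <- causal_conv(x, kern)
  x2 <- x
  x2[12, ] <- x2[12, ] + 5
  y1 <- causal_conv(x2, kern)
  expect_equal(y0[1:11, ], y1[1:11, ])
  expect_false(isTRUE(all.equal(y0[12, ], y1[12, ])))
})

test_that("glu block gates, adds the residual, and matches a loop oracle", {
  set.seed(2)
  d <- 6
  p <- glu_block_params(d, kernel_size = 3, bottleneck = 3, seed = 4)
  x <- matrix(rnorm(10 * d), 10, d)
  # zero gate branch (weights and bias) makes the whole core vanish
  p0 <- p
  p0$conv_g$W[] <- 0
  p0$conv_g$b[] <- 0
  expect_equal(glu_block(x, p0), x, tolerance = 1e-12)
  # loop-based evaluation of conv/gate/project plus residual
  k <- 3
  b <- 3
  loop_out <- x
  for (t in 1:10) {
    a_t <- g_t <- numeric(b)
    for (tau in 0:(k - 1)) {
      if (t - tau >= 1) {
        a_t <- a_t + as.numeric(x[t - tau, ] %*% p$conv_a$W[tau + 1, , ])
        g_t <- g_t + as.numeric(x[t - tau, ] %*% p$conv_g$W[tau + 1, , ])
      }
    }
    a_t <- a_t + p$conv_a$b
    g_t <- g_t + p$conv_g$b
    core <- (a_t * mish(g_t)) %*% p$proj$W + p$proj$b
    loop_out[t, ] <- x[t, ] + core
  }
  expect_equal(glu_block(x, p), loop_out, tolerance = 1e-6)
  # causality through the block
  x2 <- x
  x2[8, ] <- x2[8, ] + 1
  expect_equal(glu_block(x, p)[1:7, ], glu_block(x2, p)[1:7, ])
  expect_error(glu_block(matrix(0, 5, 4), p), class = "glula_shape_error")
})

test_that("branched block is shape-preserving, residual at zero weights, causal", {
  set.seed(3)
  d <- 8
  p <- branched_block_params(d, seed = 5)
  x <- matrix(rnorm(20 * d), 20, d)
  expect_equal(dim(branched_conv_block(x, p)), c(20, d))
  p0 <- rapply(p, function(w) w * 0, how = "replace")
  expect_equal(branched_conv_block(x, p0), x)
  x2 <- x
  x2[15, ] <- x2[15, ] - 2
  expect_equal(branched_conv_block(x, p)[1:14, ],
               branched_conv_block(x2, p)[1:14, ])
})

test_that("depthwise separable stage equals explicit depthwise-then-pointwise", {
  set.seed(4)
  d <- 5
  l <- 16
  x <- array(rnorm(l * d), c(1, l, d))
  dw <- glula:::init_depthwise(9, d)
  pw <- glula:::init_linear(d, d)
  got <- glula:::pw_fwd(glula:::dw_fwd(x, dw)$y, pw)$y[1, , ]
  # explicit composition: per-channel causal filter, then per-timestep dense
  inter <- matrix(0, l, d)
  for (ch in seq_len(d)) {
    for (t in seq_len(l)) {
      acc <- dw$b[ch]
      for (tau in 0:8) {
        if (t - tau >= 1) acc <- acc + dw$W[tau + 1, ch] * x[1, t - tau, ch]
      }
      inter[t, ch] <- acc
    }
  }
  manual <- sweep(inter %*% pw$W, 2, pw$b, `+`)
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("axial positional embedding indexes and materializes correctly", {
  p <- axial_embedding_params(6, d = 4, r = 2, cols = 3, seed = 9)
  tab <- axial_positional_embedding(6, p)
  # position 4 (0-based) = i*cols + j with i = 1, j = 1
  expect_equal(tab[5, ], p$A[2, ] + p$B[2, ])
  # full outer-sum construction
  manual <- matrix(0, 6, 4)
  for (pos in 0:5) {
    manual[pos + 1, ] <- p$A[pos %/% 3 + 1, ] + p$B[pos %% 3 + 1, ]
  }
  expect_equal(tab, manual)
  # parameter count strictly sub-linear for long windows
  p2 <- axial_embedding_params(501, d = 64, seed = 1)
  expect_lt(length(p2$A) + length(p2$B), 501 * 64)
  expect_error(axial_positional_embedding(10, p),
               class = "glula_config_error")
})

test_that("class token becomes row 0 and the rest is untouched", {
  set.seed(6)
  x <- matrix(rnorm(5 * 4), 5, 4)
  token <- rnorm(4)
  out <- prepend_class_token(x, token)
  expect_equal(dim(out), c(6, 4))
  expect_equal(out[1, ], token)
  expect_identical(out[2:6, ], x)
  # batch broadcast
  xb <- array(rnorm(3 * 5 * 4), c(3, 5, 4))
  outb <- prepend_class_token(xb, token)
  expect_equal(dim(outb), c(3, 6, 4))
  for (i in 1:3) expect_equal(outb[i, 1, ], token)
  expect_error(prepend_class_token(x, rnorm(3)), class = "glula_shape_error")
})

test_that("layer norm standardizes positions and matches a two-pass reference", {
  set.seed(7)
  x <- matrix(rnorm(10 * 8, mean = 3, sd = 2), 10, 8)
  y <- layer_norm(x)
  expect_equal(rowMeans(y), rep(0, 10), tolerance = 1e-10)
  expect_equal(apply(y, 1, function(r) mean(r^2)), rep(1, 10),
               tolerance = 1e-4)
  # invariance to adding a constant to all features of a position
  expect_equal(layer_norm(x + 5), y, tolerance = 1e-8)
  # two-pass mean/variance reference
  ref <- t(apply(x, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(y, ref, tolerance = 1e-12)
})
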