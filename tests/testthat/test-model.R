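test_that("embedding dimension rule: next power of two, optional doubling, floor 8", {
  expect_equal(embedding_dim_for(9, 1), 16L)
  expect_equal(embedding_dim_for(6, 2), 16L)
  expect_equal(embedding_dim_for(52, 1), 64L)
  expect_equal(embedding_dim_for(2, 1), 8L)
  expect_equal(embedding_dim_for(113, 1), 128L)
})

test_that("model initialization is deterministic and variant-shape-stable", {
  cfg <- tiny_model_config(seed = 31)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(glula:::tree_flatten(m1$params),
                   glula:::tree_flatten(m2$params))
  # swapping softmax <-> linear changes no parameter shapes
  shapes <- function(block) {
    rapply(build_model(tiny_model_config(block))$params,
           function(x) paste(dim(x) %||% length(x), collapse = "x"),
           how = "unlist")
  }
  expect_identical(shapes("softmax_attention"), shapes("linear_attention"))
})

test_that("reference configurations satisfy the printed parameter budgets", {
  uschad <- build_model(preset_model_config("uschad"))
  expect_lte(count_parameters(uschad), 4000L)
  pamap2 <- build_model(preset_model_config("pamap2"))
  expect_lte(count_parameters(pamap2), 50000L)
  # per-block breakdown sums to the total
  expect_equal(sum(count_parameters(uschad, "per_block")),
               count_parameters(uschad))
  # a standalone d -> d dense layer with bias at d = 16
  fc <- glula:::init_linear(16, 16)
  expect_equal(length(fc$W) + length(fc$b), 272L)
})

test_that("swapping attention flavour preserves the total parameter count", {
  for (preset in c("pamap2", "skoda", "opportunity", "uschad", "daphnet")) {
    n_la <- count_parameters(build_model(preset_model_config(preset, "linear_attention")))
    n_sa <- count_parameters(build_model(preset_model_config(preset, "softmax_attention")))
    expect_identical(n_la, n_sa)
  }
})

test_that("forward passes are batch-independent and numerically stable", {
  set.seed(41)
  model <- build_model(tiny_model_config())
  x <- array(rnorm(4 * 8 * 3), c(4, 8, 3))
  full <- model_forward(model, x)
  single <- model_forward(model, x[2, , ])
  expect_equal(as.numeric(full[2, ]), as.numeric(single), tolerance = 1e-6)
  big <- model_forward(model, x * 100)
  expect_true(all(is.finite(big)))
  expect_error(model_forward(model, array(0, c(2, 8, 5))),
               class = "glula_shape_error")
})

test_that("global receptive field comes from attention, not the causal convs", {
  set.seed(42)
  model <- build_model(tiny_model_config("linear_attention", seed = 43))
  x <- array(rnorm(1 * 8 * 3), c(1, 8, 3))
  x2 <- x
  x2[1, 8, ] <- x2[1, 8, ] + 3 # last timestep
  expect_false(isTRUE(all.equal(model_forward(model, x),
                                model_forward(model, x2))))
  # with zeroed value projections nothing can reach the class token
  blind <- model
  blind$params$additional$Wv$W[] <- 0
  blind$params$additional$Wv$b[] <- 0
  expect_equal(model_forward(blind, x), model_forward(blind, x2),
               tolerance = 1e-12)
})

test_that("window length changes only the axial positional parameters", {
  base <- count_parameters(build_model(model_config(6, 100, 12,
                                                    embedding_multiplier = 2)),
                           "per_block")
  wide <- count_parameters(build_model(model_config(6, 400, 12,
                                                    embedding_multiplier = 2)),
                           "per_block")
  diff <- wide - base
  expect_true(all(diff[setdiff(names(diff), "positional")] == 0))
  expect_gt(diff[["positional"]], 0)
})

test_that("classification reads only the token position", {
  set.seed(44)
  model <- build_model(tiny_model_config())
  x <- array(rnorm(3 * 8 * 3), c(3, 8, 3))
  logits <- model_forward(model, x, return_sequence = TRUE)
  h3 <- attr(logits, "sequence")
  h3_zeroed <- h3
  h3_zeroed[, 2:dim(h3)[2], ] <- 0
  expect_equal(glula:::head_from_sequence(model, h3_zeroed),
               unclass(logits), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("backpropagation matches finite differences for every variant (with mixup)", {
  set.seed(45)
  for (blk in c("linear_attention", "softmax_attention", "glu")) {
    cfg <- tiny_model_config(blk, seed = 50)
    model <- build_model(cfg)
    p <- model$params
    x <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
    y <- one_hot(c(0L, 2L), 3)
    mix <- list(lambda = 0.35, perm = c(2L, 1L), layer = "input_embedding")
    ym <- 0.35 * y + 0.65 * y[c(2, 1), ]
    loss_at <- function(v) {
      pp <- glula:::tree_unflatten(p, v)
      fp <- glula:::forward_pass(pp, cfg, x, mix = mix)
      glula:::cross_entropy(fp$logits, ym)$loss
    }
    v <- glula:::tree_flatten(p)
    fp <- glula:::forward_pass(p, cfg, x, mix = mix, want_cache = TRUE)
    ce <- glula:::cross_entropy(fp$logits, ym)
    g <- glula:::tree_flatten(glula:::backward_pass(p, cfg, fp$cache,
                                                    ce$dlogits))
    idx <- sort(sample(length(v), 80))
    h <- 1e-5
    num <- vapply(idx, function(i) {
      vp <- v; vp[i] <- v[i] + h
      vm <- v; vm[i] <- v[i] - h
      (loss_at(vp) - loss_at(vm)) / (2 * h)
    }, numeric(1))
    rel <- abs(num - g[idx]) / pmax(1e-6, abs(num) + abs(g[idx]))
    expect_lt(max(rel), 1e-4)
  }
})
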