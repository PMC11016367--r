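test_that("mixup degenerates exactly at lambda 1 and 0, at every eligible layer", {
  set.seed(51)
  model <- build_model(tiny_model_config())
  x <- array(rnorm(4 * 8 * 3), c(4, 8, 3))
  y <- one_hot(c(0L, 1L, 2L, 1L), 3)
  perm <- c(3L, 4L, 1L, 2L)
  plain <- model_forward(model, x)
  for (layer in c("input_embedding", "after_main_block")) {
    m1 <- mixup_forward(model, x, y, perm, lambda = 1, layer = layer)
    expect_equal(m1$logits, plain, tolerance = 1e-12)
    expect_equal(m1$mixed_labels, y)
    m0 <- mixup_forward(model, x, y, perm, lambda = 0, layer = layer)
    expect_equal(m0$logits, plain[perm, ], tolerance = 1e-12)
    expect_equal(m0$mixed_labels, y[perm, ])
  }
  expect_error(mixup_forward(model, x, y, perm, 0.5, "after_attention"),
               class = "glula_config_error")
})

test_that("input-layer mixup equals mixing the inputs (embedding is affine)", {
  set.seed(52)
  model <- build_model(tiny_model_config())
  x <- array(rnorm(4 * 8 * 3), c(4, 8, 3))
  y <- one_hot(c(0L, 1L, 2L, 1L), 3)
  perm <- c(2L, 1L, 4L, 3L)
  lam <- 0.3
  mixed <- mixup_forward(model, x, y, perm, lam, "input_embedding")
  x_mixed <- lam * x + (1 - lam) * x[perm, , , drop = FALSE]
  expect_equal(mixed$logits, model_forward(model, x_mixed), tolerance = 1e-6)
  # swapping (batch, partner, lambda) with (partner, batch, 1 - lambda)
  # produces the same mixed batch, hence the same loss
  swapped <- mixup_forward(model, x[perm, , , drop = FALSE], y[perm, ],
                           order(perm), 1 - lam, "input_embedding")
  ce1 <- glula:::cross_entropy(mixed$logits, mixed$mixed_labels)
  ce2 <- glula:::cross_entropy(swapped$logits, swapped$mixed_labels)
  expect_equal(ce1$loss, ce2$loss, tolerance = 1e-10)
})

test_that("mixup draws have the right distribution and labels stay stochastic", {
  cfg <- mixup_config(alpha = 1)
  set.seed(53)
  draws <- replicate(10000, sample_mixup(cfg)$lambda)
  expect_lt(abs(mean(draws) - 0.5), 0.02) # Beta(1,1) is uniform
  layers <- replicate(10000, sample_mixup(cfg)$layer)
  freqs <- table(layers) / 10000
  expect_true(all(abs(freqs - 0.5) < 0.03))
  y <- one_hot(sample(0:2, 50, replace = TRUE), 3)
  perm <- sample(50)
  lam <- 0.37
  mixed <- lam * y + (1 - lam) * y[perm, ]
  expect_equal(rowSums(mixed), rep(1, 50))
  expect_error(mixup_config(alpha = 0), class = "glula_config_error")
})

test_that("one-cycle schedule peaks once, anneals to near zero, stays monotone", {
  plan <- train_plan(max_lr = 1e-3, pct_start = 0.3, div = 25, final_div = 1e4)
  total <- 1000
  lrs <- one_cycle_lr(0:total, total, plan)
  expect_equal(lrs[300 + 1], 1e-3) # peak at pct_start * total
  expect_equal(lrs[total + 1], 1e-7) # max_lr / final_div
  expect_equal(lrs[1], 4e-5) # max_lr / div
  expect_true(all(diff(lrs[1:301]) > 0))
  expect_true(all(diff(lrs[301:1001]) < 0))
  expect_equal(sum(lrs == max(lrs)), 1)
  expect_lt(sum(lrs[-1]), plan$max_lr * total)
  expect_error(one_cycle_lr(-1, total, plan), class = "glula_config_error")
})

test_that("training is deterministic given the seed", {
  set.seed(54)
  windows <- array(rnorm(30 * 8 * 3), c(30, 8, 3))
  wb <- window_batch(windows, sample(0:2, 30, replace = TRUE),
                     rep("S01", 30), 8, 4)
  plan <- train_plan(epochs = 2, batch_size = 8)
  model <- build_model(tiny_model_config())
  r1 <- train(model, wb, plan, mixup_config(), seed = 5)
  r2 <- train(model, wb, plan, mixup_config(), seed = 5)
  expect_identical(r1$losses, r2$losses)
  expect_identical(glula:::tree_flatten(r1$model$params),
                   glula:::tree_flatten(r2$model$params))
  # loss trace length = epochs * steps_per_epoch
  expect_length(r1$losses, 2 * ceiling(30 / 8))
  r3 <- train(model, wb, plan, mixup_config(), seed = 6)
  expect_false(identical(r1$losses, r3$losses))
})

test_that("training halves the loss on separable synthetic data", {
  cfg <- small_generator_config(seed = 61)
  recs <- generate_dataset(cfg)
  splits <- prepare_fold(loso_folds(recs)[[5]], 64)
  model <- build_model(model_config(6, 64, 4, embedding_multiplier = 2,
                                    seed = 62))
  # mixup off: soft mixed labels put an entropy floor under the loss, so the
  # halving check is about the plain-label objective
  fit <- train(model, splits$train, train_plan(epochs = 10), mixup = NULL,
               seed = 1)
  first <- fit$epoch_losses[1]
  last <- fit$epoch_losses[length(fit$epoch_losses)]
  expect_lt(last, 0.5 * first)
})

test_that("a tiny network memorizes a 2-sample set without mixup", {
  set.seed(55)
  w <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
  w[1, , ] <- w[1, , ] + 2
  wb <- window_batch(w, c(0L, 1L), c("a", "a"), 8, 4)
  cfg <- model_config(3, 8, 2, heads = 1, seed = 71)
  model <- build_model(cfg)
  plan <- train_plan(epochs = 200, batch_size = 2, balancing = FALSE)
  fit <- train(model, wb, plan, mixup = NULL, seed = 2)
  preds <- predict(fit$model, wb)
  expect_equal(preds, c(0L, 1L))
})

test_that("the multi-seed protocol reports per-seed rows and exact aggregates", {
  cfg <- small_generator_config(seed = 81)
  recs <- generate_dataset(cfg)
  splits <- prepare_fold(loso_folds(recs)[[5]], 64)
  build_fn <- function(seed) {
    build_model(model_config(6, 64, 4, embedding_multiplier = 2, seed = seed))
  }
  plan <- train_plan(epochs = 2, n_seeds = 2)
  res <- run_protocol(build_fn, splits, plan, mixup_config())
  expect_equal(nrow(res$per_seed), 2)
  expect_equal(res$summary$mean_weighted_f1, mean(res$per_seed$weighted_f1))
  expect_equal(res$summary$sd_weighted_f1, sd(res$per_seed$weighted_f1))
  expect_true(all(res$per_seed$weighted_f1 >= 0 &
                    res$per_seed$weighted_f1 <= 1))
})

test_that("mixup does not degrade macro F1 on the imbalanced synthetic set", {
  cfg <- small_generator_config(seed = 91)
  recs <- generate_dataset(cfg)
  splits <- prepare_fold(loso_folds(recs)[[5]], 64)
  build_fn <- function(seed) {
    build_model(model_config(6, 64, 4, embedding_multiplier = 2, seed = seed))
  }
  plan <- train_plan(epochs = 20, n_seeds = 3)
  with_mix <- run_protocol(build_fn, splits, plan, mixup_config())
  without <- run_protocol(build_fn, splits, plan, mixup = NULL)
  expect_gte(with_mix$summary$mean_macro_f1,
             without$summary$mean_macro_f1 - 0.05)
})
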