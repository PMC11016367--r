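# Training: manifold mixup, the one-cycle learning-rate policy, soft-label
# cross-entropy, an AdaBelief optimizer and the seeded training loop with
# optional inverse-frequency balanced sampling.

#' Manifold mixup configuration
#'
#' Mixup draws a mixing weight `lambda ~ Beta(alpha, alpha)` and a hook layer
#' uniformly from `eligible_layers`, then convexly combines the batch's
#' hidden representations (and one-hot labels) with a re-shuffled partner
#' batch at that layer. Layers after the attention block are not eligible:
#' mixing there would blend the class token across samples.
#'
#' @param alpha Beta-distribution concentration (> 0).
#' @param eligible_layers Subset of `"input_embedding"`,
#'   `"after_main_block"`.
#' @param enabled Logical flag.
#'
#' @return An object of class `mixup_config`.
#' @export
mixup_config <- function(alpha = 2,
                         eligible_layers = c("input_embedding",
                                             "after_main_block"),
                         enabled = TRUE) {
  if (alpha <= 0) config_error("alpha must be positive")
  eligible_layers <- match.arg(eligible_layers, several.ok = TRUE)
  if (enabled && length(eligible_layers) == 0) {
    config_error("eligible_layers must be non-empty when mixup is enabled")
  }
  structure(list(alpha = alpha, eligible_layers = eligible_layers,
                 enabled = enabled),
            class = "mixup_config")
}

#' Draw a mixup weight and hook layer
#'
#' Uses the current RNG state (seed externally for reproducibility).
#'
#' @param config A [mixup_config()].
#'
#' @return List with `lambda` (in `[0, 1]`) and `layer`.
#' @export
sample_mixup <- function(config) {
  stopifnot(inherits(config, "mixup_config"))
  if (!config$enabled) config_error("mixup is disabled in this config")
  list(lambda = stats::rbeta(1, config$alpha, config$alpha),
       layer = config$eligible_layers[
         sample.int(length(config$eligible_layers), 1)])
}

#' One-hot encode integer labels
#'
#' @param labels Integer vector of 0-based labels.
#' @param n_classes Number of classes.
#'
#' @return N x n_classes matrix of 0/1 rows.
#' @export
one_hot <- function(labels, n_classes) {
  if (any(labels < 0 | labels >= n_classes)) {
    data_error("labels must lie in [0, %d)", n_classes)
  }
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

#' Mixup forward pass
#'
#' Runs the model forward with hidden representations mixed at layer `layer`:
#' `h~ = lambda*h + (1-lambda)*h[perm]`, and returns logits together with the
#' correspondingly mixed soft labels `y~ = lambda*y + (1-lambda)*y[perm]`.
#' Gradients (in training) flow through the whole mixed graph.
#'
#' @param model A `glula_model`.
#' @param batch_x N x W x C array.
#' @param batch_y N x n_classes one-hot (or soft) label matrix.
#' @param perm Partner permutation of `1:N`.
#' @param lambda Mixing weight in `[0, 1]`.
#' @param layer Hook layer; must be in the eligible set.
#' @param mixup A [mixup_config()] defining the eligible set.
#'
#' @return List with `logits` and `mixed_labels`.
#' @export
mixup_forward <- function(model, batch_x, batch_y, perm, lambda, layer,
                          mixup = mixup_config()) {
  if (!layer %in% mixup$eligible_layers) {
    config_error("layer '%s' is not in the eligible set (%s)", layer,
                 paste(mixup$eligible_layers, collapse = ", "))
  }
  if (lambda < 0 || lambda > 1) config_error("lambda must lie in [0, 1]")
  mix <- list(lambda = lambda, perm = perm, layer = layer)
  fp <- forward_pass(model$params, model$config, batch_input(model, batch_x),
                     mix = mix)
  list(logits = fp$logits,
       mixed_labels = lambda * batch_y +
         (1 - lambda) * batch_y[perm, , drop = FALSE])
}

#' Training plan
#'
#' Batch size 64, five seeds and an adaptive (AdaBelief) optimizer are the
#' reference protocol; one-cycle shape parameters and optimizer
#' hyperparameters are exposed here.
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (>= 2 when mixup is enabled).
#' @param max_lr Peak learning rate of the one-cycle schedule.
#' @param pct_start Fraction of steps spent ramping up.
#' @param div Initial learning rate = `max_lr / div`.
#' @param final_div Final learning rate = `max_lr / final_div`.
#' @param beta1,beta2,eps AdaBelief moment decays and stabilizer.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param n_seeds Number of seeds for [run_protocol()].
#' @param balancing Use inverse-frequency balanced batch sampling.
#'
#' @return An object of class `train_plan`.
#' @export
train_plan <- function(epochs = 30, batch_size = 64, max_lr = 1e-3,
                       pct_start = 0.3, div = 25, final_div = 1e4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-16,
                       weight_decay = 0, n_seeds = 5, balancing = TRUE) {
  if (!is_count(epochs)) config_error("epochs must be >= 1")
  if (!is_count(batch_size, min = 1)) config_error("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), max_lr = max_lr,
                 pct_start = pct_start, div = div, final_div = final_div,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, n_seeds = as.integer(n_seeds),
                 balancing = isTRUE(balancing)),
            class = "train_plan")
}

#' One-cycle learning rate
#'
#' Cosine ramp from `max_lr/div` to `max_lr` over the first
#' `pct_start * total_steps` steps, then cosine anneal to
#' `max_lr/final_div`; piecewise strictly monotone with a single maximum.
#'
#' @param step Current step in `[0, total_steps]`.
#' @param total_steps Total steps of the run.
#' @param plan A [train_plan()].
#'
#' @return Learning rate at `step`.
#' @export
one_cycle_lr <- function(step, total_steps, plan) {
  if (any(step < 0 | step > total_steps)) {
    config_error("step must lie in [0, total_steps]")
  }
  peak <- plan$pct_start * total_steps
  lr0 <- plan$max_lr / plan$div
  lr_end <- plan$max_lr / plan$final_div
  ifelse(step <= peak,
         lr0 + (plan$max_lr - lr0) * (1 - cos(pi * step / peak)) / 2,
         lr_end + (plan$max_lr - lr_end) *
           (1 + cos(pi * (step - peak) / (total_steps - peak))) / 2)
}

# Mean soft-label cross-entropy and its logit gradient.
cross_entropy <- function(logits, y) {
  m <- apply(logits, 1, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  loss <- -mean(rowSums(y * logp))
  probs <- exp(logp)
  list(loss = loss, dlogits = (probs - y) / nrow(logits))
}

# One AdaBelief update. The second moment tracks the variance of the
# gradient around its EMA ("belief" in the gradient direction).
adabelief_step <- function(params, grads, state, lr, plan, t) {
  b1 <- plan$beta1; b2 <- plan$beta2; eps <- plan$eps
  state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$s <- tree_map(function(s, g, m) b2 * s + (1 - b2) * (g - m)^2 + eps,
                      state$s, grads, state$m)
  bc1 <- 1 - b1^t
  bc2 <- 1 - b2^t
  params <- tree_map(function(p, m, s) {
    upd <- (m / bc1) / (sqrt(s / bc2) + eps)
    p - lr * (upd + plan$weight_decay * p)
  }, params, state$m, state$s)
  list(params = params, state = state)
}

#' Train a model
#'
#' Seeded loop: per step, a minibatch is drawn (inverse-frequency weighted
#' when `plan$balancing`), mixup is applied when configured, the loss is
#' soft-label cross-entropy, and parameters are updated by AdaBelief under
#' the one-cycle schedule. Deterministic given `seed`.
#'
#' @param model A `glula_model`.
#' @param windows A [window_batch()] of normalized NaN-free training windows.
#' @param plan A [train_plan()].
#' @param mixup A [mixup_config()] or `NULL` to disable mixup.
#' @param seed Integer seed for batch sampling and mixup draws.
#'
#' @return An object of class `train_result`: fields `model`, `losses` (one
#'   per step), `epoch_losses`, `lr_trace`, `seed`, `wall_time_s`.
#' @export
train <- function(model, windows, plan = train_plan(), mixup = mixup_config(),
                  seed = 1L) {
  stopifnot(inherits(model, "glula_model"), inherits(windows, "window_batch"))
  n <- dim(windows$windows)[1]
  if (n < 1) data_error("training set is empty")
  use_mixup <- !is.null(mixup) && inherits(mixup, "mixup_config") &&
    mixup$enabled
  if (use_mixup && plan$batch_size < 2) {
    config_error("batch_size must be >= 2 when mixup is enabled")
  }
  y_all <- one_hot(windows$labels, model$config$n_classes)
  weights <- if (plan$balancing) class_balance_weights(windows$labels) else NULL
  steps_per_epoch <- max(1L, ceiling(n / plan$batch_size))
  total_steps <- plan$epochs * steps_per_epoch
  params <- model$params
  state <- list(m = tree_zeros_like(params), s = tree_zeros_like(params))
  losses <- numeric(total_steps)
  lr_trace <- numeric(total_steps)
  t0 <- proc.time()[["elapsed"]]
  with_seed(derive_seed(seed, 733), {
    for (step in seq_len(total_steps)) {
      bsz <- min(plan$batch_size, n)
      idx <- sample.int(n, bsz, replace = TRUE, prob = weights)
      bx <- windows$windows[idx, , , drop = FALSE]
      by <- y_all[idx, , drop = FALSE]
      mix <- NULL
      if (use_mixup) {
        draw <- sample_mixup(mixup)
        mix <- list(lambda = draw$lambda, perm = sample.int(bsz),
                    layer = draw$layer)
        by <- draw$lambda * by + (1 - draw$lambda) * by[mix$perm, , drop = FALSE]
      }
      fp <- forward_pass(params, model$config, bx, mix = mix,
                         want_cache = TRUE)
      ce <- cross_entropy(fp$logits, by)
      grads <- backward_pass(params, model$config, fp$cache, ce$dlogits)
      lr <- one_cycle_lr(step, total_steps, plan)
      upd <- adabelief_step(params, grads, state, lr, plan, step)
      params <- upd$params
      state <- upd$state
      losses[step] <- ce$loss
      lr_trace[step] <- lr
    }
  })
  model$params <- params
  structure(list(
    model = model,
    losses = losses,
    epoch_losses = colMeans(matrix(losses, nrow = steps_per_epoch)),
    lr_trace = lr_trace,
    seed = as.integer(seed),
    wall_time_s = proc.time()[["elapsed"]] - t0
  ), class = "train_result")
}

#' Multi-seed training and evaluation protocol
#'
#' Repeats build/train/evaluate over several seeds and reports the mean and
#' standard deviation of weighted and macro F1 on the test split.
#'
#' @param build_fn Function `seed -> glula_model`.
#' @param splits List with `train` and `test` [window_batch()]es (e.g. from
#'   [preprocess_split()]).
#' @param plan A [train_plan()].
#' @param mixup A [mixup_config()] or `NULL`.
#' @param seeds Integer vector of seeds (default `1:plan$n_seeds`).
#'
#' @return List with `per_seed` data frame and `summary` (mean/sd of both F1
#'   aggregates).
#' @export
run_protocol <- function(build_fn, splits, plan = train_plan(),
                         mixup = mixup_config(), seeds = NULL) {
  seeds <- seeds %||% seq_len(plan$n_seeds)
  if (length(seeds) < 1) config_error("need at least one seed")
  rows <- lapply(seeds, function(s) {
    model <- build_fn(s)
    fit <- train(model, splits$train, plan, mixup, seed = s)
    preds <- predict(fit$model, splits$test)
    rep_ <- f1_scores(splits$test$labels, preds,
                      n_classes = model$config$n_classes)
    data.frame(seed = s, weighted_f1 = rep_$weighted_f1,
               macro_f1 = rep_$macro_f1)
  })
  per_seed <- do.call(rbind, rows)
  list(
    per_seed = per_seed,
    summary = list(
      mean_weighted_f1 = mean(per_seed$weighted_f1),
      sd_weighted_f1 = stats::sd(per_seed$weighted_f1),
      mean_macro_f1 = mean(per_seed$macro_f1),
      sd_macro_f1 = stats::sd(per_seed$macro_f1)
    )
  )
}
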