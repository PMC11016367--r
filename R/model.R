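# Assembly of the full network: embedding projection, class token, axial
# positional embedding, pre-norm gated convolutional main block, pre-norm
# branched convolution block, pre-norm additional block (linear attention,
# softmax attention, or a second GLU block), and a two-layer classification
# head that reads only the token position. Forward and backward passes are
# explicit; manifold-mixup hook points sit after the embedding stage and
# after the main block.

#' Embedding dimension rule
#'
#' `d = multiplier * 2^ceiling(log2(C))`, floored at 8: the embedding width
#' is the smallest power of two at least the channel count, optionally
#' doubled for very low-dimensional sensor sets.
#'
#' @param n_channels Number of sensor channels C.
#' @param multiplier 1 or 2.
#'
#' @return Embedding dimension (integer power of two).
#' @export
embedding_dim_for <- function(n_channels, multiplier = 1) {
  if (!is_count(n_channels)) config_error("n_channels must be >= 1")
  if (!multiplier %in% c(1, 2)) config_error("multiplier must be 1 or 2")
  as.integer(max(8, multiplier * 2^ceiling(log2(n_channels))))
}

#' Model configuration
#'
#' Describes one of the three architecture variants: the main block is always
#' a gated convolutional (GLU) block; the additional block selects the
#' variant (GLU -> GLU-HAR, softmax attention -> GLUSA-HAR, linear attention
#' -> GLULA-HAR).
#'
#' @param n_channels Number of input sensor channels C.
#' @param window_length Window length W in timesteps.
#' @param n_classes Number of activity classes.
#' @param embedding_multiplier 1 or 2; feeds [embedding_dim_for()].
#' @param heads Attention head count; must divide the embedding dimension.
#' @param additional_block One of `"linear_attention"`, `"softmax_attention"`,
#'   `"glu"`.
#' @param embedding_dim Optional explicit override of the derived dimension
#'   (must be a power of two).
#' @param glu_kernel,branch_kernel,sep_kernel Convolution kernel sizes.
#' @param bottleneck_ratio GLU bottleneck width as a fraction of d.
#' @param narrow_ratio Width of the kernel-3 branch as a fraction of d.
#' @param seed Integer seed controlling initialization.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_channels,
                         window_length,
                         n_classes,
                         embedding_multiplier = 1,
                         heads = 1,
                         additional_block = c("linear_attention",
                                              "softmax_attention", "glu"),
                         embedding_dim = NULL,
                         glu_kernel = 3,
                         branch_kernel = 3,
                         sep_kernel = 9,
                         bottleneck_ratio = 0.25,
                         narrow_ratio = 0.25,
                         seed = 1L) {
  additional_block <- match.arg(additional_block)
  if (!is_count(n_channels)) config_error("n_channels must be >= 1")
  if (!is_count(window_length)) config_error("window_length must be >= 1")
  if (!is_count(n_classes, min = 2)) config_error("n_classes must be >= 2")
  d <- embedding_dim %||% embedding_dim_for(n_channels, embedding_multiplier)
  if (bitwAnd(as.integer(d), as.integer(d) - 1L) != 0) {
    config_error("embedding_dim must be a power of two, got %d", d)
  }
  if (d %% heads != 0) {
    config_error("embedding_dim %d is not divisible by heads %d", d, heads)
  }
  l <- as.integer(window_length) + 1L
  pos_rows <- ceiling(sqrt(l))
  structure(
    list(
      n_channels = as.integer(n_channels),
      window_length = as.integer(window_length),
      n_classes = as.integer(n_classes),
      embedding_multiplier = embedding_multiplier,
      embedding_dim = as.integer(d),
      heads = as.integer(heads),
      additional_block = additional_block,
      glu_kernel = as.integer(glu_kernel),
      branch_kernel = as.integer(branch_kernel),
      sep_kernel = as.integer(sep_kernel),
      bottleneck = max(1L, as.integer(round(d * bottleneck_ratio))),
      narrow_width = max(1L, as.integer(round(d * narrow_ratio))),
      pos_rows = as.integer(pos_rows),
      pos_cols = as.integer(ceiling(l / pos_rows)),
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

variant_name <- function(config) {
  switch(config$additional_block,
         glu = "GLU-HAR",
         softmax_attention = "GLUSA-HAR",
         linear_attention = "GLULA-HAR")
}

#' Named dataset profiles
#'
#' Presets mirroring the five wearable-sensor benchmarks the architecture is
#' sized for: channel count, sampling rate, window seconds, embedding
#' multiplier, head count and class count. SKODA and OPPORTUNITY channel
#' counts are the conventional ones (60 and 113); the original studies do not
#' print them exactly.
#'
#' @param name One of `"pamap2"`, `"skoda"`, `"opportunity"`, `"uschad"`,
#'   `"daphnet"` (a `"-like"` suffix is accepted).
#'
#' @return List with fields `n_channels`, `sampling_rate`, `window_seconds`,
#'   `window_length`, `embedding_multiplier`, `heads`, `n_classes`.
#' @export
dataset_profile <- function(name) {
  key <- sub("[-_]like$", "", tolower(name))
  profiles <- list(
    pamap2 = list(n_channels = 52L, sampling_rate = 100, window_seconds = 5,
                  embedding_multiplier = 1, heads = 2L, n_classes = 12L),
    skoda = list(n_channels = 60L, sampling_rate = 98, window_seconds = 2.5,
                 embedding_multiplier = 1, heads = 2L, n_classes = 11L),
    opportunity = list(n_channels = 113L, sampling_rate = 30,
                       window_seconds = 5, embedding_multiplier = 1,
                       heads = 2L, n_classes = 18L),
    uschad = list(n_channels = 6L, sampling_rate = 100, window_seconds = 1,
                  embedding_multiplier = 2, heads = 1L, n_classes = 12L),
    daphnet = list(n_channels = 9L, sampling_rate = 64, window_seconds = 5,
                   embedding_multiplier = 1, heads = 1L, n_classes = 2L)
  )
  if (!key %in% names(profiles)) {
    config_error("unknown dataset profile '%s' (know: %s)", name,
                 paste(names(profiles), collapse = ", "))
  }
  prof <- profiles[[key]]
  prof$window_length <- as.integer(round(prof$window_seconds * prof$sampling_rate))
  prof$name <- key
  prof
}

#' Model configuration from a dataset profile
#'
#' @param profile Profile name or the list returned by [dataset_profile()].
#' @param additional_block Architecture variant selector.
#' @param seed Integer seed.
#'
#' @return A [model_config()].
#' @export
preset_model_config <- function(profile,
                                additional_block = "linear_attention",
                                seed = 1L) {
  if (is.character(profile)) profile <- dataset_profile(profile)
  model_config(
    n_channels = profile$n_channels,
    window_length = profile$window_length,
    n_classes = profile$n_classes,
    embedding_multiplier = profile$embedding_multiplier,
    heads = profile$heads,
    additional_block = additional_block,
    seed = seed
  )
}

#' Build a model from a configuration
#'
#' Initialization is deterministic given `config$seed`. Layer order:
#' embed, prepend token, add axial positional embedding, then three
#' pre-norm + block + residual stages (GLU main block; branched convolutions;
#' the additional block), then the two-layer head on the token position.
#'
#' @param config A [model_config()].
#'
#' @return An object of class `glula_model` (fields `config`, `params`).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$embedding_dim
  params <- with_seed(config$seed, {
    add <- switch(config$additional_block,
      glu = list(
        conv_a = init_conv(config$glu_kernel, d, config$bottleneck),
        conv_g = init_conv(config$glu_kernel, d, config$bottleneck),
        proj = init_linear(config$bottleneck, d)
      ),
      list(
        Wq = init_linear(d, d), Wk = init_linear(d, d),
        Wv = init_linear(d, d), Wo = init_linear(d, d)
      )
    )
    list(
      embed = init_linear(config$n_channels, d),
      token = stats::rnorm(d, sd = 0.02),
      pos = list(
        A = matrix(stats::rnorm(config$pos_rows * d, sd = 0.02),
                   config$pos_rows, d),
        B = matrix(stats::rnorm(config$pos_cols * d, sd = 0.02),
                   config$pos_cols, d)
      ),
      ln1 = list(g = rep(1, d), b = rep(0, d)),
      glu1 = list(
        conv_a = init_conv(config$glu_kernel, d, config$bottleneck),
        conv_g = init_conv(config$glu_kernel, d, config$bottleneck),
        proj = init_linear(config$bottleneck, d)
      ),
      ln2 = list(g = rep(1, d), b = rep(0, d)),
      branched = list(
        branch1 = init_linear(d, d),
        branch2 = init_conv(config$branch_kernel, d, config$narrow_width),
        dw = init_depthwise(config$sep_kernel, d),
        pw = init_linear(d, d)
      ),
      ln3 = list(g = rep(1, d), b = rep(0, d)),
      additional = add,
      head = list(fc1 = init_linear(d, d),
                  fc2 = init_linear(d, config$n_classes))
    )
  })
  structure(list(config = config, params = params), class = "glula_model")
}

#' @export
print.glula_model <- function(x, ...) {
  cat(sprintf("<glula_model> %s: C=%d, W=%d, d=%d, heads=%d, %d classes, %d parameters\n",
              variant_name(x$config), x$config$n_channels,
              x$config$window_length, x$config$embedding_dim,
              x$config$heads, x$config$n_classes,
              count_parameters(x)))
  invisible(x)
}

# Dense layer on a plain N x d matrix (head layers).
fc_fwd <- function(x, p) {
  list(y = sweep(x %*% p$W, 2, p$b, `+`), cache = list(x = x))
}

fc_bwd <- function(dy, p, cache) {
  list(dx = dy %*% t(p$W),
       grad = list(W = t(cache$x) %*% dy, b = colSums(dy)))
}

# Apply manifold mixup at a hook point: convex combination of the batch with
# a permuted partner batch.
mix_hidden <- function(h, mix) {
  mix$lambda * h + (1 - mix$lambda) * h[mix$perm, , , drop = FALSE]
}

mix_hidden_bwd <- function(dh, mix) {
  dpre <- mix$lambda * dh
  dpre[mix$perm, , ] <- dpre[mix$perm, , , drop = FALSE] +
    (1 - mix$lambda) * dh
  dpre
}

# Full forward pass. x is an N x W x C array. mix (optional) is
# list(lambda, perm, layer) with layer in {"input_embedding",
# "after_main_block"}. Returns logits and, if want_cache, everything needed
# for the backward pass.
forward_pass <- function(params, config, x, mix = NULL, want_cache = FALSE) {
  n <- dim(x)[1]; w <- dim(x)[2]
  if (dim(x)[3] != config$n_channels) {
    shape_error("batch has %d channels, model expects %d",
                dim(x)[3], config$n_channels)
  }
  if (w != config$window_length) {
    shape_error("batch windows have %d timesteps, model expects %d",
                w, config$window_length)
  }
  l <- w + 1L
  ef <- pw_fwd(x, params$embed)
  h <- array(0, dim = c(n, l, config$embedding_dim))
  h[, 1, ] <- matrix(rep(params$token, each = n), n, config$embedding_dim)
  h[, 2:l, ] <- ef$y
  pos_idx <- seq_len(l) - 1L
  pos_i <- pos_idx %/% config$pos_cols + 1L
  pos_j <- pos_idx %% config$pos_cols + 1L
  ptab <- params$pos$A[pos_i, , drop = FALSE] +
    params$pos$B[pos_j, , drop = FALSE]
  h <- h + array(rep(ptab, each = n), dim = dim(h))
  if (!is.null(mix) && mix$layer == "input_embedding") h <- mix_hidden(h, mix)
  h0 <- h
  n1 <- ln_fwd(h0, params$ln1)
  g1 <- glu_core_fwd(n1$y, params$glu1)
  h <- h0 + g1$y
  if (!is.null(mix) && mix$layer == "after_main_block") h <- mix_hidden(h, mix)
  h1 <- h
  n2 <- ln_fwd(h1, params$ln2)
  b2 <- branched_core_fwd(n2$y, params$branched)
  h2 <- h1 + b2$y
  n3 <- ln_fwd(h2, params$ln3)
  a3 <- switch(config$additional_block,
    glu = glu_core_fwd(n3$y, params$additional),
    softmax_attention = sm_attn_fwd(n3$y, params$additional, config$heads),
    linear_attention = lin_attn_fwd(n3$y, params$additional, config$heads)
  )
  h3 <- h2 + a3$y
  token <- matrix(h3[, 1, ], n, config$embedding_dim)
  f1 <- fc_fwd(token, params$head$fc1)
  m1 <- mish_fwd(f1$y)
  f2 <- fc_fwd(m1$y, params$head$fc2)
  out <- list(logits = f2$y)
  if (want_cache) {
    out$cache <- list(ef = ef, pos_i = pos_i, pos_j = pos_j, mix = mix,
                      n1 = n1, g1 = g1, n2 = n2, b2 = b2, n3 = n3, a3 = a3,
                      f1 = f1, m1 = m1, f2 = f2, n = n, l = l, h3 = h3)
  }
  out
}

# Full backward pass; returns the parameter-gradient tree.
backward_pass <- function(params, config, cache, dlogits) {
  n <- cache$n; l <- cache$l
  bf2 <- fc_bwd(dlogits, params$head$fc2, cache$f2$cache)
  dm1 <- mish_bwd(bf2$dx, cache$m1$cache)
  bf1 <- fc_bwd(dm1, params$head$fc1, cache$f1$cache)
  dh3 <- array(0, dim = c(n, l, config$embedding_dim))
  dh3[, 1, ] <- bf1$dx
  ba3 <- switch(config$additional_block,
    glu = glu_core_bwd(dh3, params$additional, cache$a3$cache),
    softmax_attention = sm_attn_bwd(dh3, params$additional, cache$a3$cache),
    linear_attention = lin_attn_bwd(dh3, params$additional, cache$a3$cache)
  )
  bn3 <- ln_bwd(ba3$dx, params$ln3, cache$n3$cache)
  dh2 <- dh3 + bn3$dx
  bb2 <- branched_core_bwd(dh2, params$branched, cache$b2$cache)
  bn2 <- ln_bwd(bb2$dx, params$ln2, cache$n2$cache)
  dh1 <- dh2 + bn2$dx
  mix <- cache$mix
  if (!is.null(mix) && mix$layer == "after_main_block") {
    dh1 <- mix_hidden_bwd(dh1, mix)
  }
  bg1 <- glu_core_bwd(dh1, params$glu1, cache$g1$cache)
  bn1 <- ln_bwd(bg1$dx, params$ln1, cache$n1$cache)
  dh0 <- dh1 + bn1$dx
  if (!is.null(mix) && mix$layer == "input_embedding") {
    dh0 <- mix_hidden_bwd(dh0, mix)
  }
  # positional table gradient: sum over batch, then pool by axis index
  dptab <- colSums(dh0)
  dA <- rowsum(dptab, cache$pos_i)
  dB <- rowsum(dptab, cache$pos_j)
  gA <- matrix(0, nrow(params$pos$A), ncol(params$pos$A))
  gA[sort(unique(cache$pos_i)), ] <- dA
  gB <- matrix(0, nrow(params$pos$B), ncol(params$pos$B))
  gB[sort(unique(cache$pos_j)), ] <- dB
  dtoken <- colSums(matrix(dh0[, 1, ], n, config$embedding_dim))
  de <- dh0[, 2:l, , drop = FALSE]
  be <- pw_bwd(de, params$embed, cache$ef$cache)
  list(
    embed = be$grad,
    token = dtoken,
    pos = list(A = gA, B = gB),
    ln1 = bn1$grad,
    glu1 = bg1$grad,
    ln2 = bn2$grad,
    branched = bb2$grad,
    ln3 = bn3$grad,
    additional = ba3$grad,
    head = list(fc1 = bf1$grad, fc2 = bf2$grad)
  )
}

#' Forward inference
#'
#' @param model A [build_model()] result.
#' @param batch N x W x C array, a single W x C matrix, or a
#'   [window_batch()].
#' @param return_sequence If `TRUE`, also return the final hidden sequence.
#'
#' @return N x n_classes logit matrix (with `sequence` attribute when
#'   requested).
#' @export
model_forward <- function(model, batch, return_sequence = FALSE) {
  stopifnot(inherits(model, "glula_model"))
  x <- batch_input(model, batch)
  if (any(!is.finite(x))) data_error("batch contains non-finite values")
  fp <- forward_pass(model$params, model$config, x,
                     want_cache = return_sequence)
  logits <- fp$logits
  if (return_sequence) attr(logits, "sequence") <- fp$cache$h3
  logits
}

batch_input <- function(model, batch) {
  if (inherits(batch, "window_batch")) batch <- batch$windows
  if (is.matrix(batch)) batch <- array(batch, c(1, nrow(batch), ncol(batch)))
  if (!is.array(batch) || length(dim(batch)) != 3) {
    shape_error("batch must be an N x W x C array")
  }
  batch
}

# Apply the classification head to an already-computed final hidden sequence;
# exposed for token-locality diagnostics.
head_from_sequence <- function(model, h3) {
  token <- matrix(h3[, 1, ], dim(h3)[1], model$config$embedding_dim)
  f1 <- fc_fwd(token, model$params$head$fc1)
  fc_fwd(mish(f1$y), model$params$head$fc2)$y
}

#' Predict class labels for a window batch
#'
#' @param object A `glula_model`.
#' @param batch Windows as for [model_forward()].
#' @param chunk_size Windows per forward chunk (memory control).
#' @param ... Unused.
#'
#' @return Integer vector of 0-based predicted labels.
#' @export
predict.glula_model <- function(object, batch, chunk_size = 256, ...) {
  x <- batch_input(object, batch)
  n <- dim(x)[1]
  preds <- integer(n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + chunk_size - 1L)
    logits <- forward_pass(object$params, object$config,
                           x[idx, , , drop = FALSE])$logits
    preds[idx] <- max.col(logits, ties.method = "first") - 1L
    at <- at + chunk_size
  }
  preds
}

#' Count trainable parameters
#'
#' @param model A `glula_model`.
#' @param scope `"total"` for a single integer, `"per_block"` for a named
#'   breakdown that sums to the total.
#'
#' @return Integer count or named integer vector.
#' @export
count_parameters <- function(model, scope = c("total", "per_block")) {
  scope <- match.arg(scope)
  p <- model$params
  blocks <- c(
    embedding = tree_n_params(p$embed) + length(p$token),
    positional = tree_n_params(p$pos),
    norms = tree_n_params(p$ln1) + tree_n_params(p$ln2) + tree_n_params(p$ln3),
    main_glu = tree_n_params(p$glu1),
    branched = tree_n_params(p$branched),
    additional = tree_n_params(p$additional),
    head = tree_n_params(p$head)
  )
  if (scope == "total") as.integer(sum(blocks)) else vapply(blocks, as.integer, integer(1))
}
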