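# Independent reference implementations used as oracles. These deliberately
# use naive loops and explicit formulas, never the package's vectorized code
# paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scaled dot-product softmax attention with explicit exponentials, double
# loop over query/key positions.
naive_softmax_attention <- function(x, params, heads) {
  d <- ncol(x)
  dk <- d %/% heads
  q <- sweep(x %*% params$Wq$W, 2, params$Wq$b, `+`)
  k <- sweep(x %*% params$Wk$W, 2, params$Wk$b, `+`)
  v <- sweep(x %*% params$Wv$W, 2, params$Wv$b, `+`)
  l <- nrow(x)
  ctx <- matrix(0, l, d)
  for (hh in seq_len(heads)) {
    cols <- ((hh - 1) * dk + 1):(hh * dk)
    for (i in seq_len(l)) {
      scores <- numeric(l)
      for (j in seq_len(l)) {
        scores[j] <- exp(sum(q[i, cols] * k[j, cols]) / sqrt(dk))
      }
      w <- scores / sum(scores)
      for (j in seq_len(l)) ctx[i, cols] <- ctx[i, cols] + w[j] * v[j, cols]
    }
  }
  sweep(ctx %*% params$Wo$W, 2, params$Wo$b, `+`)
}

# Generalized attention with similarity sim(q, k) = phi(q) . phi(k),
# evaluated as a quadratic-cost double loop (no summed statistics).
naive_generalized_attention <- function(x, params, heads,
                                        phi = function(z) ifelse(z > 0, z + 1, exp(z))) {
  d <- ncol(x)
  dk <- d %/% heads
  q <- sweep(x %*% params$Wq$W, 2, params$Wq$b, `+`)
  k <- sweep(x %*% params$Wk$W, 2, params$Wk$b, `+`)
  v <- sweep(x %*% params$Wv$W, 2, params$Wv$b, `+`)
  l <- nrow(x)
  ctx <- matrix(0, l, d)
  for (hh in seq_len(heads)) {
    cols <- ((hh - 1) * dk + 1):(hh * dk)
    for (i in seq_len(l)) {
      num <- numeric(dk)
      den <- 0
      for (j in seq_len(l)) {
        sim <- sum(phi(q[i, cols]) * phi(k[j, cols]))
        num <- num + sim * v[j, cols]
        den <- den + sim
      }
      ctx[i, cols] <- num / den
    }
  }
  sweep(ctx %*% params$Wo$W, 2, params$Wo$b, `+`)
}

# Instrumented attention cores: execute the naive algorithm while tallying
# every scalar multiplication, so analytic op counts can be checked against
# an actual execution trace.
instrumented_op_count <- function(mechanism, x, params, heads) {
  mults <- 0L
  mul <- function(a, b) {
    mults <<- mults + 1L
    a * b
  }
  d <- ncol(x)
  dk <- d %/% heads
  l <- nrow(x)
  project <- function(w) {
    out <- matrix(0, l, d)
    for (i in seq_len(l)) {
      for (jj in seq_len(d)) {
        acc <- 0
        for (kk in seq_len(d)) acc <- acc + mul(x[i, kk], w$W[kk, jj])
        out[i, jj] <- acc + w$b[jj]
      }
    }
    out
  }
  q <- project(params$Wq)
  k <- project(params$Wk)
  v <- project(params$Wv)
  phi <- function(z) ifelse(z > 0, z + 1, exp(z))
  ctx <- matrix(0, l, d)
  for (hh in seq_len(heads)) {
    cols <- ((hh - 1) * dk + 1):(hh * dk)
    if (mechanism == "softmax_attention") {
      scores <- matrix(0, l, l)
      for (i in seq_len(l)) {
        for (j in seq_len(l)) {
          acc <- 0
          for (cc in cols) acc <- acc + mul(q[i, cc], k[j, cc])
          scores[i, j] <- mul(acc, 1 / sqrt(dk))
        }
      }
      a <- exp(scores)
      a <- a / rowSums(a)
      for (i in seq_len(l)) {
        for (cc in cols) {
          acc <- 0
          for (j in seq_len(l)) acc <- acc + mul(a[i, j], v[j, cc])
          ctx[i, cc] <- acc
        }
      }
    } else {
      fq <- phi(q[, cols, drop = FALSE])
      fk <- phi(k[, cols, drop = FALSE])
      s <- matrix(0, dk, dk)
      for (aa in seq_len(dk)) {
        for (bb in seq_len(dk)) {
          for (j in seq_len(l)) {
            s[aa, bb] <- s[aa, bb] + mul(fk[j, aa], v[j, cols[bb]])
          }
        }
      }
      zv <- colSums(fk)
      for (i in seq_len(l)) {
        den <- 0
        for (aa in seq_len(dk)) den <- den + mul(fq[i, aa], zv[aa])
        for (bb in seq_len(dk)) {
          acc <- 0
          for (aa in seq_len(dk)) acc <- acc + mul(fq[i, aa], s[aa, bb])
          ctx[i, cols[bb]] <- acc / den
        }
      }
    }
  }
  # output projection
  for (i in seq_len(l)) {
    for (jj in seq_len(d)) {
      acc <- 0
      for (kk in seq_len(d)) acc <- acc + mul(ctx[i, kk], params$Wo$W[kk, jj])
    }
  }
  mults
}

# Brute-force per-class metrics from first principles (independent of the
# package's table()-based implementation).
brute_f1 <- function(y_true, y_pred, n_classes) {
  f1 <- numeric(n_classes)
  support <- numeric(n_classes)
  for (c in 0:(n_classes - 1)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    support[c + 1] <- sum(y_true == c)
  }
  w <- support / length(y_true)
  list(f1 = f1, weighted = sum(w * f1), macro = mean(f1))
}

# Cheap but collision-safe signature of a numeric window, for leakage checks.
window_signature <- function(w) {
  v <- as.numeric(w)
  paste(format(c(sum(v), sum(v^2), sum(v * seq_along(v))), digits = 15),
        collapse = "|")
}

# Small model config used across tests.
tiny_model_config <- function(additional_block = "linear_attention",
                              heads = 2, seed = 7) {
  model_config(n_channels = 3, window_length = 8, n_classes = 3,
               heads = heads, additional_block = additional_block,
               seed = seed)
}

# Fast generator config for training tests (scaled-down study conditions).
small_generator_config <- function(seed = 3, ...) {
  generator_config(duration_s = 60, seed = seed, ...)
}
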