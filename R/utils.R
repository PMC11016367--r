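# Internal helpers: classed errors, seeded evaluation, nested-list (pytree-style)
# arithmetic used by the optimizer, and small shape utilities.

glula_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "glula_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

config_error <- function(msg, ...) glula_stop("glula_config_error", msg, ...)
data_error <- function(msg, ...) glula_stop("glula_data_error", msg, ...)
shape_error <- function(msg, ...) glula_stop("glula_shape_error", msg, ...)
parse_error <- function(msg, ...) glula_stop("glula_parse_error", msg, ...)
checkpoint_error <- function(msg, ...) glula_stop("glula_checkpoint_error", msg, ...)

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic 31-bit hash of a string (for deriving per-subject seeds).
string_seed <- function(x) {
  codes <- utf8ToInt(as.character(x))
  h <- 0
  for (ch in codes) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Combine a base seed with extra integers into a 31-bit seed.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483629
  for (k in c(...)) h <- (h * 48271 + as.numeric(k)) %% 2147483629
  as.integer(h)
}

# Apply f leaf-wise over one or more parallel nested lists of numeric arrays.
tree_map <- function(f, ...) {
  trees <- list(...)
  x <- trees[[1]]
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros_like <- function(p) tree_map(function(x) x * 0, p)

tree_n_params <- function(p) {
  total <- 0
  rapply(p, function(x) total <<- total + length(x))
  total
}

# Flatten a parameter tree to a single numeric vector (used by tests and the
# finite-difference gradient checker).
tree_flatten <- function(p) unlist(p, use.names = FALSE)

tree_unflatten <- function(p, v) {
  i <- 0
  tree_map(function(x) {
    out <- v[(i + 1):(i + length(x))]
    i <<- i + length(x)
    array(out, dim = if (is.null(dim(x))) length(x) else dim(x))
  }, p)
}

# Reshape an (N, L, d) array to an (N*L) x d matrix and back.
mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

unmat3 <- function(x, n, l) {
  dim(x) <- c(n, l, ncol(x))
  x
}

# Coerce a single L x d matrix to a 1 x L x d batch.
as_batch3 <- function(x) {
  if (is.matrix(x)) {
    array(x, dim = c(1, nrow(x), ncol(x)))
  } else if (is.array(x) && length(dim(x)) == 3) {
    x
  } else {
    shape_error("expected an L x d matrix or an N x L x d array")
  }
}

# Shift an (N, L, C) array forward in time by 'lag' steps, zero-filling the
# start; used to express causal convolution as a sum of shifted products.
time_shift <- function(x, lag) {
  if (lag == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = d)
  if (lag < d[2]) out[, (lag + 1):d[2], ] <- x[, 1:(d[2] - lag), , drop = FALSE]
  out
}

# Adjoint of time_shift: push gradient back to the unshifted positions.
time_unshift <- function(x, lag) {
  if (lag == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = d)
  if (lag < d[2]) out[, 1:(d[2] - lag), ] <- x[, (lag + 1):d[2], , drop = FALSE]
  out
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
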