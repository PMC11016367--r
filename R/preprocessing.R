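#' Replace missing values by per-channel linear interpolation
#'
#' Interior NaNs are replaced by linear interpolation between the nearest
#' finite neighbours along time; leading/trailing NaNs are filled with the
#' nearest finite value. Matches the usual repair step for wearable-sensor
#' dropouts.
#'
#' @param recording A [sensor_recording()]; each channel must contain at
#'   least one finite value.
#'
#' @return The recording with all NaNs replaced.
#' @export
interpolate_nans <- function(recording) {
  stopifnot(inherits(recording, "sensor_recording"))
  v <- recording$values
  t_n <- nrow(v)
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    finite <- which(is.finite(col))
    if (length(finite) == 0) {
      data_error("channel '%s' contains no finite values",
                 recording$channel_names[j])
    }
    if (length(finite) < t_n) {
      v[, j] <- stats::approx(x = finite, y = col[finite], xout = seq_len(t_n),
                              method = "linear", rule = 2)$y
    }
  }
  recording$values <- v
  recording
}

#' Fit per-channel z-score normalization statistics
#'
#' Pools all timesteps of the supplied (training) recordings and computes the
#' per-channel mean and population standard deviation (divide-by-N
#' convention, so the statistics are reproducible bit-for-bit from pooled
#' moments). Statistics must be fit on training subjects only to avoid
#' evaluation leakage.
#'
#' @param recordings A [sensor_recording()] or list of them, NaN-free.
#' @param epsilon Guard used at apply time for constant channels.
#'
#' @return An object of class `normalization_stats` with fields `mean`, `sd`
#'   (per channel) and `epsilon`.
#' @export
fit_normalization <- function(recordings, epsilon = 1e-8) {
  if (inherits(recordings, "sensor_recording")) recordings <- list(recordings)
  if (length(recordings) == 0) data_error("no recordings supplied")
  mats <- lapply(recordings, function(r) {
    stopifnot(inherits(r, "sensor_recording"))
    if (any(!is.finite(r$values))) {
      data_error("recordings must be NaN-free; run interpolate_nans() first")
    }
    r$values
  })
  pooled <- do.call(rbind, mats)
  mu <- colMeans(pooled)
  sdv <- sqrt(colMeans(sweep(pooled, 2, mu)^2))
  structure(list(mean = mu, sd = sdv, epsilon = epsilon),
            class = "normalization_stats")
}

#' Apply (or invert) z-score normalization
#'
#' Transforms each value to `(value - mean_c) / max(sd_c, epsilon)`. With
#' `invert = TRUE` the algebraic inverse is applied instead.
#'
#' @param recording A [sensor_recording()].
#' @param stats A `normalization_stats` from [fit_normalization()].
#' @param invert If `TRUE`, undo the transformation.
#'
#' @return The transformed recording.
#' @export
apply_normalization <- function(recording, stats, invert = FALSE) {
  stopifnot(inherits(recording, "sensor_recording"),
            inherits(stats, "normalization_stats"))
  if (ncol(recording$values) != length(stats$mean)) {
    data_error("recording has %d channels but stats describe %d",
               ncol(recording$values), length(stats$mean))
  }
  denom <- pmax(stats$sd, stats$epsilon)
  if (invert) {
    recording$values <- sweep(sweep(recording$values, 2, denom, `*`),
                              2, stats$mean, `+`)
  } else {
    recording$values <- sweep(sweep(recording$values, 2, stats$mean, `-`),
                              2, denom, `/`)
  }
  recording
}

#' Construct a window batch
#'
#' @param windows N x W x C numeric array of segmented windows.
#' @param labels Length-N integer vector (0-based window labels).
#' @param subject_ids Length-N character vector.
#' @param window_length Window length W in timesteps.
#' @param step Hop size in timesteps.
#'
#' @return An object of class `window_batch`.
#' @export
window_batch <- function(windows, labels, subject_ids, window_length, step) {
  stopifnot(is.array(windows), length(dim(windows)) == 3)
  if (any(!is.finite(windows))) data_error("windows must be NaN-free")
  structure(
    list(windows = windows, labels = as.integer(labels),
         subject_ids = as.character(subject_ids),
         window_length = as.integer(window_length), step = as.integer(step)),
    class = "window_batch"
  )
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_batch> %d windows of %d timesteps x %d channels (step %d)\n",
              d[1], d[2], d[3], x$step))
  invisible(x)
}

#' Segment a recording into overlapping sliding windows
#'
#' Windows are `[i*step, i*step + W)` in 0-based half-open time coordinates
#' with `step = round(W * (1 - overlap))`; the number of windows is
#' `floor((T - W)/step) + 1` for `T >= W`, else 0. Each window receives the
#' majority vote of its per-timestep labels, ties broken by the lowest class
#' index.
#'
#' @param recording A NaN-free [sensor_recording()].
#' @param window_length Window length W in timesteps.
#' @param overlap Fractional overlap in `[0, 1)`; 0.5 is the conventional
#'   choice for wearable-sensor pipelines.
#'
#' @return A [window_batch()]; empty (0 windows) when `T < W`.
#' @export
sliding_windows <- function(recording, window_length, overlap = 0.5) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (!is_count(window_length)) config_error("window_length must be >= 1")
  if (overlap < 0 || overlap >= 1) config_error("overlap must lie in [0, 1)")
  w <- as.integer(window_length)
  step <- as.integer(round(w * (1 - overlap)))
  if (step < 1) config_error("step = round(W*(1-overlap)) must be >= 1")
  if (any(!is.finite(recording$values))) {
    data_error("recording contains NaN; run interpolate_nans() first")
  }
  t_n <- nrow(recording$values)
  c_n <- ncol(recording$values)
  n_win <- if (t_n >= w) (t_n - w) %/% step + 1L else 0L
  if (n_win == 0) {
    warning(sprintf("recording of %d timesteps is shorter than window %d; empty batch",
                    t_n, w))
    return(window_batch(array(0, c(0, w, c_n)), integer(0), character(0), w, step))
  }
  windows <- array(0, dim = c(n_win, w, c_n))
  labels <- integer(n_win)
  for (i in seq_len(n_win)) {
    start <- (i - 1L) * step
    idx <- (start + 1L):(start + w)
    windows[i, , ] <- recording$values[idx, ]
    labels[i] <- majority_label(recording$labels[idx])
  }
  window_batch(windows, labels, rep(recording$subject_id, n_win), w, step)
}

# Majority vote with lowest-class-index tie break.
majority_label <- function(labels) {
  counts <- table(labels)
  winners <- as.integer(names(counts)[counts == max(counts)])
  min(winners)
}

#' Inverse-frequency sampling weights for class balancing
#'
#' Each window gets weight proportional to `1 / count(class(window))`,
#' normalized to sum to 1; sampling training batches with these weights makes
#' expected class proportions uniform. Used only by the training sampler,
#' never by evaluation.
#'
#' @param labels Integer vector of window labels.
#'
#' @return Numeric vector of per-window probabilities summing to 1.
#' @export
class_balance_weights <- function(labels) {
  if (length(labels) < 1) data_error("need at least one window")
  counts <- table(labels)
  w <- 1 / as.numeric(counts[as.character(labels)])
  w / sum(w)
}

#' Combine several window batches into one
#'
#' @param batches List of [window_batch()] objects with identical window
#'   length and channel count.
#'
#' @return A single [window_batch()].
#' @export
bind_window_batches <- function(batches) {
  batches <- Filter(function(b) dim(b$windows)[1] > 0, batches)
  if (length(batches) == 0) data_error("no non-empty batches to bind")
  w <- batches[[1]]$window_length
  c_n <- dim(batches[[1]]$windows)[3]
  for (b in batches) {
    if (b$window_length != w || dim(b$windows)[3] != c_n) {
      shape_error("window batches differ in window length or channel count")
    }
  }
  n_tot <- sum(vapply(batches, function(b) dim(b$windows)[1], integer(1)))
  windows <- array(0, dim = c(n_tot, w, c_n))
  labels <- integer(n_tot)
  subjects <- character(n_tot)
  at <- 0L
  for (b in batches) {
    n <- dim(b$windows)[1]
    windows[at + seq_len(n), , ] <- b$windows
    labels[at + seq_len(n)] <- b$labels
    subjects[at + seq_len(n)] <- b$subject_ids
    at <- at + n
  }
  window_batch(windows, labels, subjects, w, batches[[1]]$step)
}

#' Run the full preprocessing chain on train/test recording sets
#'
#' Interpolates NaNs, fits z-score statistics on the training recordings
#' only, normalizes both sets and segments them into 50%-overlap windows
#' (overridable).
#'
#' @param train_recordings,test_recordings Lists of [sensor_recording()].
#' @param window_length Window length in timesteps.
#' @param overlap Fractional window overlap.
#'
#' @return List with `train` and `test` [window_batch()]es and the fitted
#'   `stats`.
#' @export
preprocess_split <- function(train_recordings, test_recordings, window_length,
                             overlap = 0.5) {
  train_recordings <- lapply(train_recordings, interpolate_nans)
  test_recordings <- lapply(test_recordings, interpolate_nans)
  stats <- fit_normalization(train_recordings)
  seg <- function(recs) {
    bind_window_batches(lapply(recs, function(r) {
      sliding_windows(apply_normalization(r, stats), window_length, overlap)
    }))
  }
  list(train = seg(train_recordings), test = seg(test_recordings), stats = stats)
}
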