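# Metrics (per-class precision/recall/F1 with weighted and macro
# aggregates), leave-one-subject-out folds, the single-subject chunk
# protocol, and an inference-timing harness.

#' Per-class and aggregate F1 scores
#'
#' Computes the confusion matrix, per-class precision and recall (0/0
#' convention: an empty denominator yields 0), per-class F1, the weighted F1
#' (per-class F1 averaged with weights equal to each class's support
#' proportion in `y_true`) and the macro F1 (unweighted mean).
#'
#' @param y_true,y_pred Equal-length integer vectors of 0-based labels.
#' @param n_classes Number of classes (default: inferred from the data).
#'
#' @return An object of class `evaluation_report` with fields `confusion`,
#'   `per_class` (data frame), `weighted_f1`, `macro_f1`, `accuracy`,
#'   `support_weights`.
#' @export
f1_scores <- function(y_true, y_pred, n_classes = NULL) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    data_error("y_true and y_pred must be equal-length non-empty vectors")
  }
  n_classes <- n_classes %||% (max(c(y_true, y_pred)) + 1L)
  lev <- 0:(n_classes - 1)
  confusion <- table(factor(y_true, levels = lev),
                     factor(y_pred, levels = lev))
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- true_n / sum(true_n)
  structure(list(
    confusion = unclass(confusion),
    per_class = data.frame(class = lev, support = as.integer(true_n),
                           precision = as.numeric(precision),
                           recall = as.numeric(recall),
                           f1 = as.numeric(f1)),
    support_weights = as.numeric(w),
    weighted_f1 = sum(w * f1),
    macro_f1 = mean(f1),
    accuracy = sum(tp) / length(y_true)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> weighted F1 %.4f | macro F1 %.4f | accuracy %.4f\n",
              x$weighted_f1, x$macro_f1, x$accuracy))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is that subject's recording,
#' the training set is everyone else. Normalization statistics must be
#' refit per fold on the training subjects only (done by
#' [prepare_fold()] / [loso_evaluate()]).
#'
#' @param recordings List of [sensor_recording()] objects with distinct
#'   subject ids; at least 2 subjects (for a single subject use
#'   [chunk_folds()]).
#'
#' @return List of folds, each with `test_subject`, `train_subjects`,
#'   `train` (recordings list) and `test` (recordings list).
#' @export
loso_folds <- function(recordings) {
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids)) data_error("subject ids must be distinct")
  if (length(recordings) < 2) {
    data_error("need >= 2 subjects for LOSO; use chunk_folds() for one subject")
  }
  lapply(seq_along(recordings), function(i) {
    structure(list(
      test_subject = ids[i],
      train_subjects = ids[-i],
      train = recordings[-i],
      test = recordings[i]
    ), class = "loso_fold")
  })
}

#' Preprocess one fold without leakage
#'
#' Runs the full preprocessing chain with normalization fit on the fold's
#' training recordings only.
#'
#' @param fold A fold from [loso_folds()] or [chunk_folds()].
#' @param window_length Window length in timesteps.
#' @param overlap Fractional overlap.
#'
#' @return As [preprocess_split()].
#' @export
prepare_fold <- function(fold, window_length, overlap = 0.5) {
  preprocess_split(fold$train, fold$test, window_length, overlap)
}

#' Single-subject chunk folds
#'
#' Splits one recording into `n_chunks` contiguous non-overlapping chunks
#' (boundaries at `floor(i*T/n_chunks)`, so lengths differ by at most one
#' timestep) and randomly assigns each chunk to a fold; each fold tests one
#' chunk and trains on the rest. Chunks stay contiguous in time so no window
#' can straddle a fold boundary through the segmentation overlap.
#'
#' @param recording A single [sensor_recording()].
#' @param n_chunks Number of chunks (default 10).
#' @param window_length Window length, used to validate the recording is
#'   long enough.
#' @param seed Integer seed for the random chunk-to-fold assignment.
#'
#' @return List of folds as in [loso_folds()], with chunk recordings carrying
#'   subject ids `"<id>#chunk<k>"`.
#' @export
chunk_folds <- function(recording, n_chunks = 10, window_length = 1,
                        seed = 1L) {
  stopifnot(inherits(recording, "sensor_recording"))
  t_n <- nrow(recording$values)
  if (t_n < n_chunks * window_length) {
    data_error("recording too short: %d timesteps for %d chunks of >= %d",
               t_n, n_chunks, window_length)
  }
  bounds <- floor(seq_len(n_chunks) * t_n / n_chunks)
  starts <- c(0, bounds[-n_chunks]) + 1
  chunks <- lapply(seq_len(n_chunks), function(k) {
    idx <- starts[k]:bounds[k]
    sensor_recording(recording$values[idx, , drop = FALSE],
                     recording$labels[idx],
                     sprintf("%s#chunk%02d", recording$subject_id, k),
                     recording$sampling_rate, recording$channel_names)
  })
  order_ <- with_seed(derive_seed(seed, 977), sample.int(n_chunks))
  lapply(order_, function(k) {
    structure(list(
      test_subject = chunks[[k]]$subject_id,
      train_subjects = vapply(chunks[-k], function(r) r$subject_id,
                              character(1)),
      train = chunks[-k],
      test = chunks[k]
    ), class = "loso_fold")
  })
}

#' Leave-one-subject-out evaluation of a model configuration
#'
#' For each fold: preprocess (stats fit on train only), build a model per
#' seed, train and evaluate; reports per-fold, per-seed weighted and macro F1
#' plus overall means.
#'
#' @param recordings List of [sensor_recording()]s (>= 2 subjects).
#' @param config_fn Function `seed -> glula_model` builder taking the seed.
#' @param window_length Window length in timesteps.
#' @param plan A [train_plan()].
#' @param mixup A [mixup_config()] or `NULL`.
#' @param overlap Window overlap.
#' @param seeds Seeds (default `1:plan$n_seeds`).
#'
#' @return List with `per_fold` data frame and `summary`.
#' @export
loso_evaluate <- function(recordings, config_fn, window_length,
                          plan = train_plan(), mixup = mixup_config(),
                          overlap = 0.5, seeds = NULL) {
  seeds <- seeds %||% seq_len(plan$n_seeds)
  folds <- loso_folds(recordings)
  rows <- list()
  for (fold in folds) {
    splits <- prepare_fold(fold, window_length, overlap)
    res <- run_protocol(config_fn, splits, plan, mixup, seeds)
    df <- res$per_seed
    df$test_subject <- fold$test_subject
    rows[[length(rows) + 1]] <- df
  }
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       summary = list(mean_weighted_f1 = mean(per_fold$weighted_f1),
                      sd_weighted_f1 = stats::sd(per_fold$weighted_f1),
                      mean_macro_f1 = mean(per_fold$macro_f1),
                      sd_macro_f1 = stats::sd(per_fold$macro_f1)))
}

#' Inference-timing harness
#'
#' Times single-instance forward passes: `warmup` untimed passes, then
#' `reps` timed passes whose mean is reported in milliseconds. Timing values
#' are hardware-dependent and informational only; analytic op counts for the
#' model's attention mechanism at the same shape are reported alongside.
#'
#' @param model A `glula_model`.
#' @param reps Number of timed repetitions.
#' @param warmup Number of untimed warm-up passes.
#' @param seed Seed for the random probe window.
#'
#' @return List with `mean_ms`, `reps`, `timings_ms` (length `reps`) and
#'   `op_counts`.
#' @export
benchmark_inference <- function(model, reps = 500, warmup = 10, seed = 1L) {
  if (!is_count(reps)) config_error("reps must be >= 1")
  cfg <- model$config
  x <- with_seed(seed, array(stats::rnorm(cfg$window_length * cfg$n_channels),
                             dim = c(1, cfg$window_length, cfg$n_channels)))
  for (i in seq_len(warmup)) forward_pass(model$params, cfg, x)
  timings <- numeric(reps)
  for (i in seq_len(reps)) {
    t0 <- proc.time()[["elapsed"]]
    forward_pass(model$params, cfg, x)
    timings[i] <- (proc.time()[["elapsed"]] - t0) * 1000
  }
  n_seq <- cfg$window_length + 1
  ops <- c(
    linear_attention = op_count("linear_attention", n_seq,
                                cfg$embedding_dim, cfg$heads),
    softmax_attention = op_count("softmax_attention", n_seq,
                                 cfg$embedding_dim, cfg$heads)
  )
  list(mean_ms = mean(timings), reps = reps, timings_ms = timings,
       op_counts = ops)
}
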