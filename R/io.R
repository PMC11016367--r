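# File formats: the CSV recording dialect (one row per timestep: timestamp,
# channel_1..channel_C, label; NaN as empty field; YAML metadata sidecar),
# the window-batch container, model checkpoints and JSON reports.

#' Write a sensor recording to CSV
#'
#' Columns: `timestamp` (seconds), `channel_1..channel_C`, `label`; missing
#' values are written as empty fields.
#'
#' @param recording A [sensor_recording()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "sensor_recording"))
  t_n <- nrow(recording$values)
  df <- data.table::as.data.table(recording$values)
  data.table::setnames(df, paste0("channel_", seq_len(ncol(recording$values))))
  df <- cbind(
    data.table::data.table(timestamp = (seq_len(t_n) - 1) / recording$sampling_rate),
    df,
    data.table::data.table(label = recording$labels)
  )
  data.table::fwrite(df, path, na = "", quote = FALSE)
  invisible(path)
}

#' Read a sensor recording from CSV
#'
#' @param path CSV file in the dialect of [write_recording_csv()].
#' @param sampling_rate Sampling rate in Hz; if `NULL`, inferred from the
#'   timestamp column.
#' @param subject_id Subject id; defaults to the file name without extension.
#'
#' @return A [sensor_recording()].
#' @export
read_recording_csv <- function(path, sampling_rate = NULL, subject_id = NULL) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  fields <- utils::count.fields(path, sep = ",", quote = "", blank.lines.skip = FALSE)
  bad <- which(fields != fields[1])
  if (length(bad) > 0) {
    parse_error("ragged row in %s at line %d (%d fields, expected %d)",
                path, bad[1], fields[bad[1]], fields[1])
  }
  dt <- data.table::fread(path, na.strings = "", sep = ",", header = TRUE)
  cols <- names(dt)
  chan_cols <- grep("^channel_", cols, value = TRUE)
  if (!"label" %in% cols || length(chan_cols) == 0) {
    parse_error("%s lacks the expected timestamp/channel_*/label columns", path)
  }
  values <- as.matrix(dt[, chan_cols, with = FALSE])
  values[is.na(values)] <- NaN
  if (is.null(sampling_rate)) {
    ts <- dt$timestamp
    sampling_rate <- if (length(ts) > 1) 1 / stats::median(diff(ts)) else 1
  }
  sensor_recording(values, dt$label, subject_id %||%
                     sub("\\.[^.]*$", "", basename(path)),
                   sampling_rate, chan_cols)
}

#' Write a dataset (one CSV per subject plus a metadata sidecar)
#'
#' @param recordings List of [sensor_recording()]s.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in recordings) {
    write_recording_csv(r, file.path(dir, paste0(r$subject_id, ".csv")))
  }
  meta <- list(
    sampling_rate = recordings[[1]]$sampling_rate,
    channel_names = as.list(recordings[[1]]$channel_names),
    subjects = lapply(recordings, function(r) r$subject_id),
    n_classes = max(vapply(recordings, function(r) max(r$labels), integer(1))) + 1L
  )
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset_csv()]
#'
#' @param dir Dataset directory.
#'
#' @return List of [sensor_recording()]s.
#' @export
read_dataset_csv <- function(dir) {
  meta_path <- file.path(dir, "metadata.yaml")
  if (!file.exists(meta_path)) parse_error("no metadata.yaml in %s", dir)
  meta <- yaml::read_yaml(meta_path)
  lapply(meta$subjects, function(id) {
    read_recording_csv(file.path(dir, paste0(id, ".csv")),
                       sampling_rate = meta$sampling_rate, subject_id = id)
  })
}

#' Save / load a window-batch container
#'
#' Serializes the segmented windows with their labels, subjects and
#' segmentation attributes (window length, step, normalization stats) in a
#' single binary container.
#'
#' @param batch A [window_batch()].
#' @param path Container path.
#' @param stats Optional `normalization_stats` stored alongside.
#'
#' @return `path` invisibly (save); the batch with a `stats` attribute
#'   (load).
#' @export
save_window_batch <- function(batch, path, stats = NULL) {
  stopifnot(inherits(batch, "window_batch"))
  saveRDS(list(format = "glula_windows", batch = batch, stats = stats), path)
  invisible(path)
}

#' @rdname save_window_batch
#' @export
load_window_batch <- function(path) {
  if (!file.exists(path)) parse_error("window container not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "glula_windows")) {
    parse_error("%s is not a window-batch container", path)
  }
  batch <- obj$batch
  attr(batch, "stats") <- obj$stats
  batch
}

#' Save a model checkpoint
#'
#' The checkpoint embeds the full configuration and parameter tensors;
#' loading reproduces bitwise-identical forward outputs.
#'
#' @param model A `glula_model`.
#' @param path Checkpoint path.
#'
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "glula_model"))
  saveRDS(list(format = "glula_checkpoint", version = 1L,
               config = model$config, params = model$params), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path.
#' @param config Optional [model_config()]; if supplied, the checkpoint must
#'   match it (variant and all shape-determining fields).
#'
#' @return A `glula_model`.
#' @export
load_checkpoint <- function(path, config = NULL) {
  if (!file.exists(path)) checkpoint_error("checkpoint not found: %s", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    checkpoint_error("cannot read checkpoint %s: %s", path, conditionMessage(e))
  })
  if (!identical(obj$format, "glula_checkpoint")) {
    checkpoint_error("%s is not a model checkpoint", path)
  }
  if (!is.null(config)) {
    keys <- c("n_channels", "window_length", "n_classes", "embedding_dim",
              "heads", "additional_block", "glu_kernel", "branch_kernel",
              "sep_kernel", "bottleneck", "narrow_width")
    for (k in keys) {
      if (!identical(obj$config[[k]], config[[k]])) {
        checkpoint_error("checkpoint %s mismatch: %s is %s, config wants %s",
                         path, k, format(obj$config[[k]]), format(config[[k]]))
      }
    }
  }
  structure(list(config = obj$config, params = obj$params),
            class = "glula_model")
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report` (or any list of results).
#' @param path Output path.
#' @param provenance Optional named list (seed, fold ids, config hash)
#'   stored under `provenance`.
#'
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, provenance = NULL) {
  obj <- unclass(report)
  obj$confusion <- if (!is.null(obj$confusion)) as.matrix(obj$confusion)
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
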