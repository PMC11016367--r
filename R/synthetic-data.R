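#' Configuration for the synthetic wearable-sensor generator
#'
#' Describes a synthetic multichannel sensor dataset with the statistical
#' structure typical of body-worn sensor benchmarks: recordings are
#' concatenations of activity bouts, each bout carrying a class-specific
#' oscillatory signature (frequency, amplitude, postural baseline) on every
#' channel, modulated by a per-subject channel-scale vector, with additive
#' Gaussian sensor noise and contiguous runs of missing values emulating
#' sensor dropouts.
#'
#' @param n_subjects Number of subjects to generate.
#' @param n_classes Number of activity classes (>= 2).
#' @param n_channels Number of sensor channels (>= 1).
#' @param sampling_rate Sampling rate in Hz.
#' @param duration_s Recording length per subject, in seconds.
#' @param segment_length_range Integer vector of length 2: min and max bout
#'   length in timesteps.
#' @param class_frequencies Per-class oscillation frequency in Hz
#'   (length `n_classes`).
#' @param class_amplitudes Per-class oscillation amplitude (length `n_classes`).
#' @param class_baselines Per-class postural baseline offset
#'   (length `n_classes`).
#' @param subject_scale_sd Standard deviation of the log-normal multiplicative
#'   per-subject channel scale.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param nan_fraction Target fraction of missing values in `[0, 1)`,
#'   inserted as contiguous runs per channel.
#' @param class_weights Sampling probabilities over classes for bout labels;
#'   must sum to 1.
#' @param seed Integer seed; the generator is a pure function of
#'   `(config, subject_id)`.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 5,
                             n_classes = 4,
                             n_channels = 6,
                             sampling_rate = 50,
                             duration_s = 300,
                             segment_length_range = c(150, 400),
                             class_frequencies = NULL,
                             class_amplitudes = NULL,
                             class_baselines = NULL,
                             subject_scale_sd = 0.1,
                             noise_sd = 0.4,
                             nan_fraction = 0.02,
                             class_weights = NULL,
                             seed = 1L) {
  if (!is_count(n_subjects)) config_error("n_subjects must be a positive integer")
  if (!is_count(n_classes, min = 2)) config_error("n_classes must be an integer >= 2")
  if (!is_count(n_channels)) config_error("n_channels must be an integer >= 1")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    config_error("sampling_rate must be positive")
  }
  if (length(segment_length_range) != 2 ||
      segment_length_range[1] < 1 ||
      segment_length_range[2] < segment_length_range[1]) {
    config_error("segment_length_range must be (min, max) with 1 <= min <= max")
  }
  class_frequencies <- class_frequencies %||%
    (0.8 * 1.55^(seq_len(n_classes) - 1))
  class_amplitudes <- class_amplitudes %||%
    (1 + 0.5 * ((seq_len(n_classes) - 1) %% 3))
  class_baselines <- class_baselines %||%
    (0.6 * seq(-1, 1, length.out = n_classes))
  class_weights <- class_weights %||% {
    w <- rev(seq_len(n_classes))
    w / sum(w)
  }
  for (nm in c("class_frequencies", "class_amplitudes", "class_baselines",
               "class_weights")) {
    if (length(get(nm)) != n_classes) {
      config_error("%s must have length n_classes (%d)", nm, n_classes)
    }
  }
  if (any(class_weights < 0) || abs(sum(class_weights) - 1) > 1e-8) {
    config_error("class_weights must be non-negative and sum to 1")
  }
  if (!is.numeric(nan_fraction) || nan_fraction < 0 || nan_fraction >= 1) {
    config_error("nan_fraction must lie in [0, 1)")
  }
  if (noise_sd < 0 || subject_scale_sd < 0) {
    config_error("noise_sd and subject_scale_sd must be non-negative")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_classes = as.integer(n_classes),
      n_channels = as.integer(n_channels),
      sampling_rate = sampling_rate,
      duration_s = duration_s,
      segment_length_range = as.integer(segment_length_range),
      class_frequencies = class_frequencies,
      class_amplitudes = class_amplitudes,
      class_baselines = class_baselines,
      subject_scale_sd = subject_scale_sd,
      noise_sd = noise_sd,
      nan_fraction = nan_fraction,
      class_weights = class_weights,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Construct a sensor recording object
#'
#' A `sensor_recording` holds one subject's raw multichannel time series: a
#' T x C numeric matrix of sensor values (NaN allowed), a length-T vector of
#' integer activity labels in `[0, n_classes)`, a subject identifier and the
#' sampling rate.
#'
#' @param values T x C numeric matrix (rows = timesteps, columns = channels).
#' @param labels Length-T integer vector of 0-based class labels.
#' @param subject_id Subject identifier (coerced to character).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Optional length-C character vector.
#'
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(values, labels, subject_id, sampling_rate,
                             channel_names = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) {
    data_error("recording must have at least one timestep and one channel")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(values)) {
    data_error("labels length (%d) must equal number of timesteps (%d)",
               length(labels), nrow(values))
  }
  if (any(is.na(labels)) || any(labels < 0)) {
    data_error("labels must be non-negative integers")
  }
  channel_names <- channel_names %||% paste0("channel_", seq_len(ncol(values)))
  if (length(channel_names) != ncol(values)) {
    data_error("channel_names must have one entry per channel")
  }
  colnames(values) <- channel_names
  structure(
    list(
      values = values,
      labels = labels,
      subject_id = as.character(subject_id),
      sampling_rate = sampling_rate,
      channel_names = channel_names
    ),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> subject %s: %d timesteps x %d channels @ %g Hz, %d classes, %.1f%% NaN\n",
    x$subject_id, nrow(x$values), ncol(x$values), x$sampling_rate,
    length(unique(x$labels)), 100 * mean(is.nan(x$values))
  ))
  invisible(x)
}

# Per-subject multiplicative channel-scale vector; the single mechanism that
# makes leave-one-subject-out splits harder than random splits.
subject_scales <- function(config, subject_id) {
  with_seed(derive_seed(config$seed, 101, string_seed(subject_id)), {
    exp(stats::rnorm(config$n_channels, mean = 0, sd = config$subject_scale_sd))
  })
}

#' Generate one subject's synthetic sensor recording
#'
#' The recording is a concatenation of activity bouts. Within a bout of class
#' c, channel j carries
#' `amplitude_c * gain_j * scale_j * sin(2*pi*f_c*t + phase_j) + baseline_c + noise`,
#' where `gain_j`/`phase_j` are fixed channel signatures, `scale_j` is the
#' subject's channel scale and the noise is iid Gaussian. Missing values are
#' inserted as contiguous runs (geometric length, mean 5) per channel to
#' approximate `nan_fraction`, never covering an entire channel. The output
#' is a pure function of `(config, subject_id)`.
#'
#' @param config A [generator_config()].
#' @param subject_id Subject identifier.
#'
#' @return A [sensor_recording()].
#' @export
generate_recording <- function(config, subject_id) {
  if (!inherits(config, "generator_config")) {
    config_error("config must be a generator_config")
  }
  total_t <- as.integer(round(config$duration_s * config$sampling_rate))
  scales <- subject_scales(config, subject_id)
  with_seed(derive_seed(config$seed, 211, string_seed(subject_id)), {
    c_n <- config$n_channels
    # fixed per-channel signature: phase spread over the circle, mild gain taper
    phases <- 2 * pi * (seq_len(c_n) - 1) / c_n
    gains <- 0.7 + 0.6 * (seq_len(c_n) %% 2) # alternating strong/weak axes
    values <- matrix(0, nrow = total_t, ncol = c_n)
    labels <- integer(total_t)
    t0 <- 0
    while (t0 < total_t) {
      len <- sample(seq(config$segment_length_range[1],
                        config$segment_length_range[2]), 1)
      len <- min(len, total_t - t0)
      cls <- sample.int(config$n_classes, 1, prob = config$class_weights) - 1L
      tt <- (t0 + seq_len(len)) / config$sampling_rate
      f <- config$class_frequencies[cls + 1]
      a <- config$class_amplitudes[cls + 1]
      b <- config$class_baselines[cls + 1]
      for (j in seq_len(c_n)) {
        values[t0 + seq_len(len), j] <-
          a * gains[j] * scales[j] * sin(2 * pi * f * tt + phases[j]) + b
      }
      labels[t0 + seq_len(len)] <- cls
      t0 <- t0 + len
    }
    if (config$noise_sd > 0) {
      values <- values + matrix(stats::rnorm(total_t * c_n, sd = config$noise_sd),
                                nrow = total_t)
    }
    if (config$nan_fraction > 0) {
      values <- insert_nan_runs(values, config$nan_fraction)
    }
    sensor_recording(values, labels, subject_id, config$sampling_rate)
  })
}

# Insert contiguous NaN runs (geometric length, mean 5) per channel until the
# channel's missing fraction reaches the target; at least one finite value is
# always kept per channel.
insert_nan_runs <- function(values, nan_fraction) {
  t_n <- nrow(values)
  target <- nan_fraction * t_n
  max_missing <- t_n - 1 # never a fully-missing channel
  for (j in seq_len(ncol(values))) {
    missing <- 0
    # cap attempts so pathological draws cannot loop forever
    for (i in seq_len(10 * ceiling(target / 5) + 10)) {
      if (missing >= target) break
      run <- 1 + stats::rgeom(1, prob = 1 / 5)
      run <- min(run, ceiling(target - missing), max_missing - missing)
      if (run < 1) break
      start <- sample.int(t_n - run + 1, 1)
      idx <- start:(start + run - 1)
      fresh <- !is.nan(values[idx, j])
      values[idx, j] <- NaN
      missing <- missing + sum(fresh)
    }
  }
  values
}

#' Generate a full synthetic dataset (one recording per subject)
#'
#' @param config A [generator_config()].
#'
#' @return A list of [sensor_recording()] objects with distinct subject ids
#'   (`"S01"`, `"S02"`, ...), each with its own multiplicative channel-scale
#'   vector.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) {
    config_error("config must be a generator_config")
  }
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  lapply(ids, function(id) generate_recording(config, id))
}
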