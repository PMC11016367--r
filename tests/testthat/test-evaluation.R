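test_that("F1 worked example matches the hand-evaluated formulas", {
  rep_ <- f1_scores(c(0L, 0L, 0L, 1L), c(0L, 0L, 1L, 1L), 2)
  # class 0: precision 1, recall 2/3 -> F1 0.8; class 1: precision 1/2,
  # recall 1 -> F1 2/3
  expect_equal(rep_$per_class$f1, c(0.8, 2 / 3))
  expect_equal(rep_$weighted_f1, 0.75 * 0.8 + 0.25 * (2 / 3))
  expect_equal(rep_$macro_f1, mean(c(0.8, 2 / 3)))
  expect_equal(rep_$support_weights, c(0.75, 0.25))
})

test_that("F1 degenerate cases: perfect, all-wrong, empty input", {
  y <- c(0L, 1L, 2L, 1L, 0L)
  perfect <- f1_scores(y, y, 3)
  expect_equal(perfect$weighted_f1, 1)
  expect_equal(perfect$macro_f1, 1)
  wrong <- f1_scores(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L), 2)
  expect_equal(wrong$weighted_f1, 0)
  expect_error(f1_scores(integer(0), integer(0)), class = "glula_data_error")
  expect_error(f1_scores(0:3, 0:2), class = "glula_data_error")
})

test_that("F1 agrees with a brute-force confusion-matrix implementation", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(5:40, 1)
    y_true <- sample(0:(k - 1), n, replace = TRUE)
    y_pred <- sample(0:(k - 1), n, replace = TRUE)
    got <- f1_scores(y_true, y_pred, k)
    ref <- brute_f1(y_true, y_pred, k)
    expect_equal(got$per_class$f1, ref$f1)
    expect_equal(got$weighted_f1, ref$weighted)
    expect_equal(got$macro_f1, ref$macro)
  }
})

test_that("majority predictor's weighted F1 matches the closed form", {
  y <- rep(0:2, times = c(120, 60, 20))
  pred <- rep(0L, length(y))
  p0 <- 120 / 200
  # majority class: precision p0, recall 1 -> F1 = 2 p0 / (1 + p0); other
  # classes 0; weighted by supports
  expect_equal(f1_scores(y, pred, 3)$weighted_f1, p0 * 2 * p0 / (1 + p0))
})

test_that("LOSO folds partition subjects exhaustively and disjointly", {
  cfg <- generator_config(n_subjects = 3, duration_s = 20, seed = 15)
  recs <- generate_dataset(cfg)
  folds <- loso_folds(recs)
  expect_length(folds, 3)
  test_ids <- vapply(folds, function(f) f$test_subject, character(1))
  expect_setequal(test_ids, c("S01", "S02", "S03"))
  for (f in folds) {
    expect_false(f$test_subject %in% f$train_subjects)
    expect_length(f$train_subjects, 2)
  }
  expect_error(loso_folds(recs[1]), class = "glula_data_error")
})

test_that("per-fold normalization stats differ when subjects differ in scale", {
  cfg <- generator_config(n_subjects = 3, duration_s = 20, nan_fraction = 0,
                          subject_scale_sd = 0.5, seed = 16)
  recs <- generate_dataset(cfg)
  folds <- loso_folds(recs)
  s1 <- fit_normalization(folds[[1]]$train)
  s2 <- fit_normalization(folds[[2]]$train)
  expect_gt(max(abs(s1$sd - s2$sd)), 1e-4)
})

test_that("LOSO preprocessing leaks no test window into training", {
  cfg <- generator_config(n_subjects = 3, duration_s = 30, seed = 17)
  recs <- generate_dataset(cfg)
  for (fold in loso_folds(recs)) {
    splits <- prepare_fold(fold, 32)
    train_sig <- vapply(seq_len(dim(splits$train$windows)[1]), function(i) {
      window_signature(splits$train$windows[i, , ])
    }, character(1))
    test_sig <- vapply(seq_len(dim(splits$test$windows)[1]), function(i) {
      window_signature(splits$test$windows[i, , ])
    }, character(1))
    expect_length(intersect(train_sig, test_sig), 0)
    expect_false(fold$test_subject %in% splits$train$subject_ids)
  }
})

test_that("chunk folds are contiguous, disjoint, near-equal and seeded", {
  cfg <- generator_config(n_subjects = 1, duration_s = 40, seed = 18)
  rec <- generate_recording(cfg, "S01") # T = 2000
  folds <- chunk_folds(rec, n_chunks = 10, window_length = 32, seed = 4)
  expect_length(folds, 10)
  lens <- vapply(folds, function(f) nrow(f$test[[1]]$values), integer(1))
  expect_equal(sum(lens), 2000)
  expect_lte(max(lens) - min(lens), 1)
  # chunks are contiguous slices: values match the original at their offsets
  test_ids <- vapply(folds, function(f) f$test_subject, character(1))
  expect_length(unique(test_ids), 10)
  folds2 <- chunk_folds(rec, n_chunks = 10, window_length = 32, seed = 4)
  expect_identical(vapply(folds2, function(f) f$test_subject, character(1)),
                   test_ids)
  # coverage: concatenating chunks in index order rebuilds the recording
  ord <- order(test_ids)
  rebuilt <- do.call(rbind, lapply(folds[ord], function(f) f$test[[1]]$values))
  expect_equal(unname(rebuilt), unname(rec$values))
  expect_error(chunk_folds(rec, n_chunks = 10, window_length = 300),
               class = "glula_data_error")
})

test_that("the timing harness times exactly reps passes and reports op counts", {
  model <- build_model(tiny_model_config())
  bench <- benchmark_inference(model, reps = 5, warmup = 2)
  expect_length(bench$timings_ms, 5)
  expect_equal(bench$reps, 5)
  expect_equal(bench$mean_ms, mean(bench$timings_ms))
  expect_true(all(c("linear_attention", "softmax_attention") %in%
                    names(bench$op_counts)))
  # softmax/linear op ratio grows with N while parameters stay equal
  ratio <- function(n) {
    op_count("softmax_attention", n, 16, 2) /
      op_count("linear_attention", n, 16, 2)
  }
  expect_gt(ratio(512), ratio(64))
})
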