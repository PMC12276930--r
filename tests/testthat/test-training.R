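# Splits, training loop behaviour, transfer-learning plumbing.

# synthetic frame table: 3 bouts x n frames, all stance, for split tests
fake_dataset <- function(n_per_bout = c(24000L, 24000L, 24000L),
                         centers = c(70, 100, 130), cohort = "clinical") {
  meta <- do.call(rbind, lapply(seq_along(n_per_bout), function(b) {
    data.frame(time = seq_len(n_per_bout[b]) / 100, stance = TRUE,
               stride_id = b * 1000L + seq_len(n_per_bout[b]) %/% 70L,
               frame_idx = seq_len(n_per_bout[b]),
               target = 0, bout_id = b, bout_center = centers[b],
               n_frames_bout = n_per_bout[b])
  }))
  subj <- if (cohort == "clinical") clin_subject() else
    subject_spec("h", 70, 1.0, "healthy")
  structure(list(meta = meta, maps = NULL, cop = NULL, imu = NULL,
                 side = "left", subject = subj, config = preproc_config()),
            class = "gait_dataset")
}

test_that("by-bout split sends the bouts nearest CWS to validation and test", {
  ds <- fake_dataset(rep(1000L, 5), centers = c(70, 90, 100, 110, 130))
  sp <- split_by_bout(ds)
  # CWS bout (100 %CWS) is validation; 90 vs 110 tie -> earlier bout tests
  expect_equal(unique(ds$meta$bout_id[sp$val]), 3L)
  expect_equal(unique(ds$meta$bout_id[sp$test]), 2L)
  expect_setequal(unique(ds$meta$bout_id[sp$train]), c(1L, 4L, 5L))
  # partition: every frame exactly once
  all_rows <- sort(c(sp$train, sp$val, sp$test))
  expect_equal(all_rows, seq_len(nrow(ds$meta)))
  # 3 bouts leave exactly one training bout; fewer error out
  ds3b <- fake_dataset()
  sp3 <- split_by_bout(ds3b)
  expect_equal(length(unique(ds3b$meta$bout_id[sp3$train])), 1L)
  ds2 <- fake_dataset(rep(100L, 2), centers = c(90, 110))
  expect_error(split_by_bout(ds2), "3 bouts")
})

test_that("ratio splits produce the protocol frame counts and partition", {
  ds <- fake_dataset(24000L, centers = 100)
  sp <- split_by_ratio(ds, 0.15, "forward")
  expect_equal(length(sp$train), 3600L)
  expect_equal(length(sp$val), 2400L)
  expect_equal(length(sp$test), 18000L)
  # forward vs reverse training windows are disjoint at f = 0.15
  spr <- split_by_ratio(ds, 0.15, "reverse")
  expect_length(intersect(sp$train, spr$train), 0L)
  # reverse: training is the bout tail
  expect_equal(min(ds$meta$frame_idx[spr$train]), 24000L - 3600L + 1L)
  # partition for every fraction and direction
  ds3 <- fake_dataset(c(5000L, 4000L, 6000L))
  for (f in c(0.15, 0.30, 0.45, 0.60)) for (dir in c("forward", "reverse")) {
    s <- split_by_ratio(ds3, f, dir)
    expect_equal(sort(c(s$train, s$val, s$test)), seq_len(nrow(ds3$meta)),
                 label = paste(f, dir))
  }
  expect_error(split_by_ratio(ds, 0.95), "below 1")
})

test_that("training is seed-deterministic and selection rules work", {
  ds <- fx_dataset("left")
  sp <- split_by_bout(ds)
  spec <- model_spec("imu_only", lstm_hidden = 8L, lstm_layers = 1L,
                     lstm_fc = c(16L), cnn_fc = 8L, penultimate = 4L)
  cfg <- train_config(epochs = 3L, lr = 2e-3, batch_size = 256L,
                      decim = 16L, seed = 44)
  t1 <- train_model(ds, sp, spec, cfg)
  t2 <- train_model(ds, sp, spec, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$model$params, t2$model$params)
  expect_equal(nrow(t1$history), 3L)
  expect_true(all(is.finite(t1$history$val_mse)))
  # best-validation weights are the ones kept
  best_ep <- which.min(t1$history$val_mse)
  cfg_last <- cfg; cfg_last$selection <- "last"
  t3 <- train_model(ds, sp, spec, cfg_last)
  if (best_ep != nrow(t1$history)) {
    expect_false(identical(t1$model$params, t3$model$params))
  }
  expect_identical(t1$history, t3$history)
})

test_that("zero targets drive predictions to zero", {
  ds <- fx_dataset("left")
  ds$meta$target <- 0
  sp <- split_by_bout(ds)
  spec <- model_spec("imu_only", lstm_hidden = 6L, lstm_layers = 1L,
                     lstm_fc = c(8L), cnn_fc = 8L, penultimate = 4L)
  cfg <- train_config(epochs = 25L, lr = 5e-3, decim = 4L, seed = 2)
  tr <- train_model(ds, sp, spec, cfg)
  preds <- predict_grf(tr, ds, sp$test[seq(1, length(sp$test), 16)])
  expect_lt(mean(preds^2), 1e-4)
})

test_that("a briefly trained fusion model beats the climatology baseline", {
  rep1 <- fx_study_seed(1)
  r <- rep1$reports$left_fusion
  # R^2 > 0 is exactly "beats the mean predictor"; require a wide margin
  expect_gt(r$r2, 0.9)
  expect_lt(r$rmse, 1.0)
})

test_that("pooled pre-training stacks healthy training frames and is seeded", {
  h1 <- subject_spec("h1", 70, 1.0, "healthy")
  h2 <- subject_spec("h2", 80, 1.1, "healthy")
  d1 <- memo("healthy1", build_dataset(simulate_session(h1, seed = 51,
                                                        n_bouts = 3L,
                                                        duration_scale = 0.1), "left"))
  d2 <- memo("healthy2", build_dataset(simulate_session(h2, seed = 52,
                                                        n_bouts = 3L,
                                                        duration_scale = 0.1), "left"))
  s1 <- split_by_bout(d1); s2 <- split_by_bout(d2)
  pooled <- gaitfuse:::pool_datasets(list(d1, d2), list(s1, s2))
  expect_equal(length(pooled$split$train),
               length(s1$train) + length(s2$train))
  expect_equal(nrow(pooled$dataset$meta), nrow(d1$meta) + nrow(d2$meta))
  expect_error(pretrain_pooled(list(d1), list(s1), model_spec("fusion")),
               ">= 2")
})

test_that("fine-tuning consumes the requested fraction and keeps the test set", {
  ds <- fx_dataset("left")
  sp <- split_by_bout(ds)
  rows_all <- gaitfuse:::tune_fraction_rows(ds$meta, sp, 1.0)
  expect_setequal(rows_all, c(sp$train, sp$val))
  rows_half <- gaitfuse:::tune_fraction_rows(ds$meta, sp, 0.5)
  expect_lt(abs(length(rows_half) - length(rows_all) / 2), 3)
  # the half set is the LATER half of each bout's frames
  for (b in unique(ds$meta$bout_id[rows_half])) {
    rb_all <- rows_all[ds$meta$bout_id[rows_all] == b]
    rb_half <- rows_half[ds$meta$bout_id[rows_half] == b]
    expect_gte(min(ds$meta$frame_idx[rb_half]),
               stats::median(ds$meta$frame_idx[rb_all]) - 1)
  }
})
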