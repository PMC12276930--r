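#' Training configuration
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay folded into the gradient.
#' @param batch_size minibatch size.
#' @param selection `"best_val"` (weights with the lowest validation loss)
#'   or `"last"` (final-epoch weights, used for pooled pre-training).
#' @param decim keep every `decim`-th training frame (1 = all). Validation
#'   frames are thinned the same way; test data never are.
#' @param seed seed for init, shuffling and any stochastic layer.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 500L, lr = 5e-4, weight_decay = 1e-5,
                         batch_size = 256L, selection = c("best_val", "last"),
                         decim = 1L, seed = 1L) {
  selection <- match.arg(selection)
  assert_that(epochs > 0, "epochs must be > 0")
  assert_that(lr > 0, "lr must be > 0")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), selection = selection,
                 decim = as.integer(decim), seed = as.integer(seed)),
            class = "train_config")
}

#' Training presets
#'
#' `"paper"` is the full-scale recipe (Adam, lr 5e-4, weight decay 1e-5,
#' 500 epochs, full-width architecture). `"desk"` is the reduced profile
#' used throughout this package's experiments and acceptance runs: the same
#' architecture family at reduced width (32 hidden LSTM features in 2
#' bidirectional layers, 4/8 convolution channels), fewer epochs with a
#' proportionally larger learning rate, and 4x thinning of training frames.
#' The desk profile exists so that multi-seed experiments complete in CPU
#' minutes; it is a documented configuration preset, not a change to the
#' defaults.
#'
#' @param name `"paper"` or `"desk"`.
#' @param mode passed to [model_spec()].
#' @param seed training seed.
#' @return list(spec, config).
#' @export
train_preset <- function(name = c("desk", "paper"),
                         mode = c("fusion", "imu_only", "insole_only"),
                         seed = 1L) {
  name <- match.arg(name)
  mode <- match.arg(mode)
  if (name == "paper") {
    list(spec = model_spec(mode),
         config = train_config(epochs = 500L, lr = 5e-4, seed = seed))
  } else {
    list(spec = model_spec(mode, conv_channels = c(4L, 8L),
                           lstm_hidden = 32L, lstm_layers = 2L,
                           lstm_fc = c(64L, 84L)),
         config = train_config(epochs = 30L, lr = 2e-3, decim = 4L,
                               batch_size = 128L, seed = seed))
  }
}

#' Split a dataset by walking bout
#'
#' The two bouts whose center speeds are closest to the subject's
#' comfortable walking speed become validation and test (the nearer bout is
#' validation; ties go to the earlier bout); all remaining bouts are
#' training data.
#'
#' @param dataset a [build_dataset()] result.
#' @return list(train, val, test) of row indices into `dataset$meta`.
#' @export
split_by_bout <- function(dataset) {
  meta <- dataset$meta
  bouts <- unique(meta[, c("bout_id", "bout_center")])
  assert_that(nrow(bouts) >= 3, "by-bout split needs at least 3 bouts, got %d",
              nrow(bouts))
  cws <- dataset$subject$cws
  v2 <- if (dataset$subject$cohort == "clinical") bouts$bout_center / 100 * cws
        else bouts$bout_center
  d <- abs(v2 - cws)
  ord <- order(d, bouts$bout_id)  # ties broken by earlier bout
  val_bout <- bouts$bout_id[ord[1]]
  test_bout <- bouts$bout_id[ord[2]]
  list(train = which(!meta$bout_id %in% c(val_bout, test_bout)),
       val = which(meta$bout_id == val_bout),
       test = which(meta$bout_id == test_bout))
}

#' Split a dataset by within-bout time ratio
#'
#' Forward: the first `fraction` of each bout's timeline is training, the
#' next 10 % validation, the remainder test. Reverse: the last `fraction`
#' is training, the 10 % immediately before it validation, the remainder
#' (the bout start) test. Fractions refer to the bout's full 100 Hz
#' timeline, so a stance-only dataset keeps its frames' original positions.
#'
#' @param dataset a [build_dataset()] result.
#' @param fraction training fraction, one of 0.15, 0.30, 0.45, 0.60
#'   (other values in (0, 0.9) are allowed but off-protocol).
#' @param direction `"forward"` or `"reverse"`.
#' @param val_fraction validation fraction (default 0.10).
#' @return list(train, val, test) of row indices into `dataset$meta`.
#' @export
split_by_ratio <- function(dataset, fraction = 0.15,
                           direction = c("forward", "reverse"),
                           val_fraction = 0.10) {
  direction <- match.arg(direction)
  assert_that(fraction > 0 && fraction + val_fraction < 1,
              "fraction + val_fraction must stay below 1")
  meta <- dataset$meta
  lab <- rep(NA_character_, nrow(meta))
  for (b in unique(meta$bout_id)) {
    rows <- which(meta$bout_id == b)
    n <- meta$n_frames_bout[rows[1]]
    n_tr <- round(fraction * n); n_va <- round(val_fraction * n)
    assert_that(n_tr >= 1 && n_va >= 1, "bout %d too short for the split", b)
    fi <- meta$frame_idx[rows]
    if (direction == "forward") {
      lab[rows[fi <= n_tr]] <- "train"
      lab[rows[fi > n_tr & fi <= n_tr + n_va]] <- "val"
      lab[rows[fi > n_tr + n_va]] <- "test"
    } else {
      lab[rows[fi > n - n_tr]] <- "train"
      lab[rows[fi > n - n_tr - n_va & fi <= n - n_tr]] <- "val"
      lab[rows[fi <= n - n_tr - n_va]] <- "test"
    }
  }
  list(train = which(lab == "train"), val = which(lab == "val"),
       test = which(lab == "test"))
}

# normalized feature arrays + sequence index for a dataset
prep_arrays <- function(dataset, norm = NULL, train_rows = NULL) {
  feat <- cbind(dataset$imu, dataset$cop)
  if (is.null(norm)) {
    assert_that(!is.null(train_rows), "need train_rows to fit normalization")
    norm <- list(
      maps = fit_minmax(dataset$maps[train_rows, , drop = FALSE],
                        list(map = seq_len(ncol(dataset$maps)))),
      feat = fit_minmax(feat[train_rows, , drop = FALSE], feature_groups())
    )
  }
  seg <- dataset$meta$stride_id
  seg[is.na(seg)] <- -1L
  list(maps = apply_minmax(dataset$maps, norm$maps),
       feat = apply_minmax(feat, norm$feat),
       target = dataset$meta$target,
       seqidx = make_sequences(seg),
       norm = norm)
}

seq_cols <- function(mode) {
  switch(mode, fusion = 1:23, imu_only = 1:21, insole_only = 22:23)
}

# assemble one batch for the given dataset rows
gather_batch <- function(arr, rows, mode, L) {
  cols <- seq_cols(mode)
  seq <- vector("list", L)
  for (t in seq_len(L)) {
    seq[[t]] <- arr$feat[arr$seqidx[rows, t], cols, drop = FALSE]
  }
  b <- list(seq = seq)
  if (uses_cnn(mode)) b$map <- arr$maps[rows, , drop = FALSE]
  b
}

# mean squared error of the model over rows, evaluated in chunks
eval_mse <- function(model, arr, rows, chunk = 2048L) {
  if (!length(rows)) return(NA_real_)
  tot <- 0
  for (i in seq(1, length(rows), by = chunk)) {
    r <- rows[i:min(i + chunk - 1L, length(rows))]
    b <- gather_batch(arr, r, model$spec$mode, model$spec$sequence_len)
    yh <- model_forward(model, b)
    tot <- tot + sum((yh - arr$target[r])^2)
  }
  tot / length(rows)
}

#' Train an estimator on a split dataset
#'
#' Minimises mean squared error on the training frames with Adam, logging
#' per-epoch training and validation losses, and returns either the
#' best-validation or the last-epoch weights. Normalization constants are
#' fitted on the training rows only and stored with the model. The whole
#' run is deterministic given the config seed.
#'
#' @param dataset a [build_dataset()] result.
#' @param split list(train, val, test) row indices (see [split_by_bout()]).
#' @param spec a [model_spec()].
#' @param config a [train_config()].
#' @param init_params optional parameter list to start from (transfer
#'   learning); must match `spec`.
#' @param norm optional pre-fitted normalization (transfer learning).
#' @return list of class `gf_trained`: `model`, `norm`, `history`
#'   (data.frame epoch/train_mse/val_mse), `split`, `config`.
#' @export
train_model <- function(dataset, split, spec, config = train_config(),
                        init_params = NULL, norm = NULL) {
  arr <- prep_arrays(dataset, norm = norm, train_rows = split$train)
  model <- build_model(spec, seed = config$seed)
  if (!is.null(init_params)) {
    assert_that(identical(lapply(model$params, dim), lapply(init_params, dim)),
                "init_params do not match the model spec")
    model$params <- init_params
  }
  tr_rows <- split$train
  va_rows <- split$val
  if (config$decim > 1L) {
    tr_rows <- tr_rows[seq(1, length(tr_rows), by = config$decim)]
    va_rows <- va_rows[seq(1, length(va_rows), by = config$decim)]
  }
  assert_that(length(tr_rows) >= config$batch_size / 8,
              "too few training frames (%d)", length(tr_rows))
  state <- adam_init(model$params)
  hist <- data.frame(epoch = seq_len(config$epochs), train_mse = NA_real_,
                     val_mse = NA_real_)
  best <- list(val = Inf, params = model$params)
  L <- spec$sequence_len
  with_seed(sub_seed(config$seed, paste0("train_", spec$mode)), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_rows)
      ep_loss <- 0; nseen <- 0L
      for (i in seq(1, length(ord), by = config$batch_size)) {
        rows <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        b <- gather_batch(arr, rows, spec$mode, L)
        fw <- model_forward(model, b, keep_cache = TRUE)
        err <- fw$yhat - arr$target[rows]
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop_gf("NaN/Inf loss at epoch %d (mode %s, lr %g); aborting",
                  ep, spec$mode, config$lr)
        }
        gr <- model_backward(model, fw$cache, 2 * err / length(err))
        upd <- adam_step(model$params, gr, state, config$lr, config$weight_decay)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss * length(rows); nseen <- nseen + length(rows)
      }
      hist$train_mse[ep] <- ep_loss / nseen
      if (length(va_rows)) {
        hist$val_mse[ep] <- eval_mse(model, arr, va_rows)
        if (is.finite(hist$val_mse[ep]) && hist$val_mse[ep] < best$val) {
          best$val <- hist$val_mse[ep]
          best$params <- model$params
        }
      }
    }
  })
  if (config$selection == "best_val" && is.finite(best$val)) {
    model$params <- best$params
  }
  structure(list(model = model, norm = arr$norm, history = hist,
                 split = split, config = config),
            class = "gf_trained")
}

#' Predict AP GRF for dataset rows with a trained model
#'
#' @param trained a `gf_trained`.
#' @param dataset the dataset to predict on (same preprocessing layout).
#' @param rows row indices (default: all rows).
#' @return numeric vector of AP GRF estimates (%BW).
#' @export
predict_grf <- function(trained, dataset, rows = NULL) {
  arr <- prep_arrays(dataset, norm = trained$norm)
  if (is.null(rows)) rows <- seq_len(nrow(dataset$meta))
  out <- numeric(length(rows))
  chunk <- 2048L
  for (i in seq(1, length(rows), by = chunk)) {
    r <- rows[i:min(i + chunk - 1L, length(rows))]
    b <- gather_batch(arr, r, trained$model$spec$mode,
                      trained$model$spec$sequence_len)
    out[i:(i + length(r) - 1L)] <- model_forward(trained$model, b)
  }
  out
}

#' Pre-train one model on pooled healthy datasets
#'
#' Concatenates the training frames of two or more healthy datasets (each
#' with its own split), fits normalization on the pooled training frames,
#' and trains a single model, returning the last-epoch weights.
#'
#' @param datasets list of [build_dataset()] results (healthy subjects).
#' @param splits list of splits matching `datasets`.
#' @param spec a [model_spec()].
#' @param config a [train_config()]; its `selection` is forced to
#'   `"last"`.
#' @return a `gf_trained` whose `norm` is the pooled-healthy constants.
#' @export
pretrain_pooled <- function(datasets, splits, spec, config = train_config()) {
  assert_that(length(datasets) >= 2, "pre-training needs >= 2 healthy datasets")
  for (d in datasets) {
    assert_that(ncol(d$imu) == ncol(datasets[[1]]$imu),
                "incompatible channel inventories across datasets")
  }
  pooled <- pool_datasets(datasets, splits)
  config$selection <- "last"
  train_model(pooled$dataset, pooled$split, spec, config)
}

# stack datasets row-wise, keeping split roles; bout ids offset per source
pool_datasets <- function(datasets, splits) {
  metas <- list(); maps <- list(); cops <- list(); imus <- list()
  tr <- integer(0); va <- integer(0); te <- integer(0)
  row0 <- 0L; bout0 <- 0L; stride0 <- 0L
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]; s <- splits[[i]]
    m <- d$meta
    m$bout_id <- m$bout_id + bout0
    m$stride_id <- m$stride_id + stride0
    bout0 <- max(m$bout_id)
    stride0 <- max(m$stride_id, na.rm = TRUE)
    metas[[i]] <- m; maps[[i]] <- d$maps; cops[[i]] <- d$cop; imus[[i]] <- d$imu
    tr <- c(tr, s$train + row0); va <- c(va, s$val + row0); te <- c(te, s$test + row0)
    row0 <- row0 + nrow(m)
  }
  dataset <- structure(list(meta = do.call(rbind, metas),
                            maps = do.call(rbind, maps),
                            cop = do.call(rbind, cops),
                            imu = do.call(rbind, imus),
                            side = datasets[[1]]$side,
                            subject = datasets[[1]]$subject,
                            config = datasets[[1]]$config),
                       class = "gait_dataset")
  list(dataset = dataset, split = list(train = tr, val = va, test = te))
}

#' Fine-tune pre-trained weights on a clinical dataset
#'
#' Initialises from pre-trained weights (keeping the pooled normalization
#' constants so inputs stay on the pre-training scale) and continues
#' training on the clinical subject's training + validation frames — all
#' of them (`fraction = 1`) or the later half of each bout's portion
#' (`fraction = 0.5`). Model selection uses the clinical validation
#' frames; the test set is untouched.
#'
#' @param pretrained a `gf_trained` from [pretrain_pooled()].
#' @param dataset the clinical [build_dataset()] (paretic side).
#' @param split the clinical split (test set preserved).
#' @param config a [train_config()].
#' @param fraction 1.0 or 0.5 (fraction of train+val frames used).
#' @return a `gf_trained`.
#' @export
finetune <- function(pretrained, dataset, split, config = train_config(),
                     fraction = 1.0) {
  assert_that(fraction %in% c(0.5, 1.0), "fraction must be 0.5 or 1.0")
  tune_rows <- tune_fraction_rows(dataset$meta, split, fraction)
  ft_split <- list(train = tune_rows, val = split$val, test = split$test)
  train_model(dataset, ft_split, pretrained$model$spec, config,
              init_params = pretrained$model$params, norm = pretrained$norm)
}

# later-`fraction` part (by time, per bout) of the train+val frames
tune_fraction_rows <- function(meta, split, fraction) {
  rows <- sort(c(split$train, split$val))
  if (fraction >= 1) return(rows)
  keep <- integer(0)
  for (b in unique(meta$bout_id[rows])) {
    rb <- rows[meta$bout_id[rows] == b]
    rb <- rb[order(meta$frame_idx[rb])]
    n <- length(rb)
    if (n) keep <- c(keep, rb[(n - floor(fraction * n) + 1L):n])
  }
  sort(keep)
}
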