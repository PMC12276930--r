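# Experiment orchestration: the three-model comparison, the data-budget
# grid and the transfer-learning study, each as a reproducible seeded run.

#' Default desk-scale run configuration
#'
#' Bundles the choices shared by the experiment drivers: a clinical virtual
#' subject (85 kg, CWS 0.8 m/s, left-paretic, impairment 0.35), a 4-bout
#' protocol session, the preprocessing defaults and the desk training
#' preset. `duration_scale` controls the simulated bout length.
#'
#' @param seed master seed.
#' @param duration_scale bout-length scale (1 = full protocol bouts).
#' @param preset `"desk"` or `"paper"` training preset.
#' @param n_bouts bouts per session.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, duration_scale = 0.25, preset = "desk",
                       n_bouts = 4L) {
  structure(list(seed = as.integer(seed), duration_scale = duration_scale,
                 preset = preset, n_bouts = as.integer(n_bouts),
                 subject = subject_spec("virtual-clinical", 85, 0.8,
                                        "clinical", "left", 0.35),
                 preproc = preproc_config()),
            class = "run_config")
}

# simulate + preprocess one side of a fresh session for a run seed
prep_side <- function(config, seed, side) {
  ses <- simulate_session(config$subject, seed = seed,
                          n_bouts = config$n_bouts,
                          duration_scale = config$duration_scale)
  build_dataset(ses, side, config$preproc)
}

#' Train and evaluate the three input configurations on one session
#'
#' Trains the Insole-only, IMU-only and IMU+Insole models on identical
#' splits, seeds and training budgets, and evaluates each on the held-out
#' bout of the paretic side.
#'
#' @param config a [run_config()].
#' @param modes subset of the three modes.
#' @param dataset optional pre-built dataset (else simulated from
#'   `config`).
#' @return list with `reports` (per-mode [evaluate_model()] results) and
#'   `rmse` (named stance-RMSE vector).
#' @export
run_comparison <- function(config = run_config(),
                           modes = c("fusion", "imu_only", "insole_only"),
                           dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- prep_side(config, config$seed, config$subject$paretic_side)
  }
  split <- split_by_bout(dataset)
  reports <- list()
  for (mode in modes) {
    pre <- train_preset(config$preset, mode, seed = config$seed)
    tr <- train_model(dataset, split, pre$spec, pre$config)
    reports[[mode]] <- evaluate_model(tr, dataset, split)
  }
  list(reports = reports,
       rmse = vapply(reports, `[[`, numeric(1), "rmse"),
       seed = config$seed)
}

#' Data-budget grid: training fraction x split direction x mode
#'
#' Reproduces the reduced-training-data experiment: for each training
#' fraction and each split direction (forward = bout starts, mostly
#' constant speed; reverse = bout ends, including the speed ramps) a model
#' is trained per requested mode and evaluated on that split's test
#' frames.
#'
#' @param config a [run_config()].
#' @param fractions training fractions.
#' @param directions split directions.
#' @param modes model modes.
#' @param dataset optional pre-built dataset.
#' @return data.frame with one row per grid cell: fraction, direction,
#'   mode, stance rmse, nrmse, r2, seed.
#' @export
run_data_budget <- function(config = run_config(),
                            fractions = c(0.15, 0.30, 0.45, 0.60),
                            directions = c("forward", "reverse"),
                            modes = "fusion",
                            dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- prep_side(config, config$seed, config$subject$paretic_side)
  }
  grid <- expand.grid(fraction = fractions, direction = directions,
                      mode = modes, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    split <- split_by_ratio(dataset, g$fraction, g$direction)
    pre <- train_preset(config$preset, g$mode, seed = config$seed)
    tr <- train_model(dataset, split, pre$spec, pre$config)
    rep <- evaluate_model(tr, dataset, split)
    out[[i]] <- data.frame(fraction = g$fraction, direction = g$direction,
                           mode = g$mode, rmse = rep$rmse, nrmse = rep$nrmse,
                           r2 = rep$r2, seed = config$seed)
  }
  do.call(rbind, out)
}

#' Transfer-learning study: pre-train on healthy, fine-tune on clinical
#'
#' Pre-trains the fusion architecture on pooled healthy sessions, then for
#' each requested data fraction compares a fine-tuned model against a
#' from-scratch model trained on the same (possibly reduced) clinical
#' tuning frames. The clinical test set is identical across all arms.
#'
#' @param config a [run_config()].
#' @param n_healthy number of healthy virtual subjects.
#' @param fractions tuning-data fractions (subset of c(0.5, 1.0)).
#' @param healthy_scale bout-length scale for the healthy sessions.
#' @param pretrained optional pre-computed [pretrain_pooled()] result to
#'   reuse across seeds.
#' @return list with `arms` data.frame (fraction, arm, rmse) and
#'   `pretrained` for reuse.
#' @export
run_transfer <- function(config = run_config(), n_healthy = 2L,
                         fractions = c(0.5, 1.0), healthy_scale = 0.1,
                         pretrained = NULL) {
  pre <- train_preset(config$preset, "fusion", seed = config$seed)
  if (is.null(pretrained)) {
    hsets <- list(); hsplits <- list()
    for (i in seq_len(n_healthy)) {
      hs <- subject_spec(paste0("virtual-healthy-", i), 60 + 10 * i,
                         0.9 + 0.1 * i, "healthy")
      ses <- simulate_session(hs, seed = sub_seed(config$seed, paste0("healthy", i)),
                              n_bouts = 3L, duration_scale = healthy_scale)
      hsets[[i]] <- build_dataset(ses, "left", config$preproc)
      hsplits[[i]] <- split_by_bout(hsets[[i]])
    }
    pcfg <- pre$config
    pcfg$epochs <- 2L * pcfg$epochs  # pre-training runs twice the epochs
    pretrained <- pretrain_pooled(hsets, hsplits, pre$spec, pcfg)
  }
  dataset <- prep_side(config, config$seed, config$subject$paretic_side)
  split <- split_by_bout(dataset)
  arms <- list()
  for (f in fractions) {
    ft <- finetune(pretrained, dataset, split, pre$config, fraction = f)
    rep_ft <- evaluate_model(ft, dataset, split)
    tune_rows <- tune_fraction_rows(dataset$meta, split, f)
    sc_split <- list(train = tune_rows, val = split$val, test = split$test)
    sc <- train_model(dataset, sc_split, pre$spec, pre$config)
    rep_sc <- evaluate_model(sc, dataset, split)
    arms[[length(arms) + 1L]] <- data.frame(
      fraction = f, arm = c("finetuned", "scratch"),
      rmse = c(rep_ft$rmse, rep_sc$rmse), seed = config$seed)
  }
  list(arms = do.call(rbind, arms), pretrained = pretrained)
}
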