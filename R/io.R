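# Disk persistence. Sessions and aligned datasets are written as plain
# CSV + JSON directories (one folder per artifact), so every stream stays
# inspectable with standard tools; trained models are saved as RDS
# checkpoints carrying their spec and normalization constants.

#' Write a simulated session to a directory
#'
#' Layout: `meta.json` (subject, seed, clock offsets, bout plan) plus, per
#' bout and side, `bout<k>_<side>_{plate,insole,imu,events}.csv`.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(subject = unclass(session$subject), seed = session$seed,
               clock_offsets = session$clock_offsets,
               duration_scale = session$duration_scale,
               span = session$span,
               bout_plan = session$bout_plan)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (b in session$bouts) {
    for (sd in c("left", "right")) {
      st <- b$sides[[sd]]
      pfx <- file.path(dir, sprintf("bout%d_%s_", b$bout_id, sd))
      data.table::fwrite(data.frame(t = st$plate$t, ap = st$plate$ap,
                                    v = st$plate$v),
                         paste0(pfx, "plate.csv"))
      ins <- data.frame(t = st$insole$t, cop_row = st$insole$cop[, 1],
                        cop_col = st$insole$cop[, 2])
      pr <- as.data.frame(st$insole$pressure)
      names(pr) <- sprintf("s%03d", seq_len(ncol(pr)))
      data.table::fwrite(cbind(ins, pr), paste0(pfx, "insole.csv"))
      imu <- data.frame(t = st$imu$t)
      data.table::fwrite(cbind(imu, as.data.frame(st$imu$channels)),
                         paste0(pfx, "imu.csv"))
      data.table::fwrite(st$events, paste0(pfx, "events.csv"))
    }
  }
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory.
#' @return a `gait_session` (profiles reconstructed from the bout plan;
#'   stream clock offsets restored from the metadata).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  subj <- subject_spec(meta$subject$subject_id, meta$subject$bodyweight,
                       meta$subject$cws, meta$subject$cohort,
                       meta$subject$paretic_side, meta$subject$impairment,
                       as.list(meta$subject$noise_levels))
  plan <- as.data.frame(meta$bout_plan)
  bouts <- vector("list", nrow(plan))
  t_offset <- 0
  for (k in seq_len(nrow(plan))) {
    prof <- make_speed_profile(subj$cohort, subj$cws, plan$center[k],
                               a1_sign = plan$a1_sign[k],
                               duration_scale = meta$duration_scale)
    sides <- list()
    for (sd in c("left", "right")) {
      pfx <- file.path(dir, sprintf("bout%d_%s_", k, sd))
      pl <- data.table::fread(paste0(pfx, "plate.csv"), data.table = FALSE)
      ins <- data.table::fread(paste0(pfx, "insole.csv"), data.table = FALSE)
      imu <- data.table::fread(paste0(pfx, "imu.csv"), data.table = FALSE)
      ev <- data.table::fread(paste0(pfx, "events.csv"), data.table = FALSE)
      pcols <- grep("^s\\d+$", names(ins))
      sides[[sd]] <- list(
        plate = structure(list(t = pl$t, ap = pl$ap, v = pl$v, side = sd,
                               fs = 2000), class = "plate_stream"),
        events = ev,
        insole = structure(list(t = ins$t,
                                pressure = as.matrix(ins[, pcols]),
                                cop = as.matrix(ins[, c("cop_row", "cop_col")]),
                                side = sd, fs = 50,
                                clock_offset = meta$clock_offsets$insole),
                           class = "insole_stream"),
        imu = structure(list(t = imu$t,
                             channels = as.matrix(imu[, imu_channels()]),
                             side = sd, fs = 100,
                             clock_offset = meta$clock_offsets$imu),
                        class = "imu_stream"))
    }
    bouts[[k]] <- list(bout_id = k, center = plan$center[k],
                       a1_sign = plan$a1_sign[k], t_offset = t_offset,
                       profile = prof, sides = sides)
    t_offset <- t_offset + prof$t4
  }
  structure(list(subject = subj, seed = meta$seed,
                 clock_offsets = meta$clock_offsets,
                 duration_scale = meta$duration_scale, bout_plan = plan,
                 bout_plan_input = plan, bouts = bouts, span = t_offset),
            class = "gait_session")
}

#' Save or load a trained model checkpoint
#'
#' Checkpoints carry the architecture spec, weights, normalization
#' constants and training history; loading verifies the stored spec hash
#' so weights are never applied to a mismatched architecture.
#'
#' @param trained a `gf_trained`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` (save) / the `gf_trained` (load).
#' @export
save_checkpoint <- function(trained, path) {
  stopifnot(inherits(trained, "gf_trained"))
  obj <- list(spec = trained$model$spec, params = trained$model$params,
              norm = trained$norm, history = trained$history,
              config = trained$config,
              spec_hash = spec_hash(trained$model$spec))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  assert_that(identical(spec_hash(obj$spec), obj$spec_hash),
              "checkpoint spec hash mismatch: file corrupted or edited")
  model <- build_model(obj$spec, seed = 1L)
  assert_that(identical(lapply(model$params, dim), lapply(obj$params, dim)),
              "checkpoint weights do not match the stored spec")
  model$params <- obj$params
  structure(list(model = model, norm = obj$norm, history = obj$history,
                 split = NULL, config = obj$config),
            class = "gf_trained")
}

# order-stable hash of a model spec
spec_hash <- function(spec) {
  s <- unclass(spec)
  paste(names(s), vapply(s, function(v) paste(v, collapse = ","), ""),
        sep = "=", collapse = ";")
}

#' Write an aligned dataset to a directory
#'
#' `frames.csv` holds the per-frame metadata, targets, CoP and IMU
#' channels; `maps.csv` the 784-column pressure maps; `meta.json` the
#' subject and preprocessing configuration.
#'
#' @param dataset a [build_dataset()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fr <- cbind(dataset$meta,
              stats::setNames(as.data.frame(dataset$cop), c("cop_row", "cop_col")),
              as.data.frame(dataset$imu))
  data.table::fwrite(fr, file.path(dir, "frames.csv"))
  data.table::fwrite(as.data.frame(dataset$maps), file.path(dir, "maps.csv"))
  jsonlite::write_json(list(side = dataset$side,
                            subject = unclass(dataset$subject),
                            config = unclass(dataset$config),
                            session_seed = dataset$session_seed),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `gait_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  fr <- data.table::fread(file.path(dir, "frames.csv"), data.table = FALSE)
  maps <- as.matrix(data.table::fread(file.path(dir, "maps.csv"),
                                      data.table = FALSE))
  metacols <- c("time", "stance", "stride_id", "frame_idx", "target",
                "bout_id", "bout_center", "n_frames_bout")
  subj <- subject_spec(meta$subject$subject_id, meta$subject$bodyweight,
                       meta$subject$cws, meta$subject$cohort,
                       meta$subject$paretic_side, meta$subject$impairment,
                       as.list(meta$subject$noise_levels))
  cfg <- do.call(preproc_config,
                 meta$config[names(meta$config) %in% names(formals(preproc_config))])
  structure(list(meta = fr[, metacols],
                 maps = maps,
                 cop = as.matrix(fr[, c("cop_row", "cop_col")]),
                 imu = as.matrix(fr[, imu_channels()]),
                 side = meta$side, subject = subj, config = cfg,
                 session_seed = meta$session_seed),
            class = "gait_dataset")
}
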