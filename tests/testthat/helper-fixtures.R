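# Shared fixtures, memoised so expensive simulations and trainings are
# computed once per test run regardless of which file asks first.

# the cache must survive helper re-sourcing between test files
.fx <- local({
  if (!exists(".gf_test_cache", envir = globalenv(), inherits = FALSE)) {
    assign(".gf_test_cache", new.env(parent = emptyenv()), envir = globalenv())
  }
  get(".gf_test_cache", envir = globalenv())
})

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

clin_subject <- function(noise = list()) {
  subject_spec("fx-clin", 85, 0.8, "clinical", "left", 0.35, noise)
}

quiet_noise <- function() {
  list(fp = 0, insole = 0, insole_offset = c(0, 0),
       imu_acc = 0, imu_gyr = 0, imu_ang = 0)
}

# short noiseless single-bout kinetics for oracle tests
fx_quiet_kin <- function() memo("quiet_kin", {
  subj <- clin_subject(quiet_noise())
  pr <- make_speed_profile("clinical", 0.8, 100, 1, duration_scale = 0.25)
  simulate_kinetics(pr, subj, "left", seed = 11)
})

# short noisy session (both sides) used by preprocessing tests
fx_session <- function() memo("session", {
  simulate_session(clin_subject(), seed = 31, duration_scale = 0.25)
})

fx_dataset <- function(side = "left") memo(paste0("dataset_", side), {
  build_dataset(fx_session(), side)
})

# --- learning-suite fixtures (desk preset, reduced bout length) ---------

mdc_scale <- 0.2
mdc_seeds <- 1:5

fx_clin_dataset <- function(seed, side) {
  cfg <- run_config(seed = seed, duration_scale = mdc_scale)
  ses <- simulate_session(cfg$subject, seed = seed, n_bouts = cfg$n_bouts,
                          duration_scale = cfg$duration_scale)
  build_dataset(ses, side, cfg$preproc)
}

# one seed of the clinical study: paretic side trained in all three modes,
# non-paretic side with the fusion model (for symmetry); reports memoised,
# datasets discarded to bound memory
fx_study_seed <- function(seed) {
  memo(sprintf("study_%d", seed), {
    out <- list(seed = seed, reports = list())
    for (side in c("left", "right")) {
      ds <- fx_clin_dataset(seed, side)
      sp <- split_by_bout(ds)
      modes <- if (side == "left") c("fusion", "imu_only", "insole_only")
               else "fusion"
      for (mode in modes) {
        pre <- train_preset("desk", mode, seed = seed)
        tr <- train_model(ds, sp, pre$spec, pre$config)
        out$reports[[paste(side, mode, sep = "_")]] <-
          evaluate_model(tr, ds, sp)
      }
      rm(ds)
    }
    out
  })
}
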