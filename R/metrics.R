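#' Minimal detectable change thresholds
#'
#' Published MDC thresholds for treadmill walking in people post-stroke:
#' an estimator whose error falls below these can resolve changes beyond
#' stride-to-stride variability.
#'
#' @return named vector: peak propulsion (%BW), propulsion impulse
#'   (%BW*s), propulsion symmetry (%).
#' @export
mdc_thresholds <- function() {
  c(peak = 0.80, impulse = 0.24, symmetry = 3.92)
}

#' Stance-phase time-series errors
#'
#' RMSE (%BW), normalized RMSE (RMSE scaled to the range of the true
#' signal over the stance frames, in %) and the coefficient of
#' determination R^2, all computed over stance frames only.
#'
#' @param est,truth equal-length AP GRF series (%BW).
#' @param stance_mask logical mask of stance frames (default: all).
#' @return list(rmse, nrmse, r2).
#' @export
timeseries_errors <- function(est, truth, stance_mask = NULL) {
  assert_that(length(est) == length(truth), "est and truth lengths differ")
  if (is.null(stance_mask)) stance_mask <- rep(TRUE, length(est))
  assert_that(any(stance_mask), "empty stance mask")
  e <- est[stance_mask]; y <- truth[stance_mask]
  rmse <- sqrt(mean((e - y)^2))
  rng <- diff(range(y))
  nrmse <- if (rng > 0) rmse / rng * 100 else NA_real_
  ss_res <- sum((e - y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(rmse = rmse, nrmse = nrmse, r2 = r2)
}

#' Per-stride propulsion point metrics
#'
#' Peak propulsion is the maximum AP GRF over the stride's stance phase;
#' peak timing is the position of that maximum as a percentage of stance
#' duration (ties broken by the earliest frame); propulsion impulse is the
#' trapezoidal time integral of the positive region of AP GRF.
#'
#' @param ap_grf one stride's stance-phase AP GRF (%BW) at a fixed rate.
#' @param fs sampling rate, Hz (default 100).
#' @return list(peak %BW, timing_pct % of stance, impulse %BW*s).
#' @export
stride_point_metrics <- function(ap_grf, fs = 100) {
  n <- length(ap_grf)
  assert_that(n >= 2, "stride too short (%d frames)", n)
  peak <- max(ap_grf)
  timing <- (which.max(ap_grf) - 1) / (n - 1) * 100
  impulse <- pracma::trapz(seq(0, by = 1 / fs, length.out = n), pmax(ap_grf, 0))
  list(peak = peak, timing_pct = timing, impulse = impulse)
}

#' Propulsion symmetry
#'
#' The paretic propulsion impulse as a percentage of the two-limb total;
#' 50 % is perfect symmetry.
#'
#' @param paretic_impulse,nonparetic_impulse mean propulsion impulses
#'   (%BW*s), both non-negative with a positive total.
#' @return symmetry in percent.
#' @export
propulsion_symmetry <- function(paretic_impulse, nonparetic_impulse) {
  assert_that(paretic_impulse >= 0 && nonparetic_impulse >= 0,
              "impulses must be non-negative")
  tot <- paretic_impulse + nonparetic_impulse
  assert_that(tot > 0, "total impulse must be positive")
  100 * paretic_impulse / tot
}

#' Stride-matched point-metric RMSEs
#'
#' @param est data.frame of per-stride estimated metrics (columns `peak`,
#'   `timing_pct`, `impulse`).
#' @param truth matching data.frame of true metrics (same strides, same
#'   order).
#' @return named vector of RMSEs: peak (%BW), timing_pct (% of stance),
#'   impulse (%BW*s).
#' @export
metric_rmse <- function(est, truth) {
  assert_that(nrow(est) == nrow(truth) && nrow(est) >= 1,
              "stride sets must match and be non-empty")
  vapply(c("peak", "timing_pct", "impulse"), function(m) {
    sqrt(mean((est[[m]] - truth[[m]])^2))
  }, numeric(1))
}

#' Compare point-metric RMSEs against MDC thresholds
#'
#' @param rmses named vector with entries `peak`, `impulse` and optionally
#'   `symmetry`.
#' @return logical vector: RMSE strictly below its MDC threshold.
#' @export
mdc_check <- function(rmses) {
  thr <- mdc_thresholds()
  common <- intersect(names(thr), names(rmses))
  stats::setNames(rmses[common] < thr[common], common)
}

#' Paired model-comparison t-test
#'
#' Two-sided paired t-test on per-dataset error values of two models
#' (e.g. stance RMSEs of fusion vs IMU-only across datasets, both legs
#' pooled). With (near-)constant differences the test is degenerate and no
#' p-value is produced.
#'
#' @param errors_a,errors_b equal-length numeric vectors of paired errors.
#' @return list(t, p, df, mean_diff, degenerate).
#' @export
paired_model_test <- function(errors_a, errors_b) {
  assert_that(length(errors_a) == length(errors_b) && length(errors_a) >= 3,
              "need >= 3 paired error values")
  d <- errors_a - errors_b
  if (stats::sd(d) < 1e-12) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(errors_a, errors_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Evaluate a trained model on its test frames
#'
#' Predicts AP GRF on the test rows, computes stance time-series errors
#' and stride-matched propulsion point metrics (estimate vs the
#' force-plate-derived truth carried in the dataset targets), and flags
#' each point metric against its MDC threshold. Strides whose stance is
#' clipped by the bout boundary (fewer than `min_frames` frames) are
#' excluded from point metrics.
#'
#' @param trained a `gf_trained`.
#' @param dataset the dataset it was trained on.
#' @param split the split used (its `test` rows are evaluated).
#' @param min_frames minimum stance frames per stride (default 20).
#' @return list of class `eval_report`: `rmse`, `nrmse`, `r2`,
#'   `metric_rmse`, `mdc`, `strides` (per-stride est/true metrics),
#'   `mean_impulse_est`, `mean_impulse_true`, `n_test_frames`.
#' @export
evaluate_model <- function(trained, dataset, split, min_frames = 20L) {
  rows <- split$test
  assert_that(length(rows) > 0, "empty test set")
  est <- predict_grf(trained, dataset, rows)
  truth <- dataset$meta$target[rows]
  stance <- dataset$meta$stance[rows]
  ts <- timeseries_errors(est, truth, stance)
  sid <- dataset$meta$stride_id[rows]
  strides <- list()
  for (s in unique(stats::na.omit(sid[stance]))) {
    sel <- which(sid == s & stance)
    if (length(sel) < min_frames) next
    me <- stride_point_metrics(est[sel])
    mt <- stride_point_metrics(truth[sel])
    strides[[length(strides) + 1L]] <- data.frame(
      stride_id = s,
      peak_est = me$peak, peak_true = mt$peak,
      timing_est = me$timing_pct, timing_true = mt$timing_pct,
      impulse_est = me$impulse, impulse_true = mt$impulse)
  }
  strides <- if (length(strides)) do.call(rbind, strides) else NULL
  mr <- if (!is.null(strides)) {
    metric_rmse(
      data.frame(peak = strides$peak_est, timing_pct = strides$timing_est,
                 impulse = strides$impulse_est),
      data.frame(peak = strides$peak_true, timing_pct = strides$timing_true,
                 impulse = strides$impulse_true))
  } else c(peak = NA_real_, timing_pct = NA_real_, impulse = NA_real_)
  structure(list(
    rmse = ts$rmse, nrmse = ts$nrmse, r2 = ts$r2,
    metric_rmse = mr, mdc = mdc_check(mr),
    strides = strides,
    mean_impulse_est = if (!is.null(strides)) mean(pmax(strides$impulse_est, 0)) else NA_real_,
    mean_impulse_true = if (!is.null(strides)) mean(strides$impulse_true) else NA_real_,
    n_test_frames = length(rows)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> stance RMSE %.3f %%BW, NRMSE %.2f %%, ",
                     "R2 %.3f\n  peak RMSE %.3f %%BW, impulse RMSE %.3f ",
                     "%%BW.s, timing RMSE %.2f %%stance\n"),
              x$rmse, x$nrmse, x$r2, x$metric_rmse["peak"],
              x$metric_rmse["impulse"], x$metric_rmse["timing_pct"]))
  invisible(x)
}
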